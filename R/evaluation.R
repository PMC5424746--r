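# Gesture-level evaluation: end-to-end error over interleaved sessions,
# sample-level cross-validation accuracy, and the COMPLETE vs REDUCED
# comparison on one synthetic subject.

#' End-to-end gesture execution error
#'
#' Counts wrong movements at the gesture level: intended and executed
#' movements are matched in order, a wrong gesture counts one error, and a
#' missed movement (an onset that produced no actuation, `NA`, or a missing
#' tail entry) also counts one. One error in 10 movements is a 10% error
#' rate (90% accuracy); one in 60 is 1.67% (the headline session length).
#'
#' @param intended Character vector of intended movements, resets included.
#' @param executed Character vector of movements in order of actuation;
#'   `NA` entries mark onsets that produced no movement.
#' @return An object of class `session_result`: `intended`, `executed`,
#'   `fsm_errors`, `error_rate_pct`, `accuracy_pct`.
#' @examples
#' r <- end_to_end_error(rep("POWER_GRASP", 10),
#'                       c(rep("POWER_GRASP", 9), "POINT_INDEX"))
#' r$error_rate_pct  # 10
#' @export
end_to_end_error <- function(intended, executed) {
  if (!length(intended)) stop("intended must be non-empty")
  n <- length(intended)
  m <- length(executed)
  comp <- executed[seq_len(n)]            # pads with NA when m < n
  errors <- sum(is.na(comp) | comp != intended)
  if (m > n) errors <- errors + (m - n)   # extra movements are wrong too
  structure(list(intended = intended, executed = executed,
                 fsm_errors = as.integer(errors),
                 error_rate_pct = 100 * errors / n,
                 accuracy_pct = 100 - 100 * errors / n),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %d movements, %d FSM errors (%.2f%% error, %.2f%% accuracy)\n",
              length(x$intended), x$fsm_errors, x$error_rate_pct,
              x$accuracy_pct))
  invisible(x)
}

#' Stratified k-fold cross-validation sample accuracy
#'
#' Splits each class into `k` folds, trains on `k - 1` and scores
#' [svm_predict()] on the held-out frames; reports the mean per-sample
#' accuracy over folds, as a percentage.
#'
#' @param frames Labeled frame set (see [gen_training_set()]).
#' @param gamma,cost Classifier hyperparameters (see [train_model()]).
#' @param k Number of folds (>= 2); every class needs at least `k` samples.
#' @param seed Integer seed for the fold assignment.
#' @param mode Training mode passed to [train_model()].
#' @return Accuracy percentage.
#' @export
cross_val_accuracy <- function(frames, gamma = NULL, cost = 1, k = 5,
                               seed = 1, mode = c("COMPLETE", "REDUCED")) {
  mode <- match.arg(mode)
  if (k < 2) stop("k must be >= 2")
  # canonical row order (label, then feature values) so folds — and hence
  # the reported accuracy — do not depend on the input sample order
  canon <- do.call(order, c(list(frames$label),
                            unname(frames[setdiff(names(frames), "label")])))
  frames <- frames[canon, , drop = FALSE]
  labs <- as.character(frames$label)
  counts <- table(labs)
  if (any(counts < k))
    stop("every class needs at least k samples; smallest has ", min(counts))
  fold <- integer(length(labs))
  fold_of <- withr::with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labs == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
  acc <- vapply(seq_len(k), function(f) {
    train <- frames[fold_of != f, , drop = FALSE]
    test <- frames[fold_of == f, , drop = FALSE]
    m <- train_model(train, gamma = gamma, cost = cost, mode = mode)
    x <- as.matrix(test[setdiff(names(test), "label")])
    mean(svm_predict(x, m) == test$label)
  }, 1.0)
  100 * mean(acc)
}

#' Run the full experiment on one synthetic subject
#'
#' The synthetic analogue of one subject row of the study: generate a
#' training set and a 60-movement interleaved session from one profile
#' set, train a COMPLETE (4-class) and a REDUCED (3-class, open hand
#' excluded) model, run the controller in both modes on the same session
#' stream, and report model size and gesture-level results for each.
#'
#' @param profiles Named list of [gesture_profile()]s
#'   (default [default_profiles()]).
#' @param reps Session repetitions per gesture (10 gives 60 movements).
#' @param reps_training Training contractions per gesture.
#' @param seed Integer seed for the subject.
#' @param cv If `TRUE`, also compute 5-fold cross-validation accuracy.
#' @param gamma,cost Classifier hyperparameters.
#' @return A list with `reports` (per mode: `mode`, `n_sv`,
#'   `footprint_bytes`, `cv_accuracy_pct`) and `sessions` (per mode: a
#'   [end_to_end_error()] `session_result`), plus the generated `intended`
#'   sequence.
#' @export
run_experiment <- function(profiles = default_profiles(), reps = 10,
                           reps_training = 4, seed = 1, cv = TRUE,
                           gamma = NULL, cost = 1) {
  session <- gen_session(profiles, reps = reps, seed = seed)
  out <- list(reports = list(), sessions = list(), intended = session$intended)
  for (mode in c("COMPLETE", "REDUCED")) {
    tr <- gen_training_set(profiles, reps_per_gesture = reps_training,
                           mode = mode, seed = seed + 1L)
    model <- train_model(tr, gamma = gamma, cost = cost, mode = mode)
    cfg <- controller_config(mode = mode)
    run <- run_controller(session$stream, model, cfg)
    res <- end_to_end_error(session$intended, run$attempts)
    out$reports[[mode]] <- list(
      mode = mode, n_sv = sum(model$sv_counts),
      footprint_bytes = model_footprint_bytes(model),
      cv_accuracy_pct = if (cv) cross_val_accuracy(tr, gamma = gamma,
                                                   cost = cost, seed = seed,
                                                   mode = mode) else NA_real_)
    out$sessions[[mode]] <- res
  }
  out
}

#' Replay a recorded session CSV through the controller
#'
#' Identical semantics to [run_controller()] followed by
#' [end_to_end_error()], with the intended movement sequence recovered
#' from the CSV's label column (each contiguous non-REST label run is one
#' intended movement). Works for any channel count consistent with the
#' model.
#'
#' @param path Session CSV path (dialect of [write_session_csv()]).
#' @param model An [emg_svm_model()].
#' @param config A [controller_config()].
#' @param hand A [hand_sim()].
#' @return A list: `result` (a `session_result`), `run` (the
#'   [run_controller()] output), `intended`.
#' @export
replay_csv <- function(path, model, config = controller_config(),
                       hand = hand_sim()) {
  stream <- read_session_csv(path)
  if (n_channels(stream) != model$n_features)
    stop("session has ", n_channels(stream),
         " channels but the model expects ", model$n_features)
  if (is.null(stream$labels))
    stop("replay needs a labeled session to recover the intended sequence")
  runs <- rle(stream$labels)
  intended <- runs$values[runs$values != REST]
  if (!length(intended)) stop("session contains no intended movements")
  run <- run_controller(stream, model, config, hand)
  list(result = end_to_end_error(intended, run$attempts),
       run = run, intended = intended)
}
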
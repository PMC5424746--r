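# Classification-mode finite state machine.
#
# Pipeline per frame: ADC acquisition (16-sample averaging happens upstream
# of the stream), spike removal (bursts above the activation threshold for
# less than 100 ms are ignored as involuntary artifacts), SVM majority
# voting over 20 consecutive classifications, gesture configuration and
# actuation with motor current-feedback stop, then a hold phase: the user
# may relax, the hand keeps its configuration, and the next detected
# contraction can only lead back to the open (reset) position — directly in
# REDUCED mode, or after an open-hand classification in COMPLETE mode.

#' Controller configuration
#'
#' @param activation_threshold Envelope level (V) that counts as a
#'   contraction; with 0.05 V baseline and 0.15 V noise, 0.3 V triggers on
#'   real onsets while rest noise cannot sustain it for 100 ms.
#' @param decontraction_threshold Level (V) below which the muscles count
#'   as relaxed; kept under the activation threshold for hysteresis.
#' @param spike_min_duration_ms Minimum supra-threshold duration (ms) for a
#'   voluntary contraction; shorter bursts are filtered (boundary
#'   inclusive: exactly 100 ms triggers).
#' @param vote_window Consecutive SVM classifications pooled by majority
#'   voting into one gesture decision; 20 at 500 Hz gives a decision
#'   every 40 ms.
#' @param mode `"COMPLETE"` (open hand is a recognized class) or
#'   `"REDUCED"` (any contraction while holding a gesture triggers the
#'   reset without classification).
#' @param activation_measure Per-frame aggregate compared against the
#'   thresholds: `"max"` (default, most sensitive), `"mean"` or `"sum"`
#'   over channels.
#' @param frame_rate_hz Sampling rate (Hz).
#' @param adc_oversample ADC samples averaged per frame upstream.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(activation_threshold = 0.3,
                              decontraction_threshold = 0.2,
                              spike_min_duration_ms = 100,
                              vote_window = 20,
                              mode = c("COMPLETE", "REDUCED"),
                              activation_measure = c("max", "mean", "sum"),
                              frame_rate_hz = EMG_SAMPLE_RATE_HZ,
                              adc_oversample = 16) {
  mode <- match.arg(mode)
  activation_measure <- match.arg(activation_measure)
  if (activation_threshold <= 0 || activation_threshold >= ADC_SPAN_V[2] ||
      decontraction_threshold <= 0 || decontraction_threshold >= ADC_SPAN_V[2])
    stop("thresholds must lie within (0, 3.3) V")
  if (vote_window < 1) stop("vote_window must be >= 1")
  spike_frames <- spike_min_duration_ms * frame_rate_hz / 1000
  if (spike_frames != as.integer(spike_frames))
    stop("spike_min_duration_ms must correspond to an integer frame count")
  structure(list(activation_threshold = activation_threshold,
                 decontraction_threshold = decontraction_threshold,
                 spike_min_duration_ms = spike_min_duration_ms,
                 spike_frames = as.integer(spike_frames),
                 vote_window = as.integer(vote_window),
                 mode = mode,
                 activation_measure = activation_measure,
                 frame_rate_hz = frame_rate_hz,
                 adc_oversample = as.integer(adc_oversample)),
            class = "controller_config")
}

activation_of <- function(channels, measure) {
  switch(measure,
         max = if (is.matrix(channels)) apply(channels, 1, max) else max(channels),
         mean = if (is.matrix(channels)) rowMeans(channels) else mean(channels),
         sum = if (is.matrix(channels)) rowSums(channels) else sum(channels))
}

#' Average a burst of raw ADC samples into one envelope frame
#'
#' The acquisition stage extracts the per-channel arithmetic mean of 16
#' consecutive ADC samples of the EMG channels.
#'
#' @param raw A `adc_oversample x NF` matrix of raw samples.
#' @param config A [controller_config()].
#' @return Numeric vector of per-channel means.
#' @export
acquire_frame <- function(raw, config = controller_config()) {
  raw <- as.matrix(raw)
  if (nrow(raw) != config$adc_oversample)
    stop("expected ", config$adc_oversample, " samples per channel, got ",
         nrow(raw))
  colMeans(raw)
}

#' Majority vote over consecutive classifications
#'
#' Returns the label with the highest count; ties resolve to the gesture
#' with the lowest id.
#'
#' @param labels Non-empty character vector of gesture names.
#' @return A single gesture name.
#' @examples
#' majority_vote(c("POWER_GRASP", "POINT_INDEX", "POWER_GRASP"))
#' @export
majority_vote <- function(labels) {
  if (!length(labels)) stop("cannot vote over an empty label list")
  ids <- sort(unique(gesture_id(labels)))
  counts <- vapply(ids, function(i) sum(gesture_id(labels) == i), 1L)
  gesture_name(ids[which.max(counts)])  # ties: lowest id wins
}

#' Create a fresh controller state
#'
#' The FSM node is one of `IDLE` (hand open, waiting for a contraction),
#' `ONSET_CHECK` (counting supra-threshold frames for spike removal),
#' `VOTING` (collecting classifications), `ACTUATING` (motors driving a
#' gesture), `HOLDING` (hand in a non-open configuration, muscles may be
#' relaxed) and `RESETTING` (motors driving back to open). `armed` records
#' that a decontraction was seen since the last actuation — the re-trigger
#' condition.
#'
#' @param config A [controller_config()].
#' @param hand A [hand_sim()].
#' @return An object of class `controller_state`.
#' @export
controller_state <- function(config = controller_config(),
                             hand = hand_sim()) {
  structure(list(node = "IDLE", above_threshold_frames = 0L,
                 vote_buffer = character(0), from_hold = FALSE,
                 armed = TRUE, hand = hand, hand_position = "OPEN_HAND",
                 pending = NULL, motor_frames_left = 0L),
            class = "controller_state")
}

#' One spike-removal step
#'
#' Applies the artifact filter to a single frame while the FSM sits in
#' `IDLE` or `ONSET_CHECK`: the supra-threshold counter increments while
#' the activation measure exceeds the threshold, resets if the signal drops
#' below before 100 ms worth of frames, and promotes the state to `VOTING`
#' once the count reaches the 100 ms bound (inclusive).
#'
#' @param state A [controller_state()] in node `IDLE` or `ONSET_CHECK`.
#' @param frame Numeric channel vector for one frame.
#' @param config A [controller_config()].
#' @return The updated `controller_state`.
#' @export
spike_filter_step <- function(state, frame, config = controller_config()) {
  stopifnot(inherits(state, "controller_state"))
  if (!state$node %in% c("IDLE", "ONSET_CHECK"))
    stop("spike_filter_step applies only in IDLE or ONSET_CHECK")
  a <- activation_of(frame, config$activation_measure)
  if (state$node == "IDLE") {
    if (!state$armed) {
      if (a < config$decontraction_threshold) state$armed <- TRUE
    } else if (a >= config$activation_threshold) {
      state$node <- "ONSET_CHECK"
      state$above_threshold_frames <- 1L
      state$from_hold <- FALSE
    }
    return(state)
  }
  if (a >= config$activation_threshold) {
    state$above_threshold_frames <- state$above_threshold_frames + 1L
    if (state$above_threshold_frames >= config$spike_frames) {
      state$above_threshold_frames <- 0L
      if (state$from_hold && config$mode == "REDUCED") {
        state$node <- "RESETTING"
        state$pending <- "OPEN_HAND"
      } else {
        state$node <- "VOTING"
        state$vote_buffer <- character(0)
      }
    }
  } else {
    state$above_threshold_frames <- 0L
    state$node <- if (state$from_hold) "HOLDING" else "IDLE"
  }
  state
}

#' One SVM-voting step
#'
#' Classifies a frame and appends the label to the vote buffer; once the
#' buffer holds `vote_window` entries the majority gesture is resolved and
#' the state moves to actuation (or, while holding in COMPLETE mode, the
#' decision is ignored unless it is the open hand).
#'
#' @param state A [controller_state()] in node `VOTING`.
#' @param frame Numeric channel vector.
#' @param model An [emg_svm_model()].
#' @param config A [controller_config()].
#' @return The updated `controller_state`; after a resolved decision the
#'   field `decision` holds the majority gesture (or `NA` for an ignored
#'   one).
#' @export
voting_step <- function(state, frame, model, config = controller_config()) {
  stopifnot(inherits(state, "controller_state"))
  if (state$node != "VOTING") stop("voting_step applies only in VOTING")
  state$vote_buffer <- c(state$vote_buffer, svm_predict(frame, model))
  if (length(state$vote_buffer) < config$vote_window) return(state)
  g <- majority_vote(state$vote_buffer)
  state$vote_buffer <- character(0)
  state$decision <- g
  if (state$from_hold) {
    if (config$mode == "COMPLETE" && g == "OPEN_HAND") {
      state$node <- "RESETTING"; state$pending <- "OPEN_HAND"
    } else {  # hand holds its configuration; wait for decontraction
      state$node <- "HOLDING"; state$armed <- FALSE; state$decision <- NA
    }
  } else {
    if (g == "OPEN_HAND") {  # hand is already open: nothing to actuate
      state$node <- "IDLE"; state$armed <- FALSE; state$decision <- NA
    } else {
      state$node <- "ACTUATING"; state$pending <- g
    }
  }
  state
}

#' Run the full control strategy over a stream
#'
#' Executes the classification-mode FSM frame by frame: spike removal,
#' majority voting, actuation with simulated motor time, hold until
#' decontraction, and reset logic per the configured mode. The output
#' trace uses the controller encoding: positive codes for gestures, -1
#' for the reset (open hand) position.
#'
#' @param stream A 500 Hz [emg_stream()].
#' @param model An [emg_svm_model()]; its class set must match the mode
#'   (no OPEN_HAND class in REDUCED mode).
#' @param config A [controller_config()].
#' @param hand A [hand_sim()].
#' @return A list:
#'   \describe{
#'     \item{executed}{data frame `(t_ms, gesture)` of completed movements,
#'       resets included.}
#'     \item{attempts}{character vector with one entry per decision
#'       episode: the executed gesture, or `NA` for an onset that produced
#'       no actuation.}
#'     \item{trace}{data frame `(t_ms, node, output_code)` per frame.}
#'     \item{events}{data frame `(t_ms, event, gesture)` marking
#'       `voting_start`, `decision`, `actuated` and `reset`.}
#'     \item{hand}{final [hand_sim()] state.}
#'   }
#' @export
run_controller <- function(stream, model, config = controller_config(),
                           hand = hand_sim()) {
  stopifnot(inherits(stream, "emg_stream"), inherits(model, "emg_svm_model"),
            inherits(config, "controller_config"))
  has_open <- 0L %in% model$class_ids
  if (config$mode == "REDUCED" && has_open)
    stop("REDUCED mode requires a model without the OPEN_HAND class")
  if (config$mode == "COMPLETE" && !has_open)
    stop("COMPLETE mode requires a model that recognizes OPEN_HAND")
  if (n_channels(stream) != model$n_features)
    stop("stream has ", n_channels(stream), " channels but the model expects ",
         model$n_features)

  n <- n_frames(stream)
  t_ms <- stream$t_ms
  act <- activation_of(stream$channels, config$activation_measure)
  ch <- stream$channels
  frame_ms <- 1000 / config$frame_rate_hz
  spike_frames <- config$spike_frames
  vote_window <- config$vote_window
  reduced <- config$mode == "REDUCED"
  act_thr <- config$activation_threshold
  dec_thr <- config$decontraction_threshold

  # lean single-frame predictor over the packed model
  ncl <- model$n_classes
  svt <- t(model$support_vectors)
  gamma <- model$gamma
  coefs <- model$coefficients
  rho <- model$rho
  blocks <- lapply(seq_len(ncl), function(i) class_block(model, i))
  predict_id <- function(x) {
    K <- exp(-gamma * colSums((svt - x)^2))
    v <- integer(ncl); p <- 0L
    for (j in seq_len(ncl - 1L)) for (k in (j + 1L):ncl) {
      p <- p + 1L
      f <- sum(coefs[blocks[[j]], k - 1] * K[blocks[[j]]]) +
           sum(coefs[blocks[[k]], j] * K[blocks[[k]]]) - rho[p]
      if (f > 0) v[j] <- v[j] + 1L else v[k] <- v[k] + 1L
    }
    which.max(v)
  }
  class_labels <- gesture_name(model$class_ids)

  node <- "IDLE"; cnt <- 0L; from_hold <- FALSE; armed <- TRUE
  votes <- integer(vote_window); nv <- 0L
  pending <- NA_character_; motor_left <- 0L
  hand_position <- "OPEN_HAND"
  trace_node <- character(n); trace_code <- integer(n)
  exec_t <- numeric(0); exec_g <- character(0)
  attempts <- character(0)
  ev_t <- numeric(0); ev_e <- character(0); ev_g <- character(0)

  start_motor <- function(gesture) {
    res <- actuate(hand, gesture)
    hand <<- res$hand
    motor_left <<- max(1L, as.integer(ceiling(res$duration_ms / frame_ms)))
    pending <<- gesture
  }

  for (i in seq_len(n)) {
    a <- act[i]
    if (node == "IDLE" || node == "HOLDING") {
      if (!armed) {
        if (a < dec_thr) armed <- TRUE
      } else if (a >= act_thr) {
        from_hold <- node == "HOLDING"
        node <- "ONSET_CHECK"
        cnt <- 1L
      }
    } else if (node == "ONSET_CHECK") {
      if (a >= act_thr) {
        cnt <- cnt + 1L
        if (cnt >= spike_frames) {
          cnt <- 0L
          if (from_hold && reduced) {
            node <- "RESETTING"
            start_motor("OPEN_HAND")
          } else {
            node <- "VOTING"; nv <- 0L
            ev_t <- c(ev_t, t_ms[i]); ev_e <- c(ev_e, "voting_start")
            ev_g <- c(ev_g, NA_character_)
          }
        }
      } else {
        cnt <- 0L
        node <- if (from_hold) "HOLDING" else "IDLE"
      }
    } else if (node == "VOTING") {
      nv <- nv + 1L
      votes[nv] <- predict_id(ch[i, ])
      if (nv == vote_window) {
        tab <- tabulate(votes, nbins = ncl)
        g <- class_labels[which.max(tab)]
        ev_t <- c(ev_t, t_ms[i]); ev_e <- c(ev_e, "decision"); ev_g <- c(ev_g, g)
        if (from_hold) {
          if (!reduced && g == "OPEN_HAND") {
            node <- "RESETTING"; start_motor("OPEN_HAND")
          } else {
            attempts <- c(attempts, NA_character_)
            node <- "HOLDING"; armed <- FALSE
          }
        } else {
          if (g == "OPEN_HAND") {
            attempts <- c(attempts, NA_character_)
            node <- "IDLE"; armed <- FALSE
          } else {
            node <- "ACTUATING"; start_motor(g)
          }
        }
      }
    } else {  # ACTUATING or RESETTING
      motor_left <- motor_left - 1L
      if (motor_left <= 0L) {
        hand_position <- pending
        exec_t <- c(exec_t, t_ms[i]); exec_g <- c(exec_g, pending)
        attempts <- c(attempts, pending)
        ev_t <- c(ev_t, t_ms[i])
        ev_e <- c(ev_e, if (pending == "OPEN_HAND") "reset" else "actuated")
        ev_g <- c(ev_g, pending)
        node <- if (pending == "OPEN_HAND") "IDLE" else "HOLDING"
        armed <- FALSE
        pending <- NA_character_
      }
    }
    trace_node[i] <- node
    trace_code[i] <- gesture_code(hand_position)
  }

  list(executed = data.frame(t_ms = exec_t, gesture = exec_g,
                             stringsAsFactors = FALSE),
       attempts = attempts,
       trace = data.frame(t_ms = t_ms, node = trace_node,
                          output_code = trace_code, stringsAsFactors = FALSE),
       events = data.frame(t_ms = ev_t, event = ev_e, gesture = ev_g,
                           stringsAsFactors = FALSE),
       hand = hand)
}
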
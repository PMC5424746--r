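# One-vs-one RBF-SVM prediction as executed on the embedded node, plus the
# offline training front-end that packs a solver's output into the flash
# layout. Storage is single precision; the decision sums accumulate in
# double precision.

#' RBF kernel
#'
#' `exp(-gamma * ||x - s||^2)`; equals 1 exactly when `x == s` and is
#' bounded in (0, 1] for finite inputs. `gamma = 1 / (2 sigma^2)`.
#'
#' @param x,s Numeric feature vectors of equal length.
#' @param gamma Positive kernel parameter.
#' @return A scalar in (0, 1].
#' @examples
#' rbf_kernel(c(0, 0, 0, 0), c(1, 0, 0, 0), gamma = 0.5)  # exp(-0.5)
#' @export
rbf_kernel <- function(x, s, gamma) {
  if (length(x) != length(s))
    stop("feature vectors must have equal length")
  if (gamma <= 0) stop("gamma must be positive")
  exp(-gamma * sum((x - s)^2))
}

# kernel values of x against every SV of the model (double accumulation)
kernel_row <- function(x, model) {
  d2 <- colSums((t(model$support_vectors) - x)^2)
  exp(-model$gamma * d2)
}

#' Binary decision value for one class pair
#'
#' Evaluates `f(x) = sum_i C_i K(x, s_i) - rho` over the support vectors of
#' classes `j` and `k` (the one-vs-one convention: only those two blocks
#' participate), using the pre-computed coefficients `C_i = y_i alpha_i`.
#' Sign convention: `f(x) > 0` votes class `j`, otherwise class `k`.
#'
#' @param x Feature vector of length `NF`.
#' @param model An [emg_svm_model()].
#' @param j,k Stored class indices with `j < k`.
#' @return The real decision value `f(x)`.
#' @export
pair_decision <- function(x, model, j, k) {
  stopifnot(inherits(model, "emg_svm_model"))
  ncl <- model$n_classes
  if (!(j >= 1 && k <= ncl && j < k))
    stop("invalid class pair: need 1 <= j < k <= NCl")
  if (length(x) != model$n_features)
    stop("feature vector length must equal the model's NF")
  K <- kernel_row(x, model)
  bi <- class_block(model, j); bj <- class_block(model, k)
  sum(model$coefficients[bi, k - 1] * K[bi]) +
    sum(model$coefficients[bj, j] * K[bj]) -
    model$rho[pair_index(ncl, j, k)]
}

#' Predict the gesture of envelope frames
#'
#' Runs the one-vs-one vote: every class pair casts exactly one vote
#' (`f(x) > 0` for the first class of the pair, otherwise the second —
#' `f(x) = 0` therefore votes the second), and the class with the most
#' votes wins; vote ties resolve to the lowest stored class index.
#'
#' @param x A feature vector of length `NF`, or a matrix with one frame
#'   per row.
#' @param model An [emg_svm_model()].
#' @param votes If `TRUE`, also return the vote vector(s); votes always sum
#'   to `NCl (NCl - 1) / 2`.
#' @return Gesture name(s); with `votes = TRUE`, a list with `label` and
#'   `votes`.
#' @export
svm_predict <- function(x, model, votes = FALSE) {
  stopifnot(inherits(model, "emg_svm_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_features)
    stop("frames have ", ncol(x), " features but the model expects ",
         model$n_features)
  ncl <- model$n_classes
  vm <- matrix(0L, nrow(x), ncl)
  idx <- integer(nrow(x))
  for (r in seq_len(nrow(x))) {
    K <- kernel_row(x[r, ], model)
    v <- integer(ncl); p <- 0L
    for (j in seq_len(ncl - 1L)) {
      bi <- class_block(model, j)
      for (k in (j + 1L):ncl) {
        p <- p + 1L
        bj <- class_block(model, k)
        f <- sum(model$coefficients[bi, k - 1] * K[bi]) +
             sum(model$coefficients[bj, j] * K[bj]) - model$rho[p]
        if (f > 0) v[j] <- v[j] + 1L else v[k] <- v[k] + 1L
      }
    }
    vm[r, ] <- v
    idx[r] <- which.max(v)
  }
  labels <- gesture_name(model$class_ids[idx])
  if (votes) list(label = labels, votes = vm) else labels
}

#' Train and pack a gesture classifier
#'
#' Delegates the soft-margin optimization to libsvm (via e1071) with an RBF
#' kernel on raw envelope voltages (no feature scaling, matching the
#' embedded pipeline), then repacks the solver's dual solution into the
#' flash layout with pre-computed coefficients `C_i = y_i alpha_i`.
#' Training frames are ordered by gesture id first, so the packed class
#' order (and hence the vote tie-break) is ascending id.
#'
#' @param frames Data frame of labeled steady-state frames as produced by
#'   [gen_training_set()]: channel columns plus a `label` column.
#' @param gamma RBF parameter; default `1 / NF`.
#' @param cost Soft-margin regularization constant C.
#' @param mode `"COMPLETE"` or `"REDUCED"`; in REDUCED mode the open-hand
#'   gesture must be absent from `frames`.
#' @return An [emg_svm_model()].
#' @examples
#' tr <- gen_training_set(default_profiles(), 2, "COMPLETE", seed = 1)
#' m <- train_model(tr)
#' m$n_classes
#' @export
train_model <- function(frames, gamma = NULL, cost = 1,
                        mode = c("COMPLETE", "REDUCED")) {
  mode <- match.arg(mode)
  if (!"label" %in% names(frames)) stop("frames must have a label column")
  labs <- as.character(frames$label)
  if (REST %in% labs) stop("REST frames are not classes; remove them before training")
  classes <- unique(labs)
  if (length(classes) < 2) stop("training needs at least two classes")
  if (mode == "REDUCED" && "OPEN_HAND" %in% classes)
    stop("REDUCED mode excludes OPEN_HAND from the training set")
  x <- as.matrix(frames[setdiff(names(frames), "label")])
  storage.mode(x) <- "double"
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  ids <- gesture_id(labs)
  ord <- order(ids)            # ascending gesture id -> stored class order
  x <- x[ord, , drop = FALSE]
  ids <- ids[ord]
  y <- factor(ids, levels = sort(unique(ids)))
  fit <- e1071::svm(x, y, scale = FALSE, kernel = "radial",
                    gamma = gamma, cost = cost)
  # libsvm stores SVs grouped by class in order of appearance; with frames
  # sorted by id this is ascending id order. coefs is already NS x (NCl-1)
  # in the per-class-column convention; rho is one offset per pair (j,k).
  class_ids <- as.integer(as.character(fit$levels[fit$labels]))
  emg_svm_model(gamma = gamma,
                class_ids = class_ids,
                sv_counts = fit$nSV,
                support_vectors = fit$SV,
                coefficients = fit$coefs,
                rho = fit$rho)
}
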
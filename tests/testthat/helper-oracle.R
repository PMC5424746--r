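# Independent brute-force one-vs-one evaluator, written directly from the
# decision-function definition with plain loops. It shares no code with the
# package's prediction path and serves as its oracle.

naive_rbf <- function(x, s, gamma) {
  d2 <- 0
  for (q in seq_along(x)) d2 <- d2 + (x[q] - s[q])^2
  exp(-gamma * d2)
}

naive_ovo_predict <- function(x, model) {
  ncl <- model$n_classes
  ends <- cumsum(model$sv_counts)
  starts <- c(1L, ends[-ncl] + 1L)
  v <- integer(ncl)
  p <- 0L
  for (j in 1:(ncl - 1)) {
    for (k in (j + 1):ncl) {
      p <- p + 1L
      f <- 0
      for (i in starts[j]:ends[j])
        f <- f + model$coefficients[i, k - 1] *
          naive_rbf(x, model$support_vectors[i, ], model$gamma)
      for (i in starts[k]:ends[k])
        f <- f + model$coefficients[i, j] *
          naive_rbf(x, model$support_vectors[i, ], model$gamma)
      f <- f - model$rho[p]
      if (f > 0) v[j] <- v[j] + 1L else v[k] <- v[k] + 1L
    }
  }
  best <- 1L
  for (c in 2:ncl) if (v[c] > v[best]) best <- c
  gesture_name(model$class_ids[best])
}

# random small packed model (NCl <= 4, NS <= 30) for equivalence sweeps
random_model <- function(seed) {
  withr::with_seed(seed, {
    ncl <- sample(2:4, 1)
    nf <- sample(2:5, 1)
    class_ids <- sort(sample(0:3, ncl))
    sv_counts <- sample(1:7, ncl, replace = TRUE)
    ns <- sum(sv_counts)
    emg_svm_model(gamma = runif(1, 0.1, 2),
                  class_ids = class_ids,
                  sv_counts = sv_counts,
                  support_vectors = matrix(runif(ns * nf, 0, 3.3), ns, nf),
                  coefficients = matrix(rnorm(ns * (ncl - 1)), ns, ncl - 1),
                  rho = rnorm(ncl * (ncl - 1) / 2))
  })
}
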
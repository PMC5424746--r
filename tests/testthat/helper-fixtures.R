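# Shared fixtures built in code at test time.

noiseless_profiles <- function() default_profiles(noise_sd = 0)

# small trained model + matching config, cached per test file run
trained_fixture <- local({
  cache <- list()
  function(mode = "COMPLETE", noise_sd = 0.15, seed = 42) {
    key <- paste(mode, noise_sd, seed)
    if (is.null(cache[[key]])) {
      p <- default_profiles(noise_sd = noise_sd)
      tr <- gen_training_set(p, reps_per_gesture = 3, mode = mode,
                             seed = seed)
      cache[[key]] <<- list(
        profiles = p, training = tr,
        model = train_model(tr, mode = mode),
        config = controller_config(mode = mode))
    }
    cache[[key]]
  }
})

# two-class, one-SV-per-class model with hand-chosen parameters
tiny_pair_model <- function(gamma = 1, rho = 0, c1 = 1, c2 = -1) {
  emg_svm_model(gamma = gamma, class_ids = c(1L, 2L), sv_counts = c(1L, 1L),
                support_vectors = rbind(c(1, 0), c(0, 1)),
                coefficients = matrix(c(c1, c2), 2, 1),
                rho = rho)
}
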
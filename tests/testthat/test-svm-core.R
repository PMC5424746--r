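test_that("the RBF kernel matches its closed form and bounds", {
  expect_equal(rbf_kernel(c(1, 2, 3), c(1, 2, 3), gamma = 5), 1)
  expect_equal(rbf_kernel(c(0, 0, 0, 0), c(1, 0, 0, 0), gamma = 0.5),
               exp(-0.5))
  expect_equal(rbf_kernel(c(0, 1), c(1, 0), gamma = 1e-12), 1,
               tolerance = 1e-9)  # gamma -> 0+ limit
  # symmetry and (0, 1] bounds on random pairs
  for (s in 1:20) {
    xy <- withr::with_seed(s, matrix(rnorm(8), 2))
    k1 <- rbf_kernel(xy[1, ], xy[2, ], gamma = 0.7)
    expect_identical(k1, rbf_kernel(xy[2, ], xy[1, ], gamma = 0.7))
    expect_true(k1 > 0 && k1 <= 1)
  }
  expect_error(rbf_kernel(1:3, 1:4, 1), "equal length")
})

test_that("pair decisions follow the two-block sum with the pair offset", {
  m <- tiny_pair_model(gamma = 1, rho = 0)
  expect_equal(pair_decision(c(1, 0), m, 1, 2), 1 - exp(-2),
               tolerance = 1e-6)
  # equidistant input with symmetric coefficients: exact cancellation
  expect_equal(pair_decision(c(0.5, 0.5), m, 1, 2), 0)
  # offset beyond the attainable kernel sum forces f < 0 everywhere
  m2 <- tiny_pair_model(gamma = 1, rho = 2.5)
  for (s in 1:10) {
    x <- withr::with_seed(s, runif(2, 0, 3.3))
    expect_lt(pair_decision(x, m2, 1, 2), 0)
  }
  expect_error(pair_decision(c(1, 0), m, 2, 1), "pair")
  expect_error(pair_decision(c(1, 0, 0), m, 1, 2), "length")
})

test_that("prediction votes per pair and breaks ties at the lowest index", {
  m <- tiny_pair_model()
  expect_equal(svm_predict(c(1, 0), m), "POWER_GRASP")
  expect_equal(svm_predict(c(0, 1), m), "POINT_INDEX")

  # 3-cycle: each class wins exactly one pair; lowest id must win
  cyc <- emg_svm_model(gamma = 1, class_ids = 1:3, sv_counts = c(1, 1, 1),
                       support_vectors = matrix(0, 3, 2),
                       coefficients = matrix(0, 3, 2),
                       rho = c(-1, 1, -1))
  out <- svm_predict(c(0, 0), cyc, votes = TRUE)
  expect_equal(as.vector(out$votes), c(1L, 1L, 1L))
  expect_equal(out$label, "POWER_GRASP")

  expect_error(svm_predict(c(1, 2, 3), m), "features")
})

test_that("votes always sum to the number of class pairs", {
  for (s in 1:25) {
    m <- random_model(s)
    x <- withr::with_seed(1000 + s,
                          matrix(runif(5 * m$n_features, 0, 3.3), 5))
    v <- svm_predict(x, m, votes = TRUE)$votes
    expect_true(all(rowSums(v) == m$n_classes * (m$n_classes - 1) / 2))
  }
})

test_that("prediction agrees with the brute-force one-vs-one oracle", {
  for (s in 1:40) {
    m <- random_model(s)
    x <- withr::with_seed(5000 + s,
                          matrix(runif(25 * m$n_features, 0, 3.3), 25))
    expect_identical(svm_predict(x, m),
                     apply(x, 1, naive_ovo_predict, model = m))
  }
})

test_that("packed models reproduce the solver's own predictions", {
  fx <- trained_fixture("COMPLETE", noise_sd = 0.4)
  tr <- fx$training
  x <- as.matrix(tr[setdiff(names(tr), "label")])
  ids <- gesture_id(tr$label)
  ord <- order(ids)
  y <- factor(ids[ord], levels = sort(unique(ids)))
  fit <- e1071::svm(x[ord, ], y, scale = FALSE, kernel = "radial",
                    gamma = 1 / ncol(x), cost = 1)
  ref <- gesture_name(as.integer(as.character(predict(fit, x))))
  expect_identical(svm_predict(x, fx$model), ref)
})

test_that("separable clouds train to full agreement; REDUCED drops a class", {
  jit <- withr::with_seed(2, rnorm(40, sd = 0.1))
  two <- data.frame(ch1 = rep(c(0, 3), each = 20) + jit,
                    ch2 = rep(c(0, 3), each = 20),
                    label = rep(c("POWER_GRASP", "POINT_INDEX"), each = 20))
  m <- train_model(two)
  expect_equal(svm_predict(as.matrix(two[1:2]), m), two$label)

  red <- trained_fixture("REDUCED")$model
  expect_equal(red$n_classes, 3)
  expect_false(0L %in% red$class_ids)

  one <- two[two$label == "POWER_GRASP", ]
  expect_error(train_model(one), "two classes")
  expect_error(train_model(data.frame(ch1 = 1:4, ch2 = 1:4,
                                      label = rep(c("OPEN_HAND",
                                                    "POWER_GRASP"), 2)),
               mode = "REDUCED"), "REDUCED")
})

test_that("the flash footprint follows the closed form and is monotone", {
  expect_equal(model_footprint_bytes(ns = 116, nf = 10, ncl = 4),
               20 + 4 * (116 * 10 + 116 * 3 + 6) + 4 * 4)
  expect_lte(model_footprint_bytes(ns = 404, nf = 4, ncl = 4), 12 * 1024)
  expect_equal(model_footprint_bytes(ns = 0, nf = 4, ncl = 4), 20 + 16)
  grid <- expand.grid(ns = c(10, 50, 200), nf = c(2, 4, 10))
  fp <- with(grid, mapply(function(a, b)
    model_footprint_bytes(ns = a, nf = b, ncl = 4), ns, nf))
  expect_true(all(diff(fp[c(1, 2, 3)]) > 0))  # grows with NS
  expect_true(all(fp[c(4, 7)] > fp[1]))       # grows with NF
  m <- trained_fixture()$model
  expect_equal(model_footprint_bytes(m), length(serialize_model(m)))
  expect_error(model_footprint_bytes(ns = 1, nf = 1, ncl = 2,
                                     dtype_size = 2), "dtype_size")
})

test_that("serialization round-trips field-for-field", {
  for (mode in c("COMPLETE", "REDUCED")) {
    m <- trained_fixture(mode)$model
    bytes <- serialize_model(m)
    expect_identical(deserialize_model(bytes), m)
    expect_equal(length(bytes), model_footprint_bytes(m, 4))
  }
  m <- trained_fixture()$model
  bytes <- serialize_model(m)
  bad <- bytes; bad[1] <- as.raw(0)
  expect_error(deserialize_model(bad), "magic")
  expect_error(deserialize_model(bytes[1:40]), "section")
  path <- withr::local_tempfile(fileext = ".emgsvm")
  write_model(m, path)
  expect_identical(read_model(path), m)
})

test_that("cross-validated accuracy is perfect without noise and decays with it", {
  p0 <- noiseless_profiles()
  tr0 <- gen_training_set(p0, reps_per_gesture = 2, seed = 3, stride = 40)
  expect_equal(cross_val_accuracy(tr0, k = 3, seed = 1), 100)
  accs <- vapply(c(0.4, 1.2), function(sd) {
    tr <- gen_training_set(default_profiles(noise_sd = sd), 2, seed = 3,
                           stride = 40)
    cross_val_accuracy(tr, k = 3, seed = 1)
  }, 1.0)
  expect_lt(accs[2], 100)
  expect_lte(accs[2], accs[1] + 2)  # degrades (on average) as noise grows
})
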
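test_that("frame acquisition averages 16 ADC samples per channel", {
  cfg <- controller_config()
  raw <- matrix(2, 16, 4)
  expect_equal(acquire_frame(raw, cfg), c(2, 2, 2, 2),
               ignore_attr = TRUE)
  ladder <- matrix(c(1:16, rep(0, 48)), 16, 4)
  expect_equal(acquire_frame(ladder, cfg)[1], 8.5, ignore_attr = TRUE)
  shuffled <- ladder[withr::with_seed(1, sample(16)), ]
  expect_equal(acquire_frame(shuffled, cfg), acquire_frame(ladder, cfg))
  expect_error(acquire_frame(matrix(0, 8, 4), cfg), "16 samples")
})

test_that("spike removal rejects bursts under 100 ms and triggers at 100 ms", {
  cfg <- controller_config()
  st <- controller_state(cfg)
  hot <- rep(1, 4); cold <- rep(0.05, 4)

  # 40 supra-threshold frames (80 ms) then a drop: back to IDLE
  for (i in 1:40) st <- spike_filter_step(st, hot, cfg)
  expect_equal(st$node, "ONSET_CHECK")
  expect_equal(st$above_threshold_frames, 40L)
  st <- spike_filter_step(st, cold, cfg)
  expect_equal(st$node, "IDLE")
  expect_equal(st$above_threshold_frames, 0L)

  # 50 supra-threshold frames (100 ms, boundary inclusive): voting starts
  st <- controller_state(cfg)
  for (i in 1:49) st <- spike_filter_step(st, hot, cfg)
  expect_equal(st$node, "ONSET_CHECK")
  st <- spike_filter_step(st, hot, cfg)
  expect_equal(st$node, "VOTING")

  # an all-baseline stream never leaves IDLE
  st <- controller_state(cfg)
  for (i in 1:200) st <- spike_filter_step(st, cold, cfg)
  expect_equal(st$node, "IDLE")
})

test_that("majority voting picks the plurality with lowest-id ties", {
  expect_equal(majority_vote(rep("POWER_GRASP", 20)), "POWER_GRASP")
  expect_equal(majority_vote(c(rep("POINT_INDEX", 11),
                               rep("POWER_GRASP", 9))), "POINT_INDEX")
  expect_equal(majority_vote(c(rep("POWER_GRASP", 10),
                               rep("POINT_INDEX", 10))), "POWER_GRASP")
  expect_error(majority_vote(character(0)), "empty")
})

test_that("voting steps fill the buffer and resolve at the window size", {
  fx <- trained_fixture("COMPLETE", noise_sd = 0)
  st <- controller_state(fx$config)
  st$node <- "VOTING"
  frame <- fx$profiles$POWER_GRASP$mean_activation
  for (i in 1:19) {
    st <- voting_step(st, frame, fx$model, fx$config)
    expect_lte(length(st$vote_buffer), fx$config$vote_window)
  }
  expect_equal(st$node, "VOTING")
  st <- voting_step(st, frame, fx$model, fx$config)
  expect_equal(st$decision, "POWER_GRASP")
  expect_equal(st$node, "ACTUATING")
  expect_length(st$vote_buffer, 0)
})

test_that("actuation drives the documented finger sets with stall stop", {
  h <- hand_sim()
  prec <- actuate(h, "PRECISION_GRASP")
  expect_equal(unname(prec$hand$position), c(1, 1, 0, 0, 0))
  expect_true(all(prec$hand$current > prec$hand$stall_threshold))

  point <- actuate(h, "POINT_INDEX")
  expect_equal(unname(point$hand$position), c(1, 0, 1, 1, 1))

  open <- actuate(prec$hand, "OPEN_HAND")
  expect_equal(unname(open$hand$position), rep(0, 5))

  grasp <- actuate(hand_sim(object_width = 0.6), "POWER_GRASP")
  expect_equal(unname(grasp$hand$position), rep(0.6, 5))
  expect_true(all(grasp$hand$current > grasp$hand$stall_threshold))

  expect_error(actuate(prec$hand, "POWER_GRASP"), "open")
})

test_that("a noiseless session is executed movement for movement", {
  p <- noiseless_profiles()
  fx <- trained_fixture("COMPLETE", noise_sd = 0)
  sess <- gen_session(p, reps = 2, seed = 11)
  run <- run_controller(sess$stream, fx$model, fx$config)
  expect_identical(run$executed$gesture, sess$intended)
  expect_identical(run$attempts, sess$intended)

  # decision latency: exactly vote_window frames = 40 ms from voting start
  ev <- run$events
  starts <- ev$t_ms[ev$event == "voting_start"]
  decisions <- ev$t_ms[ev$event == "decision"]
  expect_equal(decisions - starts, rep(40, length(starts)))
})

test_that("executed gestures strictly alternate with resets", {
  fx <- trained_fixture("COMPLETE", noise_sd = 0.15)
  sess <- gen_session(fx$profiles, reps = 3, seed = 21)
  run <- run_controller(sess$stream, fx$model, fx$config)
  g <- run$executed$gesture
  non_open <- g != "OPEN_HAND"
  # no two non-open executions without an OPEN between them
  expect_false(any(non_open[-1] & non_open[-length(g)]))
})

test_that("sub-100 ms spikes never change the executed sequence", {
  p <- noiseless_profiles()
  fx <- trained_fixture("COMPLETE", noise_sd = 0)
  sess <- gen_session(p, reps = 1, seed = 31)
  clean <- run_controller(sess$stream, fx$model, fx$config)
  # rest midpoints: 3 s contraction + 3 s rest per movement
  rest_mid <- (seq_along(sess$intended) - 1) * 6000 + 4300
  for (w in c(20, 60, 98)) {
    spiked <- sess$stream
    for (at in rest_mid)
      spiked <- inject_spike(spiked, at, w, amplitude = 1.5)
    run <- run_controller(spiked, fx$model, fx$config)
    expect_identical(run$executed$gesture, clean$executed$gesture)
  }
  # an isolated 80 ms spike on pure rest produces no movement at all
  rest <- gen_rest(5000, noise_sd = 0, seed = 1)
  spiked <- inject_spike(rest, 2000, 80, amplitude = 1.5)
  run <- run_controller(spiked, fx$model, fx$config)
  expect_equal(nrow(run$executed), 0)
})

test_that("a held grasp survives relaxation indefinitely", {
  p <- noiseless_profiles()
  fx <- trained_fixture("COMPLETE", noise_sd = 0)
  stream <- concat_streams(
    gen_contraction(p$POWER_GRASP, 3000, seed = 1),
    gen_rest(20000, noise_sd = 0, seed = 2))
  run <- run_controller(stream, fx$model, fx$config)
  expect_identical(run$executed$gesture, "POWER_GRASP")
  expect_equal(utils::tail(run$trace$output_code, 1),
               gesture_code("POWER_GRASP"))
  # holding needs no supra-threshold signal: the trace ends in HOLDING
  expect_equal(utils::tail(run$trace$node, 1), "HOLDING")
})

test_that("COMPLETE and REDUCED execute identical noiseless sequences", {
  p <- noiseless_profiles()
  sess <- gen_session(p, reps = 2, seed = 41)
  out <- lapply(c("COMPLETE", "REDUCED"), function(mode) {
    fx <- trained_fixture(mode, noise_sd = 0)
    run_controller(sess$stream, fx$model, fx$config)$executed$gesture
  })
  expect_identical(out[[1]], out[[2]])
  expect_identical(out[[1]], sess$intended)
})

test_that("mode and model class sets must agree", {
  fxc <- trained_fixture("COMPLETE", noise_sd = 0)
  fxr <- trained_fixture("REDUCED", noise_sd = 0)
  sess <- gen_session(noiseless_profiles(), reps = 1, seed = 1)
  expect_error(run_controller(sess$stream, fxc$model, fxr$config), "REDUCED")
  expect_error(run_controller(sess$stream, fxr$model, fxc$config), "COMPLETE")
})
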
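# Synthetic EMG-envelope generator.
#
# Emulates the analog acquisition front-end: active sensors deliver a
# rectified, integrated envelope per channel, digitized at 500 Hz within
# 0-3.3 V. A contraction is modeled as a raised-cosine onset ramp from a
# small rest baseline to a gesture-specific steady activation vector, plus
# i.i.d. Gaussian channel noise clipped to the ADC span.

#' Gesture activation profile
#'
#' Describes how one gesture drives the electrode channels: the steady-state
#' envelope level per channel, the duration of the onset transient and the
#' additive noise scale.
#'
#' @param label Gesture name (see [gesture_set()]).
#' @param mean_activation Numeric vector of steady envelope levels (V), one
#'   per channel, within the 0-3.3 V ADC span.
#' @param rise_time_ms Onset transient duration (ms), raised-cosine shaped.
#' @param noise_sd Additive Gaussian noise standard deviation (V).
#' @param baseline Rest envelope level (V).
#' @return An object of class `gesture_profile`.
#' @examples
#' gesture_profile("POWER_GRASP", c(2.0, 1.8, 0.5, 0.6))
#' @export
gesture_profile <- function(label, mean_activation, rise_time_ms = 200,
                            noise_sd = 0.15, baseline = 0.05) {
  gesture_id(label)  # validates
  mean_activation <- as.numeric(mean_activation)
  if (any(mean_activation < ADC_SPAN_V[1] | mean_activation > ADC_SPAN_V[2]))
    stop("mean_activation must lie within the ADC span [0, 3.3] V")
  if (rise_time_ms < 0 || noise_sd < 0 || baseline < 0)
    stop("rise_time_ms, noise_sd and baseline must be non-negative")
  structure(list(label = label, mean_activation = mean_activation,
                 rise_time_ms = rise_time_ms, noise_sd = noise_sd,
                 baseline = baseline),
            class = "gesture_profile")
}

#' Default healthy-subject gesture profiles
#'
#' Four-channel activation patterns loosely shaped after the muscles the
#' electrodes target (wrist/finger flexors on channels 1-2, extensors on
#' channels 3-4): opening drives the extensors, the power grasp the flexors,
#' pointing and the precision grasp mixed intermediate patterns. The
#' patterns are distinct and well separated at the default noise level
#' (`noise_sd` 0.15 V), the package's stand-in for a healthy subject;
#' raising `noise_sd` emulates the more confused activation patterns of a
#' compromised forearm.
#'
#' @param noise_sd Additive noise sd (V) applied to every profile.
#' @param rise_time_ms Onset transient duration (ms).
#' @param baseline Rest envelope level (V).
#' @return Named list of four [gesture_profile()] objects.
#' @examples
#' names(default_profiles())
#' @export
default_profiles <- function(noise_sd = 0.15, rise_time_ms = 200,
                             baseline = 0.05) {
  act <- list(
    OPEN_HAND       = c(0.30, 0.40, 1.80, 1.50),
    POWER_GRASP     = c(2.00, 1.80, 0.50, 0.60),
    POINT_INDEX     = c(0.80, 1.50, 1.20, 0.40),
    PRECISION_GRASP = c(1.40, 0.60, 0.90, 1.20))
  lapply(stats::setNames(names(act), names(act)), function(g)
    gesture_profile(g, act[[g]], rise_time_ms = rise_time_ms,
                    noise_sd = noise_sd, baseline = baseline))
}

frames_for <- function(duration_ms) {
  if (!is.numeric(duration_ms) || length(duration_ms) != 1 || duration_ms <= 0)
    stop("duration_ms must be a single positive number")
  as.integer(round(duration_ms / FRAME_MS))
}

#' Generate one muscular contraction
#'
#' Channels ramp from the rest baseline to the profile's steady activation
#' over `rise_time_ms` (raised-cosine), then hold; zero-mean Gaussian noise
#' is added throughout and the result is clipped to the ADC span. Every
#' frame is labeled with the profile's gesture. Deterministic given `seed`.
#'
#' @param profile A [gesture_profile()].
#' @param duration_ms Contraction duration (ms); the experimental protocol
#'   uses 3000 ms.
#' @param seed Integer seed; all randomness in the generator flows through
#'   per-call seeds, global RNG state is untouched.
#' @return A labeled [emg_stream()].
#' @examples
#' s <- gen_contraction(default_profiles()$POWER_GRASP, 3000, seed = 1)
#' n_frames(s)  # 1500 frames at 500 Hz
#' @export
gen_contraction <- function(profile, duration_ms = 3000, seed = 1) {
  stopifnot(inherits(profile, "gesture_profile"))
  n <- frames_for(duration_ms)
  t_ms <- (seq_len(n) - 1) * FRAME_MS
  nf <- length(profile$mean_activation)
  frac <- if (profile$rise_time_ms <= 0) rep(1, n) else
    ifelse(t_ms >= profile$rise_time_ms, 1,
           0.5 * (1 - cos(pi * t_ms / profile$rise_time_ms)))
  ch <- outer(frac, profile$mean_activation - profile$baseline) + profile$baseline
  if (profile$noise_sd > 0)
    ch <- ch + withr::with_seed(seed,
      matrix(stats::rnorm(n * nf, 0, profile$noise_sd), n, nf))
  emg_stream(t_ms, clip_span(ch), rep(profile$label, n))
}

#' Generate a rest interval
#'
#' All channels sit at the rest baseline with additive Gaussian noise,
#' clipped to the ADC span; frames are labeled `REST`.
#'
#' @inheritParams gen_contraction
#' @param noise_sd Noise sd (V).
#' @param baseline Rest envelope level (V).
#' @param nf Number of channels.
#' @return A labeled [emg_stream()].
#' @export
gen_rest <- function(duration_ms = 3000, noise_sd = 0.15, seed = 1,
                     baseline = 0.05, nf = 4) {
  n <- frames_for(duration_ms)
  ch <- matrix(baseline, n, nf)
  if (noise_sd > 0)
    ch <- ch + withr::with_seed(seed,
      matrix(stats::rnorm(n * nf, 0, noise_sd), n, nf))
  emg_stream((seq_len(n) - 1) * FRAME_MS, clip_span(ch), rep(REST, n))
}

#' Superimpose a short spurious spike on a stream
#'
#' Emulates a movement artifact: a supra-threshold burst of the given width
#' added to all channels. Labels are unchanged — spikes are not gestures,
#' and the controller's spike-removal stage is expected to reject bursts
#' shorter than 100 ms.
#'
#' @param stream An [emg_stream()].
#' @param at_ms Spike onset time (ms) relative to the stream start.
#' @param width_ms Spike width (ms); the burst covers frames with
#'   `at_ms <= t < at_ms + width_ms`.
#' @param amplitude Added voltage (V); 0 leaves the stream unchanged.
#' @param seed Seed for the (small) amplitude jitter.
#' @param jitter_sd Per-frame amplitude jitter sd (V).
#' @return A modified copy of `stream`.
#' @export
inject_spike <- function(stream, at_ms, width_ms, amplitude = 1.5,
                         seed = 1, jitter_sd = 0) {
  stopifnot(inherits(stream, "emg_stream"))
  if (width_ms <= 0) stop("width_ms must be positive")
  t0 <- stream$t_ms[1]
  tend <- stream$t_ms[n_frames(stream)]
  if (at_ms < t0 || at_ms + width_ms > tend + FRAME_MS)
    stop("spike interval lies outside the stream")
  idx <- which(stream$t_ms >= at_ms & stream$t_ms < at_ms + width_ms)
  ch <- stream$channels
  add <- rep(amplitude, length(idx))
  if (jitter_sd > 0)
    add <- add + withr::with_seed(seed, stats::rnorm(length(idx), 0, jitter_sd))
  ch[idx, ] <- clip_span(ch[idx, , drop = FALSE] + add)
  emg_stream(stream$t_ms, ch, stream$labels)
}

#' Generate an interleaved gesture session
#'
#' Follows the evaluation protocol: for each repetition of each non-open
#' gesture, a 3 s contraction followed by 3 s of rest, then a 3 s open-hand
#' contraction followed by 3 s of rest — the open hand being the mechanical
#' reset interleaved between movements. With 10 repetitions of 3 gestures
#' this yields 60 consecutive movements.
#'
#' @param profiles Named list of [gesture_profile()]s; must contain
#'   `OPEN_HAND` and at least one other gesture.
#' @param reps Repetitions per non-open gesture.
#' @param contraction_ms,rest_ms Segment durations (ms).
#' @param seed Integer seed.
#' @return A list with `stream` (labeled [emg_stream()]) and `intended`
#'   (character vector of every movement in order, opens included).
#' @examples
#' s <- gen_session(default_profiles(noise_sd = 0), reps = 1, seed = 1)
#' s$intended
#' @export
gen_session <- function(profiles, reps = 10, contraction_ms = 3000,
                        rest_ms = 3000, seed = 1) {
  if (!length(profiles)) stop("profiles must not be empty")
  if (!"OPEN_HAND" %in% names(profiles))
    stop("profiles must include OPEN_HAND for the interleaved resets")
  if (reps < 1) stop("reps must be >= 1")
  gestures <- setdiff(names(profiles), "OPEN_HAND")
  if (!length(gestures)) stop("profiles must include at least one non-open gesture")
  noise_sd <- profiles[[1]]$noise_sd
  baseline <- profiles[[1]]$baseline
  nf <- length(profiles[[1]]$mean_activation)
  parts <- list(); intended <- character(0); k <- 0L
  for (r in seq_len(reps)) {
    for (g in gestures) {
      for (mv in c(g, "OPEN_HAND")) {
        k <- k + 1L
        parts[[length(parts) + 1L]] <-
          gen_contraction(profiles[[mv]], contraction_ms, seed = seed * 13L + k)
        parts[[length(parts) + 1L]] <-
          gen_rest(rest_ms, noise_sd = noise_sd, baseline = baseline,
                   nf = nf, seed = seed * 13L + 100000L + k)
        intended <- c(intended, mv)
      }
    }
  }
  list(stream = concat_streams(parts), intended = intended)
}

#' Generate a labeled training set of steady-state frames
#'
#' Emits plateau frames (onset transient excluded) from repeated
#' contractions of each gesture, decimated by `stride` to thin out the
#' strongly autocorrelated 500 Hz envelope samples. REST frames are never
#' included; in `REDUCED` mode the open-hand gesture is omitted from the
#' set, since the control strategy can reach the reset position from any
#' contraction without classifying it.
#'
#' @param profiles Named list of [gesture_profile()]s.
#' @param reps_per_gesture Contractions per gesture.
#' @param mode `"COMPLETE"` (all four gestures) or `"REDUCED"` (open hand
#'   excluded).
#' @param seed Integer seed.
#' @param contraction_ms Duration of each contraction (ms).
#' @param stride Keep every `stride`-th plateau frame.
#' @return A data frame with channel columns `ch1..chN` and a `label`
#'   column, plus attribute `nf`.
#' @examples
#' tr <- gen_training_set(default_profiles(), reps_per_gesture = 2,
#'                        mode = "REDUCED", seed = 1)
#' table(tr$label)
#' @export
gen_training_set <- function(profiles, reps_per_gesture = 4,
                             mode = c("COMPLETE", "REDUCED"), seed = 1,
                             contraction_ms = 3000, stride = 20) {
  mode <- match.arg(mode)
  if (reps_per_gesture < 1) stop("reps_per_gesture must be >= 1")
  use <- if (mode == "REDUCED") setdiff(names(profiles), "OPEN_HAND")
         else names(profiles)
  if (!length(use)) stop("no gestures left to train on")
  rows <- list(); k <- 0L
  for (g in use) {
    p <- profiles[[g]]
    settle_ms <- p$rise_time_ms + 100  # skip the transient plus a margin
    for (r in seq_len(reps_per_gesture)) {
      k <- k + 1L
      s <- gen_contraction(p, contraction_ms, seed = seed * 31L + k)
      keep <- which(s$t_ms >= settle_ms)
      keep <- keep[seq(1, length(keep), by = stride)]
      rows[[length(rows) + 1L]] <-
        data.frame(s$channels[keep, , drop = FALSE], label = g,
                   check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "nf") <- ncol(out) - 1L
  out
}
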
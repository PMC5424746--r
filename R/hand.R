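# Simulated poliarticulated hand with motor current feedback.
#
# Each finger is driven by its own DC motor; a finger's movement completes
# when it is fully open, fully closed, or blocked by a grasped object, at
# which point the motor current rises past a stall threshold and the drive
# is cut. Only that threshold-stop contract is modeled; the current curve
# itself is a simple baseline/stall two-level stand-in.

FINGERS <- c("thumb", "index", "middle", "ring", "little")

#' Construct a simulated prosthetic hand
#'
#' @param stall_threshold Motor current (A) above which a finger's drive is
#'   cut (end-stop or object block).
#' @param speed Finger travel speed in full-range units per second; full
#'   travel (0 = open to 1 = closed) takes `1 / speed` seconds.
#' @param baseline_current Running motor current (A).
#' @param stall_current Current (A) reached when a finger halts; must
#'   exceed `stall_threshold`.
#' @param object_width Optional closing position in (0, 1) at which fingers
#'   are blocked by a grasped object (`NULL` for free motion).
#' @return An object of class `hand_sim` with per-finger `position`
#'   (0 open, 1 closed) and `current` (A).
#' @examples
#' h <- hand_sim(object_width = 0.6)
#' actuate(h, "POWER_GRASP")$hand$position
#' @export
hand_sim <- function(stall_threshold = 0.5, speed = 2,
                     baseline_current = 0.08, stall_current = 0.9,
                     object_width = NULL) {
  if (stall_current <= stall_threshold)
    stop("stall_current must exceed stall_threshold")
  if (!is.null(object_width) &&
      (object_width <= 0 || object_width >= 1))
    stop("object_width must lie in (0, 1)")
  structure(list(
    position = stats::setNames(rep(0, 5), FINGERS),
    current = stats::setNames(rep(0, 5), FINGERS),
    stall_threshold = stall_threshold,
    speed = speed,
    baseline_current = baseline_current,
    stall_current = stall_current,
    object_width = object_width
  ), class = "hand_sim")
}

#' @export
print.hand_sim <- function(x, ...) {
  cat("<hand_sim> positions:",
      paste(sprintf("%s=%.2f", FINGERS, x$position), collapse = " "), "\n")
  invisible(x)
}

hand_is_open <- function(hand) all(hand$position < 1e-9)

gesture_targets <- function(gesture) {
  switch(gesture,
    OPEN_HAND       = stats::setNames(rep(0, 5), FINGERS),
    POWER_GRASP     = stats::setNames(rep(1, 5), FINGERS),
    PRECISION_GRASP = stats::setNames(c(1, 1, 0, 0, 0), FINGERS),
    POINT_INDEX     = stats::setNames(c(1, 0, 1, 1, 1), FINGERS),
    stop("unknown gesture: ", gesture))
}

#' Actuate a gesture on the simulated hand
#'
#' Drives the gesture's finger set until every commanded finger stalls:
#' fully closed, fully open, or blocked at the object width. In the power
#' grasp all fingers close; in the precision grasp only thumb and index
#' close; pointing closes everything except the (extended) index. Any
#' non-open gesture must start from the open (reset) position — the FSM
#' enforces this mechanically-motivated constraint.
#'
#' @param hand A [hand_sim()].
#' @param gesture Gesture name.
#' @return A list: `hand` (updated [hand_sim()], stalled fingers carrying
#'   supra-threshold current), `duration_ms` (motor run time until the last
#'   finger stalls).
#' @export
actuate <- function(hand, gesture) {
  stopifnot(inherits(hand, "hand_sim"))
  target <- gesture_targets(gesture)
  if (gesture != "OPEN_HAND" && !hand_is_open(hand))
    stop("non-open gestures can only be actuated from the open (reset) position")
  if (!is.null(hand$object_width)) {
    closing <- target > hand$position
    target[closing] <- pmin(target[closing], hand$object_width)
  }
  travel <- abs(target - hand$position)
  duration_ms <- max(travel) / hand$speed * 1000
  hand$position <- target
  # every commanded finger has halted (end-stop or block): current spikes
  # past the stall threshold and the drive is cut
  hand$current <- stats::setNames(rep(hand$stall_current, 5), FINGERS)
  list(hand = hand, duration_ms = duration_ms)
}
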
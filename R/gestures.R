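# Gesture vocabulary shared by every module.
#
# Four gesture identities exist; OPEN_HAND doubles as the mechanical reset
# position. REST is a non-gesture stream annotation, never a class.

.gesture_table <- data.frame(
  id   = c(0L, 1L, 2L, 3L),
  name = c("OPEN_HAND", "POWER_GRASP", "POINT_INDEX", "PRECISION_GRASP"),
  code = c(-1L, 1L, 2L, 3L),
  stringsAsFactors = FALSE
)

#' Gesture vocabulary
#'
#' The controller recognizes four hand gestures: open hand, power grasp
#' (closed hand), point index and precision grasp. `OPEN_HAND` additionally
#' serves as the reset position every other gesture must start from. The
#' `code` column gives the controller's output encoding: positive integers
#' for gestures, -1 reserved for the reset (open hand) position.
#'
#' @return A data frame with columns `id` (stable small-integer identity),
#'   `name` and `code` (controller trace output code).
#' @examples
#' gesture_set()
#' @export
gesture_set <- function() .gesture_table

#' @rdname gesture_set
#' @export
REST <- "REST"

gesture_names <- function() .gesture_table$name

#' Map between gesture names, ids and output codes
#'
#' @param name Gesture name (one of `gesture_set()$name`).
#' @param id Gesture id.
#' @return `gesture_id()` returns the integer id for a name; `gesture_name()`
#'   the name for an id; `gesture_code()` the controller output code for a
#'   name.
#' @examples
#' gesture_id("POWER_GRASP")
#' gesture_code("OPEN_HAND")
#' @export
gesture_id <- function(name) {
  i <- match(name, .gesture_table$name)
  if (anyNA(i)) stop("unknown gesture name: ", paste(name[is.na(i)], collapse = ", "))
  .gesture_table$id[i]
}

#' @rdname gesture_id
#' @export
gesture_name <- function(id) {
  i <- match(id, .gesture_table$id)
  if (anyNA(i)) stop("unknown gesture id: ", paste(id[is.na(i)], collapse = ", "))
  .gesture_table$name[i]
}

#' @rdname gesture_id
#' @export
gesture_code <- function(name) {
  i <- match(name, .gesture_table$name)
  if (anyNA(i)) stop("unknown gesture name: ", paste(name[is.na(i)], collapse = ", "))
  .gesture_table$code[i]
}
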
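# EMG envelope streams: time-ordered multi-channel frames at a fixed rate.

#' Sampling rate of the acquisition front-end (Hz)
#' @export
EMG_SAMPLE_RATE_HZ <- 500

#' ADC voltage span (V)
#' @export
ADC_SPAN_V <- c(0, 3.3)

FRAME_MS <- 1000 / EMG_SAMPLE_RATE_HZ  # 2 ms between consecutive frames

#' Construct an EMG envelope stream
#'
#' An `emg_stream` is a sequence of envelope frames sampled at 500 Hz: a
#' time vector (ms, consecutive frames 2 ms apart), an n x NF channel matrix
#' of voltages within the 0-3.3 V ADC span, and an optional per-frame label
#' (a gesture name or `REST`).
#'
#' @param t_ms Numeric vector of frame times in milliseconds.
#' @param channels Numeric matrix, one row per frame, one column per channel.
#' @param labels Optional character vector of per-frame annotations
#'   (gesture names or `REST`); must match the number of frames.
#' @return An object of class `emg_stream`.
#' @examples
#' s <- emg_stream(c(0, 2), matrix(0.05, 2, 4), c(REST, REST))
#' n_frames(s)
#' @export
emg_stream <- function(t_ms, channels, labels = NULL) {
  channels <- as.matrix(channels)
  if (length(t_ms) != nrow(channels))
    stop("t_ms length must equal the number of frame rows")
  if (!is.null(labels) && length(labels) != nrow(channels))
    stop("labels, if present, must have one entry per frame")
  if (is.null(colnames(channels)))
    colnames(channels) <- paste0("ch", seq_len(ncol(channels)))
  structure(list(t_ms = as.numeric(t_ms), channels = channels,
                 labels = if (is.null(labels)) NULL else as.character(labels)),
            class = "emg_stream")
}

#' @rdname emg_stream
#' @param x An `emg_stream`.
#' @export
n_frames <- function(x) length(x$t_ms)

#' @rdname emg_stream
#' @export
n_channels <- function(x) ncol(x$channels)

#' @export
print.emg_stream <- function(x, ...) {
  dur <- if (n_frames(x)) diff(range(x$t_ms)) + FRAME_MS else 0
  cat(sprintf("<emg_stream> %d frames x %d channels (%.0f ms at %d Hz)%s\n",
              n_frames(x), n_channels(x), dur, EMG_SAMPLE_RATE_HZ,
              if (is.null(x$labels)) "" else ", labeled"))
  if (!is.null(x$labels)) {
    r <- rle(x$labels)
    cat("  segments:", paste(sprintf("%s(%d)", r$values, r$lengths),
                             collapse = " "), "\n")
  }
  invisible(x)
}

#' Concatenate streams in time
#'
#' Frames of later streams are re-timed to continue 2 ms after the end of
#' the previous one.
#'
#' @param ... `emg_stream` objects with identical channel counts.
#' @return A single `emg_stream`; labels are kept only if every input has
#'   them.
#' @export
concat_streams <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "emg_stream")) parts <- parts[[1]]
  stopifnot(length(parts) >= 1)
  nf <- n_channels(parts[[1]])
  if (!all(vapply(parts, n_channels, 1L) == nf))
    stop("all streams must have the same channel count")
  keep_labels <- all(vapply(parts, function(p) !is.null(p$labels), TRUE))
  t0 <- 0
  ts <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    ts[[i]] <- t0 + parts[[i]]$t_ms - parts[[i]]$t_ms[1]
    t0 <- ts[[i]][length(ts[[i]])] + FRAME_MS
  }
  emg_stream(unlist(ts),
             do.call(rbind, lapply(parts, `[[`, "channels")),
             if (keep_labels) unlist(lapply(parts, `[[`, "labels")) else NULL)
}

#' Read and write EMG session CSV files
#'
#' The session dialect is a plain CSV with header `t_ms,ch1..chN,label`;
#' the label column holds gesture names or `REST`. The round trip is
#' lossless to at least 6 significant digits.
#'
#' @param stream An `emg_stream` (labels required for writing; unlabeled
#'   streams are written with `REST`).
#' @param path File path.
#' @return `read_session_csv()` returns an `emg_stream`;
#'   `write_session_csv()` returns `path` invisibly.
#' @export
write_session_csv <- function(stream, path) {
  labels <- if (is.null(stream$labels)) rep(REST, n_frames(stream)) else stream$labels
  df <- data.frame(t_ms = stream$t_ms, stream$channels, label = labels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path)
  nfield <- utils::count.fields(path, sep = ",", quote = "")
  if (length(nfield) < 2) stop("session CSV has no data rows: ", path)
  bad <- which(nfield != nfield[1])
  if (length(bad))
    stop(sprintf("malformed session CSV at line %d: expected %d fields, found %d",
                 bad[1], nfield[1], nfield[bad[1]]))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("t_ms", "label")
  if (!all(need %in% names(df)))
    stop("session CSV must have columns t_ms, ch1..chN, label")
  chcols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  if (!length(chcols)) stop("session CSV has no channel columns (ch1..chN)")
  chcols <- chcols[order(as.integer(sub("ch", "", chcols)))]
  bad_lab <- setdiff(unique(df$label), c(gesture_names(), REST))
  if (length(bad_lab))
    stop("unknown labels in session CSV: ", paste(bad_lab, collapse = ", "))
  emg_stream(df$t_ms, as.matrix(df[chcols]), df$label)
}

clip_span <- function(x) pmin(pmax(x, ADC_SPAN_V[1]), ADC_SPAN_V[2])
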
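# Packed SVM model: the in-memory mirror of the flash image stored on the
# wearable node. All real-valued fields are quantized to IEEE-754 single
# precision at construction, so the object is bit-identical to what a
# serialize/deserialize round trip or a packet-level transfer reproduces.

MODEL_MAGIC <- charToRaw("ESVM")
HEADER_BYTES <- 20L
INT_SIZE <- 4L

# quantize doubles to the nearest float32 value
float32 <- function(x) {
  if (!length(x)) return(numeric(0))
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
                 "numeric", n = length(x), size = 4L, endian = "little")
  if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  out
}

#' Construct a packed one-vs-one SVM model
#'
#' The model mirrors the static flash layout of the embedded classifier:
#' support vectors are stored contiguously, grouped by class, together with
#' pre-computed coefficients `C_i = y_i * alpha_i` arranged as an
#' `NS x (NCl - 1)` matrix in the per-class-column convention (for the
#' binary problem between classes j < k, class j's block reads column
#' `k - 1` and class k's block reads column `j`), one offset `rho` per
#' class pair in order (1,2), (1,3), ..., and the RBF kernel parameter
#' `gamma` (`exp(-gamma * ||x - s||^2)`, i.e. `gamma = 1 / (2 sigma^2)`).
#' All real values are quantized to single precision.
#'
#' @param gamma Positive RBF kernel parameter.
#' @param class_ids Integer gesture ids, in stored (ascending) class order.
#' @param sv_counts Support vectors per class, same order as `class_ids`.
#' @param support_vectors `NS x NF` matrix, rows grouped by class.
#' @param coefficients `NS x (NCl - 1)` dual-coefficient matrix.
#' @param rho Numeric vector of `NCl (NCl - 1) / 2` pair offsets.
#' @return An object of class `emg_svm_model`.
#' @seealso [train_model()], [serialize_model()], [model_footprint_bytes()]
#' @export
emg_svm_model <- function(gamma, class_ids, sv_counts, support_vectors,
                          coefficients, rho) {
  support_vectors <- as.matrix(support_vectors)
  coefficients <- as.matrix(coefficients)
  ncl <- length(class_ids)
  ns <- nrow(support_vectors)
  if (ncl < 2) stop("a model needs at least two classes")
  if (length(sv_counts) != ncl) stop("sv_counts must have one entry per class")
  if (sum(sv_counts) != ns) stop("sv_counts must sum to the number of SVs")
  if (ns < 1) stop("a model needs at least one support vector")
  if (any(sv_counts < 1)) stop("every class must contribute at least one SV")
  if (anyDuplicated(class_ids)) stop("class_ids must be distinct")
  if (ncol(coefficients) != ncl - 1 || nrow(coefficients) != ns)
    stop("coefficients must be an NS x (NCl - 1) matrix")
  if (length(rho) != ncl * (ncl - 1) / 2)
    stop("rho must have one offset per class pair")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("gamma must be a single positive number")
  dimnames(support_vectors) <- NULL
  dimnames(coefficients) <- NULL
  structure(list(
    n_features = ncol(support_vectors),
    n_classes = ncl,
    gamma = float32(gamma),
    class_ids = as.integer(class_ids),
    sv_counts = as.integer(sv_counts),
    support_vectors = float32(support_vectors),
    coefficients = float32(coefficients),
    rho = float32(as.numeric(rho))
  ), class = "emg_svm_model")
}

#' @export
print.emg_svm_model <- function(x, ...) {
  cat(sprintf("<emg_svm_model> %d classes (%s), NF=%d, NS=%d, gamma=%.6g\n",
              x$n_classes, paste(gesture_name(x$class_ids), collapse = ", "),
              x$n_features, sum(x$sv_counts), x$gamma))
  cat(sprintf("  SVs per class: %s; flash footprint: %d bytes\n",
              paste(x$sv_counts, collapse = "/"),
              model_footprint_bytes(x)))
  invisible(x)
}

n_support_vectors <- function(model) sum(model$sv_counts)

# row index ranges of each class's SV block
class_block <- function(model, i) {
  ends <- cumsum(model$sv_counts)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seq.int(starts[i], ends[i])
}

pair_index <- function(ncl, j, k) {
  # position of pair (j,k), j<k, in the (1,2),(1,3),...,(2,3),... ordering
  as.integer((j - 1) * ncl - j * (j - 1) / 2 + (k - j))
}

#' Flash memory footprint of a packed model
#'
#' The stored image is a fixed 20-byte header (format tag, feature count,
#' class count, kernel parameter, total SV count) plus a variable component
#' of `NS * NF` support-vector values, `NS * (NCl - 1)` coefficients and
#' `NCl (NCl - 1) / 2` offsets — each `dtype_size` bytes — plus
#' `NCl * 4` bytes of per-class SV bookkeeping. The degenerate `ns = 0`
#' shape occupies header and bookkeeping only.
#'
#' @param model An `emg_svm_model`, or `NULL` if the shape is given
#'   explicitly.
#' @param dtype_size Bytes per stored value: 4 (single) or 8 (double).
#' @param ns,nf,ncl Explicit shape (total SVs, features, classes) when no
#'   model object is supplied.
#' @return Integer number of bytes.
#' @examples
#' model_footprint_bytes(ns = 404, nf = 4, ncl = 4)  # fits in 12 kB of flash
#' @export
model_footprint_bytes <- function(model = NULL, dtype_size = 4,
                                  ns = NULL, nf = NULL, ncl = NULL) {
  if (!dtype_size %in% c(4, 8)) stop("dtype_size must be 4 or 8")
  if (!is.null(model)) {
    stopifnot(inherits(model, "emg_svm_model"))
    ns <- n_support_vectors(model); nf <- model$n_features; ncl <- model$n_classes
  }
  if (is.null(ns) || is.null(nf) || is.null(ncl))
    stop("supply a model or the full shape (ns, nf, ncl)")
  if (ns == 0) return(HEADER_BYTES + as.integer(ncl) * INT_SIZE)
  as.integer(HEADER_BYTES +
             dtype_size * (ns * nf + ns * (ncl - 1) + ncl * (ncl - 1) / 2) +
             ncl * INT_SIZE)
}

#' Serialize a model to its flash-image byte layout
#'
#' Layout (little-endian throughout): a 20-byte header — 4-byte magic
#' `"ESVM"`, uint32 NF, uint32 NCl, float32 gamma, uint32 NS — then the
#' per-class block (`NCl` entries of int16 gesture id + uint16 SV count),
#' the rho block, the contiguous support-vector block (row-major) and the
#' contiguous coefficient block (column-major, so each binary problem reads
#' contiguous slices). All values single-precision. The serialized length
#' equals [model_footprint_bytes()] with 4-byte values.
#'
#' @param model An `emg_svm_model`.
#' @param bytes A raw vector produced by `serialize_model()`.
#' @return `serialize_model()` returns a raw vector; `deserialize_model()`
#'   the reconstructed `emg_svm_model`.
#' @examples
#' tr <- gen_training_set(default_profiles(), 2, "REDUCED", seed = 1)
#' m <- train_model(tr, mode = "REDUCED")
#' identical(deserialize_model(serialize_model(m)), m)
#' @export
serialize_model <- function(model) {
  stopifnot(inherits(model, "emg_svm_model"))
  ns <- n_support_vectors(model)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(MODEL_MAGIC, con)
  writeBin(as.integer(c(model$n_features, model$n_classes)), con,
           size = 4L, endian = "little")
  writeBin(model$gamma, con, size = 4L, endian = "little")
  writeBin(as.integer(ns), con, size = 4L, endian = "little")
  for (i in seq_len(model$n_classes))
    writeBin(as.integer(c(model$class_ids[i], model$sv_counts[i])), con,
             size = 2L, endian = "little")
  writeBin(model$rho, con, size = 4L, endian = "little")
  writeBin(as.numeric(t(model$support_vectors)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(model$coefficients), con, size = 4L, endian = "little")
  rawConnectionValue(con)
}

#' @rdname serialize_model
#' @export
deserialize_model <- function(bytes) {
  stopifnot(is.raw(bytes))
  pos <- 0L
  take <- function(n, section) {
    if (pos + n > length(bytes))
      stop("truncated model image in section: ", section)
    out <- bytes[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  if (length(bytes) < HEADER_BYTES || !identical(bytes[1:4], MODEL_MAGIC))
    stop("bad magic in section: header (not an ESVM flash image)")
  pos <- 4L
  nf  <- readBin(take(4L, "header"), "integer", size = 4L, endian = "little")
  ncl <- readBin(take(4L, "header"), "integer", size = 4L, endian = "little")
  gamma <- readBin(take(4L, "header"), "numeric", size = 4L, endian = "little")
  ns  <- readBin(take(4L, "header"), "integer", size = 4L, endian = "little")
  if (nf < 1 || ncl < 2 || ns < 1)
    stop("implausible shape in section: header")
  cls <- readBin(take(4L * ncl, "class block"), "integer", n = 2L * ncl,
                 size = 2L, endian = "little")
  class_ids <- cls[seq(1, 2 * ncl, by = 2)]
  sv_counts <- cls[seq(2, 2 * ncl, by = 2)]
  if (sum(sv_counts) != ns)
    stop("SV counts disagree with header in section: class block")
  npair <- ncl * (ncl - 1) / 2
  rho <- readBin(take(4L * npair, "rho block"), "numeric", n = npair,
                 size = 4L, endian = "little")
  sv <- readBin(take(4L * ns * nf, "support-vector block"), "numeric",
                n = ns * nf, size = 4L, endian = "little")
  cf <- readBin(take(4L * ns * (ncl - 1), "coefficient block"), "numeric",
                n = ns * (ncl - 1), size = 4L, endian = "little")
  if (pos != length(bytes))
    stop("trailing bytes after section: coefficient block")
  emg_svm_model(gamma = gamma, class_ids = class_ids, sv_counts = sv_counts,
                support_vectors = matrix(sv, ns, nf, byrow = TRUE),
                coefficients = matrix(cf, ns, ncl - 1),
                rho = rho)
}

#' Read or write a model file (.emgsvm)
#'
#' Thin file wrappers over [serialize_model()]/[deserialize_model()].
#'
#' @param model An `emg_svm_model`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  writeBin(serialize_model(model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  deserialize_model(readBin(path, raw(), n = file.info(path)$size))
}
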
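# Gateway -> node model-transfer protocol: three packet types, a one-byte
# checksum per packet, stop-and-wait acknowledgements, and an injectable
# lossy channel for fault testing. Both endpoints live in-process; the
# binary field encodings match the flash-image serialization, so an
# assembled transfer equals a deserialized model file.

PACKET_TYPES <- c(CONFIG = 1L, MODEL_PARAMS = 2L, SV = 3L)

# one-byte two's-complement sum over type|seq|length|payload: the byte that
# makes the total sum 0 mod 256; any single-byte corruption breaks it
packet_checksum <- function(ptype_byte, seq, payload) {
  hdr <- c(ptype_byte,
           writeBin(as.integer(seq), raw(), size = 2L, endian = "little"),
           writeBin(length(payload), raw(), size = 2L, endian = "little"))
  s <- sum(as.integer(c(hdr, payload))) %% 256L
  as.raw((256L - s) %% 256L)
}

#' Build a protocol packet
#'
#' @param ptype `"CONFIG"`, `"MODEL_PARAMS"` or `"SV"`.
#' @param seq Sequence number (0-based).
#' @param payload Raw payload bytes.
#' @return An object of class `transfer_packet` with a valid checksum.
#' @export
transfer_packet <- function(ptype = names(PACKET_TYPES), seq, payload) {
  ptype <- match.arg(ptype)
  stopifnot(is.raw(payload))
  tb <- as.raw(PACKET_TYPES[[ptype]])
  structure(list(ptype = ptype, seq = as.integer(seq), payload = payload,
                 checksum = packet_checksum(tb, seq, payload)),
            class = "transfer_packet")
}

#' @rdname transfer_packet
#' @param packet A `transfer_packet`.
#' @return `verify_checksum()` returns `TRUE` when the stored checksum
#'   matches the recomputed one.
#' @export
verify_checksum <- function(packet) {
  tb <- as.raw(PACKET_TYPES[[packet$ptype]])
  identical(packet_checksum(tb, packet$seq, packet$payload), packet$checksum)
}

# wire format: type(1) seq(2) len(2) payload checksum(1), little-endian
packet_bytes <- function(packet) {
  c(as.raw(PACKET_TYPES[[packet$ptype]]),
    writeBin(packet$seq, raw(), size = 2L, endian = "little"),
    writeBin(length(packet$payload), raw(), size = 2L, endian = "little"),
    packet$payload, packet$checksum)
}

decode_packet <- function(bytes) {
  if (length(bytes) < 6L) stop("short packet")
  tcode <- as.integer(bytes[1])
  ptype <- names(PACKET_TYPES)[match(tcode, PACKET_TYPES)]
  if (is.na(ptype)) stop("unknown packet type byte: ", tcode)
  seq <- readBin(bytes[2:3], "integer", size = 2L, endian = "little",
                 signed = FALSE)
  len <- readBin(bytes[4:5], "integer", size = 2L, endian = "little",
                 signed = FALSE)
  if (length(bytes) != 6L + len) stop("packet length field disagrees with body")
  payload <- if (len) bytes[6:(5 + len)] else raw(0)
  structure(list(ptype = ptype, seq = seq, payload = payload,
                 checksum = bytes[length(bytes)]),
            class = "transfer_packet")
}

f32_bytes <- function(x) writeBin(as.numeric(x), raw(), size = 4L,
                                  endian = "little")
read_f32 <- function(bytes, n) readBin(bytes, "numeric", n = n, size = 4L,
                                       endian = "little")

#' Encode a model as a packet sequence
#'
#' Exactly `2 + NS` packets: one CONFIG packet (algorithm type byte, kernel
#' parameter, class count, feature count), one MODEL_PARAMS packet (total
#' SV count, per-class gesture ids and SV counts, the pair offsets rho),
#' and one SV packet per support vector (its feature values followed by
#' its `NCl - 1` coefficients), in storage order.
#'
#' @param model An [emg_svm_model()].
#' @return List of [transfer_packet()]s.
#' @export
encode_model <- function(model) {
  stopifnot(inherits(model, "emg_svm_model"))
  ns <- n_support_vectors(model)
  config <- c(as.raw(1L),                       # algorithm: C-SVC, RBF
              f32_bytes(model$gamma),
              as.raw(model$n_classes), as.raw(model$n_features))
  params <- c(writeBin(ns, raw(), size = 2L, endian = "little"),
              unlist(lapply(seq_len(model$n_classes), function(i)
                c(as.raw(model$class_ids[i]),
                  writeBin(model$sv_counts[i], raw(), size = 2L,
                           endian = "little")))),
              f32_bytes(model$rho))
  packets <- list(transfer_packet("CONFIG", 0L, config),
                  transfer_packet("MODEL_PARAMS", 1L, params))
  for (i in seq_len(ns)) {
    payload <- c(f32_bytes(model$support_vectors[i, ]),
                 f32_bytes(model$coefficients[i, ]))
    packets[[2L + i]] <- transfer_packet("SV", 1L + i, payload)
  }
  packets
}

#' Start a node-side transfer session
#'
#' @return An object of class `transfer_session` in state `AWAIT_CONFIG`.
#' @export
transfer_session <- function() {
  structure(list(state = "AWAIT_CONFIG", received_sv_count = 0L,
                 gamma = NULL, n_classes = NULL, n_features = NULL,
                 ns = NULL, class_ids = NULL, sv_counts = NULL, rho = NULL,
                 sv = list(), coef = list(), assembled = NULL),
            class = "transfer_session")
}

#' Node-side packet handler
#'
#' Verifies the checksum and protocol order, advances the session state and
#' answers ACK or NAK. On the final SV packet the assembled model is
#' validated and stored and the session reaches `DONE`. A retransmission of
#' the last acknowledged packet (same sequence number) is acknowledged
#' again without effect.
#'
#' @param session A [transfer_session()].
#' @param packet A [transfer_packet()].
#' @return List with `session` (updated) and `response` (`"ACK"` or
#'   `"NAK"`, the latter with a `reason` attribute).
#' @export
node_receive <- function(session, packet) {
  stopifnot(inherits(session, "transfer_session"))
  nak <- function(reason) {
    list(session = session,
         response = structure("NAK", reason = reason))
  }
  if (session$state == "FAILED") stop("session already FAILED")
  if (!inherits(packet, "transfer_packet")) return(nak("undecodable packet"))
  if (!verify_checksum(packet)) return(nak("checksum mismatch"))
  expected <- switch(session$state,
                     AWAIT_CONFIG = "CONFIG",
                     AWAIT_PARAMS = "MODEL_PARAMS",
                     AWAIT_SVS = "SV",
                     DONE = NA_character_)
  if (is.na(expected)) return(nak("transfer already complete"))
  if (packet$ptype != expected)
    return(nak(sprintf("out-of-order packet: got %s, expected %s",
                       packet$ptype, expected)))
  p <- packet$payload
  if (packet$ptype == "CONFIG") {
    if (length(p) != 7L) return(nak("malformed CONFIG payload"))
    session$gamma <- read_f32(p[2:5], 1L)
    session$n_classes <- as.integer(p[6])
    session$n_features <- as.integer(p[7])
    session$state <- "AWAIT_PARAMS"
  } else if (packet$ptype == "MODEL_PARAMS") {
    ncl <- session$n_classes
    npair <- ncl * (ncl - 1L) / 2L
    if (length(p) != 2L + 3L * ncl + 4L * npair)
      return(nak("malformed MODEL_PARAMS payload"))
    session$ns <- readBin(p[1:2], "integer", size = 2L, endian = "little",
                          signed = FALSE)
    off <- 2L
    ids <- integer(ncl); counts <- integer(ncl)
    for (i in seq_len(ncl)) {
      ids[i] <- as.integer(p[off + 1L])
      counts[i] <- readBin(p[(off + 2L):(off + 3L)], "integer", size = 2L,
                           endian = "little", signed = FALSE)
      off <- off + 3L
    }
    session$class_ids <- ids
    session$sv_counts <- counts
    session$rho <- read_f32(p[(off + 1L):length(p)], npair)
    session$state <- "AWAIT_SVS"
  } else {  # SV
    nf <- session$n_features
    ncl <- session$n_classes
    if (length(p) != 4L * (nf + ncl - 1L))
      return(nak("malformed SV payload"))
    i <- session$received_sv_count + 1L
    if (packet$seq == i) {
      # duplicate of the last acknowledged SV: ACK again, no state change
      return(list(session = session, response = "ACK"))
    }
    if (packet$seq != 1L + i)
      return(nak(sprintf("unexpected SV sequence number %d", packet$seq)))
    session$sv[[i]] <- read_f32(p[1:(4L * nf)], nf)
    session$coef[[i]] <- read_f32(p[(4L * nf + 1L):length(p)], ncl - 1L)
    session$received_sv_count <- i
    if (i == session$ns) {
      session$assembled <- emg_svm_model(
        gamma = session$gamma, class_ids = session$class_ids,
        sv_counts = session$sv_counts,
        support_vectors = do.call(rbind, session$sv),
        coefficients = do.call(rbind, session$coef),
        rho = session$rho)
      session$state <- "DONE"
    }
  }
  list(session = session, response = "ACK")
}

#' Lossy byte channel for fault injection
#'
#' Returns a channel function that passes serialized packets through,
#' corrupting one uniformly chosen byte (XOR with a random non-zero mask)
#' with probability `corrupt_prob` per delivery. The channel keeps its own
#' seeded RNG stream; global RNG state is untouched.
#'
#' @param corrupt_prob Per-delivery corruption probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A function `raw -> raw`.
#' @export
make_channel <- function(corrupt_prob = 0, seed = 1) {
  stopifnot(corrupt_prob >= 0, corrupt_prob <= 1)
  rng_state <- withr::with_seed(seed, get(".Random.seed", globalenv()))
  draw <- function(n) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", rng_state, globalenv())
    out <- stats::runif(n)
    rng_state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  function(bytes) {
    u <- draw(3L)
    if (u[1] < corrupt_prob) {
      pos <- 1L + as.integer(floor(u[2] * length(bytes)))
      mask <- 1L + as.integer(floor(u[3] * 255))
      bytes[pos] <- as.raw(bitwXor(as.integer(bytes[pos]), mask))
    }
    bytes
  }
}

#' Gateway-side model transmission
#'
#' Stop-and-wait: each packet is serialized, pushed through the channel,
#' decoded and handed to the node; the next packet is sent only after an
#' ACK, and a NAK (or an undecodable delivery) triggers a retransmission
#' of the same packet up to `retry_limit` times.
#'
#' @param model An [emg_svm_model()].
#' @param channel A channel function from [make_channel()].
#' @param retry_limit Maximum retransmissions per packet.
#' @return A transfer report: `outcome` (`"DONE"` or `"FAILED"`),
#'   `packets_sent` (deliveries, retransmissions included), `retries`,
#'   `acks`, `naks`, and on success `model` (the node's assembled model)
#'   and the final `session`.
#' @export
gateway_send <- function(model, channel = make_channel(), retry_limit = 5) {
  packets <- encode_model(model)
  session <- transfer_session()
  sent <- 0L; retries <- 0L; acks <- 0L; naks <- 0L
  for (pk in packets) {
    ok <- FALSE
    for (attempt in 0:retry_limit) {
      sent <- sent + 1L
      if (attempt > 0L) retries <- retries + 1L
      delivered <- channel(packet_bytes(pk))
      received <- tryCatch(decode_packet(delivered), error = function(e) NULL)
      if (is.null(received)) { naks <- naks + 1L; next }
      res <- node_receive(session, received)
      if (identical(as.character(res$response), "ACK")) {
        session <- res$session
        acks <- acks + 1L
        ok <- TRUE
        break
      }
      naks <- naks + 1L
    }
    if (!ok)
      return(list(outcome = "FAILED", packets_sent = sent, retries = retries,
                  acks = acks, naks = naks, failed_packet = pk$ptype,
                  model = NULL, session = session))
  }
  list(outcome = "DONE", packets_sent = sent, retries = retries, acks = acks,
       naks = naks, model = session$assembled, session = session)
}
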
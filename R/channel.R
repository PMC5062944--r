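#' Byte-counting message channel between protocol parties
#'
#' An in-process simulated channel with an append-only transcript. Every
#' protocol message is serialized (length-prefixed big-endian integers for
#' big-number payloads) and tallied per direction, mirroring how
#' communication cost is measured as network bandwidth consumption.
#' Payload bytes of small messages are retained so tests can inspect what
#' an eavesdropper would see; bulk messages keep only their byte count.
#'
#' @param retain_limit retain raw payloads up to this many bytes per
#'   message (larger messages count bytes only).
#' @return an `smc_channel`.
#' @export
channel <- function(retain_limit = 1e6) {
  env <- new.env(parent = emptyenv())
  env$transcript <- list()
  env$bytes <- numeric(0)
  env$retain_limit <- retain_limit
  structure(env, class = "smc_channel")
}

#' @exportS3Method base::print
print.smc_channel <- function(x, ...) {
  b <- channel_bytes(x)
  cat(sprintf("<smc_channel> %d message(s); bytes by sender: %s\n",
              length(x$transcript),
              paste(sprintf("%s=%d", names(b), b), collapse = ", ")))
  invisible(x)
}

# serialized size of a hex-string big integer vector:
# per element, 4-byte length prefix + ceil(nhex / 2) bytes
hex_payload_bytes <- function(h) {
  sum(4L + ceiling(nchar(h) / 2))
}

hex_to_raw <- function(h) {
  if (nchar(h) %% 2 == 1) h <- paste0("0", h)
  as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)), 16L))
}

serialize_hex_vec <- function(h) {
  parts <- lapply(h, function(x) {
    b <- hex_to_raw(x)
    c(writeBin(length(b), raw(), size = 4, endian = "big"), b)
  })
  do.call(c, parts)
}

#' Send a message over a channel
#'
#' Appends to the transcript and returns the payload (in-process
#' delivery). `x` may be a raw vector or a vector of hex-string big
#' integers, which is measured in its length-prefixed serialization.
#'
#' @param ch an [channel()].
#' @param from sender id (e.g. `"A"`, `"B"`, `"client"`, `"server"`).
#' @param x payload.
#' @param label human-readable message label.
#' @return `x`, invisibly.
#' @export
ch_send <- function(ch, from, x, label = "") {
  stopifnot(inherits(ch, "smc_channel"))
  if (is.raw(x)) {
    nbytes <- length(x)
    payload <- if (nbytes <= ch$retain_limit) x else NULL
  } else if (is.character(x)) {
    nbytes <- hex_payload_bytes(x)
    payload <- if (nbytes <= ch$retain_limit) serialize_hex_vec(x) else NULL
  } else if (is.numeric(x)) {
    nbytes <- 8L * length(x)
    payload <- writeBin(as.numeric(x), raw(), size = 8, endian = "big")
  } else {
    abort("unsupported payload type")
  }
  ch$transcript[[length(ch$transcript) + 1L]] <-
    list(sender = from, label = label, bytes = nbytes, payload = payload)
  prev <- ch$bytes[from]
  ch$bytes[from] <- (if (length(prev) == 0 || is.na(prev)) 0 else prev) + nbytes
  invisible(x)
}

#' Transcript and byte counters of a channel
#' @param ch an [channel()].
#' @return `channel_transcript()`: tibble `sender`, `label`, `bytes`;
#'   `channel_bytes()`: named numeric of cumulative bytes per sender.
#' @export
channel_transcript <- function(ch) {
  stopifnot(inherits(ch, "smc_channel"))
  purrr::map_dfr(ch$transcript, function(m)
    tibble::tibble(sender = m$sender, label = m$label, bytes = m$bytes))
}

#' @rdname channel_transcript
#' @export
channel_bytes <- function(ch) {
  stopifnot(inherits(ch, "smc_channel"))
  if (length(ch$bytes) == 0) c(none = 0) else ch$bytes
}

channel_payloads <- function(ch, label_pattern = NULL) {
  msgs <- ch$transcript
  if (!is.null(label_pattern))
    msgs <- Filter(function(m) grepl(label_pattern, m$label), msgs)
  lapply(msgs, `[[`, "payload")
}
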
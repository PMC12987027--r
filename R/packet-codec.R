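# Device telemetry format: fixed 40-byte frames.
#   bytes 1..3   sync word 0xAA 0xFF 0xF1
#   byte  4      payload length, fixed 0x22 = 34
#   bytes 5..36  8 channels (I, II, V1..V6), int32 little-endian raw counts
#   bytes 37..38 lead-off flags (byte 1: bit i = channel i+1 off; byte 2 opaque)
#   byte  39     checksum1 = sum(bytes 1..38) mod 256
#   byte  40     checksum2 = running mod-256 sum of checksum1 since stream start

PACKET_SYNC <- as.raw(c(0xAA, 0xFF, 0xF1))
PACKET_LEN_FIELD <- 0x22L
PACKET_BYTES <- 40L
PACKET_CHANNELS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' Encode one device packet
#'
#' Lays out one 40-byte telemetry frame. Checksum 2 is cumulative over the
#' stream, so the caller threads the running state (start a stream at 0).
#'
#' @param channel_samples exactly 8 raw ADC counts (int32 range), acquisition
#'   order I, II, V1--V6.
#' @param leadoff_flags integer 0..65535. Bit `i` of the low byte marks
#'   channel `i + 1` as disconnected; the high byte is carried verbatim.
#' @param checksum2_state running checksum-2 accumulator (0 at stream start).
#' @return list with `bytes` (raw vector of length 40) and the updated
#'   `checksum2_state`.
#' @export
#' @examples
#' p <- encode_packet(rep(0L, 8))
#' length(p$bytes)
encode_packet <- function(channel_samples, leadoff_flags = 0L,
                          checksum2_state = 0L) {
  if (length(channel_samples) != 8L)
    stop("exactly 8 channel samples required", call. = FALSE)
  if (any(!is.finite(channel_samples)) ||
      any(channel_samples < -2^31 | channel_samples > 2^31 - 1) ||
      any(channel_samples != trunc(channel_samples)))
    stop("channel samples must be integers within int32 range", call. = FALSE)
  if (leadoff_flags < 0 || leadoff_flags > 65535)
    stop("leadoff_flags must fit in 16 bits", call. = FALSE)
  payload <- writeBin(as.integer(channel_samples), raw(),
                      size = 4L, endian = "little")
  flags <- as.raw(c(leadoff_flags %% 256, leadoff_flags %/% 256))
  body <- c(PACKET_SYNC, as.raw(PACKET_LEN_FIELD), payload, flags)
  cs1 <- sum(as.integer(body)) %% 256L
  cs2 <- (checksum2_state + cs1) %% 256L
  list(bytes = c(body, as.raw(cs1), as.raw(cs2)), checksum2_state = cs2)
}

#' Decode one 40-byte window
#'
#' Rejects are returned as values (not conditions) so a corrupted byte can
#' never abort a session: the resynchronizer inspects `reason` and slides on.
#'
#' @param bytes raw vector of length 40.
#' @return list with `ok`; on success `samples` (8 int counts), `leadoff`
#'   (logical 8, per channel), `flag_bytes` (2 raw, verbatim), `checksum2`;
#'   on failure `reason` in `bad_header`, `bad_length`, `bad_checksum`.
#' @export
decode_packet <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) != PACKET_BYTES)
    stop("`bytes` must be a raw vector of length 40", call. = FALSE)
  if (!identical(bytes[1:3], PACKET_SYNC))
    return(list(ok = FALSE, reason = "bad_header"))
  if (as.integer(bytes[4]) != PACKET_LEN_FIELD)
    return(list(ok = FALSE, reason = "bad_length"))
  if (sum(as.integer(bytes[1:38])) %% 256L != as.integer(bytes[39]))
    return(list(ok = FALSE, reason = "bad_checksum"))
  samples <- readBin(bytes[5:36], integer(), n = 8L, size = 4L,
                     endian = "little")
  flag_bytes <- bytes[37:38]
  leadoff <- as.logical(rawToBits(flag_bytes[1]))[1:8]
  list(ok = TRUE, samples = samples, leadoff = leadoff,
       flag_bytes = flag_bytes, checksum2 = as.integer(bytes[40]))
}

#' Encode a whole sample matrix as a packet stream
#'
#' @param counts integer matrix, one row per frame, 8 columns (I, II,
#'   V1--V6), raw ADC counts.
#' @param leadoff_flags integer vector, one 16-bit flag word per frame
#'   (recycled if length 1).
#' @return raw vector, `40 * nrow(counts)` bytes; checksum 2 starts at 0.
#' @export
encode_stream <- function(counts, leadoff_flags = 0L) {
  stopifnot(is.matrix(counts), ncol(counts) == 8L)
  n <- nrow(counts)
  flags <- rep_len(as.integer(leadoff_flags), n)
  if (any(!is.finite(counts)) || any(abs(counts) > 2^31 - 1))
    stop("counts out of int32 range", call. = FALSE)
  # vectorised layout: payload bytes for all frames at once
  payload <- writeBin(as.integer(t(counts)), raw(), size = 4L,
                      endian = "little")
  payload <- matrix(payload, nrow = 32L)           # one column per frame
  head4 <- matrix(rep(c(PACKET_SYNC, as.raw(PACKET_LEN_FIELD)), n), nrow = 4L)
  fl <- rbind(as.raw(flags %% 256L), as.raw(flags %/% 256L))
  body <- rbind(head4, payload, fl)                # 38 x n raw
  cs1 <- colSums(matrix(as.integer(body), nrow = 38L)) %% 256L
  cs2 <- cumsum(cs1) %% 256L
  as.vector(rbind(body, as.raw(cs1), as.raw(cs2)))
}

#' Scan a byte stream and recover frames
#'
#' Slides over an arbitrary byte sequence looking for the 3-byte sync word,
#' attempts a decode at each candidate, advances 40 bytes on an accepted
#' frame and 1 byte otherwise. A spurious sync word inside junk fails its
#' checksum and is skipped, so true frames downstream are still recovered.
#'
#' @param bytes raw vector (possibly with junk, truncation, corruption).
#' @return a `frame_stream`: list with `counts` (n x 8 integer matrix),
#'   `leadoff` (n x 8 logical), `flag_bytes` (n x 2 raw matrix), `checksum2`
#'   (integer), `resync_offsets` (1-based byte positions where scanning had
#'   to skip), and `discard_count` (bytes not consumed by accepted frames).
#' @export
resync_stream <- function(bytes) {
  stopifnot(is.raw(bytes))
  n <- length(bytes)
  bi <- as.integer(bytes)
  cs <- c(0, cumsum(bi))
  starts <- integer(0)
  resync_at <- integer(0)
  pos <- 1L
  in_resync <- FALSE
  while (pos + PACKET_BYTES - 1L <= n) {
    ok <- bi[pos] == 0xAAL && bi[pos + 1L] == 0xFFL && bi[pos + 2L] == 0xF1L &&
      bi[pos + 3L] == PACKET_LEN_FIELD &&
      (cs[pos + 38L] - cs[pos]) %% 256L == bi[pos + 38L]
    if (ok) {
      starts <- c(starts, pos)
      pos <- pos + PACKET_BYTES
      in_resync <- FALSE
    } else {
      if (!in_resync) {
        resync_at <- c(resync_at, pos)
        in_resync <- TRUE
      }
      pos <- pos + 1L
    }
  }
  k <- length(starts)
  if (k > 0) {
    payload_idx <- as.vector(outer(4L:35L, starts, `+`))
    counts <- matrix(readBin(bytes[payload_idx], integer(), n = 8L * k,
                             size = 4L, endian = "little"),
                     ncol = 8L, byrow = TRUE,
                     dimnames = list(NULL, PACKET_CHANNELS))
    fb <- cbind(bytes[starts + 36L], bytes[starts + 37L])
    leadoff <- matrix(
      as.logical(rawToBits(bytes[starts + 36L])),
      ncol = 8L, byrow = TRUE, dimnames = list(NULL, PACKET_CHANNELS))
    checksum2 <- bi[starts + 39L]
  } else {
    counts <- matrix(integer(0), 0L, 8L,
                     dimnames = list(NULL, PACKET_CHANNELS))
    leadoff <- matrix(logical(0), 0L, 8L,
                      dimnames = list(NULL, PACKET_CHANNELS))
    fb <- matrix(raw(0), 0L, 2L)
    checksum2 <- integer(0)
  }
  structure(
    list(counts = counts, leadoff = leadoff, flag_bytes = fb,
         checksum2 = checksum2, resync_offsets = resync_at,
         discard_count = n - PACKET_BYTES * k),
    class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream> %d frames, %d bytes discarded\n",
              nrow(x$counts), x$discard_count))
  invisible(x)
}

#' Tidy a frame stream into a tibble
#'
#' One row per frame: frame index, the 8 raw counts and the per-channel
#' lead-off bits — the debugging export of the decoder.
#'
#' @param x a `frame_stream` from [resync_stream()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.frame_stream <- function(x, ...) {
  counts <- tibble::as_tibble(x$counts)
  off <- tibble::as_tibble(x$leadoff)
  names(off) <- paste0("off_", names(off))
  dplyr::bind_cols(
    tibble::tibble(frame = seq_len(nrow(x$counts))), counts, off)
}

#' Read / write a raw packet-stream file
#'
#' The on-disk form is the flat binary concatenation of frames, no wrapper.
#'
#' @param path file path.
#' @return `read_stream_file()`: raw vector; `write_stream_file()`: `path`.
#' @export
read_stream_file <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("empty or missing stream file: ", path, call. = FALSE)
  readBin(path, raw(), n = file.size(path))
}

#' @rdname read_stream_file
#' @param bytes raw vector to write.
#' @export
write_stream_file <- function(bytes, path) {
  writeBin(bytes, path)
  invisible(path)
}

#' Export decoded frames to CSV
#'
#' @param stream a `frame_stream`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_frames_csv <- function(stream, path) {
  readr::write_csv(tidy(stream), path)
  invisible(path)
}
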
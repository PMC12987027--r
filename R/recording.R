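#' Multichannel ECG recording container
#'
#' A `lead_recording` holds a time-aligned set of ECG channels in microvolts
#' at a fixed sampling rate, together with a per-sample, per-channel validity
#' mask (`FALSE` during lead-off or guard bands) and a free-text posture
#' label.  The transmitted device set has 8 channels (I, II, V1--V6); the
#' full clinical set has 12 (adding III, aVR, aVL, aVF).
#'
#' @param signals numeric matrix, samples in rows, one column per channel,
#'   in microvolts. Column names are the lead names.
#' @param fs sampling rate in Hz (> 0).
#' @param valid logical matrix of the same shape as `signals`; defaults to
#'   all `TRUE`.
#' @param posture free-text posture label (e.g. `"sitting"`, `"standing"`).
#'
#' @return an object of class `lead_recording`.
#' @export
#' @examples
#' x <- matrix(rnorm(1000 * 2), ncol = 2,
#'             dimnames = list(NULL, c("I", "II")))
#' rec <- lead_recording(x, fs = 500)
#' rec
lead_recording <- function(signals, fs, valid = NULL, posture = NA_character_) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("`signals` must be a numeric matrix (samples x channels)", call. = FALSE)
  if (is.null(colnames(signals)))
    stop("`signals` must have channel names as column names", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (is.null(valid)) {
    valid <- matrix(TRUE, nrow(signals), ncol(signals),
                    dimnames = dimnames(signals))
  }
  if (!identical(dim(valid), dim(signals)))
    stop("`valid` mask shape must match `signals`", call. = FALSE)
  colnames(valid) <- colnames(signals)
  structure(
    list(signals = signals, fs = fs, valid = valid,
         posture = posture),
    class = "lead_recording"
  )
}

#' @export
print.lead_recording <- function(x, ...) {
  n <- nrow(x$signals)
  cat(sprintf("<lead_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$signals), n, x$fs, n / x$fs))
  cat("  leads:", paste(colnames(x$signals), collapse = ", "), "\n")
  inval <- sum(!x$valid)
  if (inval > 0)
    cat(sprintf("  invalid samples: %d (%.1f%%)\n", inval,
                100 * inval / length(x$valid)))
  if (!is.na(x$posture)) cat("  posture:", x$posture, "\n")
  invisible(x)
}

#' @export
dim.lead_recording <- function(x) dim(x$signals)

#' Lead names of a recording
#' @param rec a [lead_recording()].
#' @return character vector of channel names.
#' @export
lead_names <- function(rec) colnames(rec$signals)

#' Extract one channel of a recording
#' @param rec a [lead_recording()].
#' @param lead channel name.
#' @return numeric vector in microvolts with invalid samples set to `NA`.
#' @export
lead_signal <- function(rec, lead) {
  if (!lead %in% lead_names(rec))
    stop("unknown lead: ", lead, call. = FALSE)
  x <- rec$signals[, lead]
  x[!rec$valid[, lead]] <- NA_real_
  x
}

#' Tidy a recording into a long tibble
#'
#' One row per (sample, lead): `time_s`, `lead`, `uv`, `valid`.
#'
#' @param x a [lead_recording()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.lead_recording <- function(x, ...) {
  n <- nrow(x$signals)
  leads <- colnames(x$signals)
  tibble::tibble(
    time_s = rep((seq_len(n) - 1) / x$fs, times = length(leads)),
    lead = factor(rep(leads, each = n), levels = leads),
    uv = as.vector(x$signals),
    valid = as.vector(x$valid)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a recording to CSV
#'
#' Wide format: a `time_s` column followed by one column per lead (uV).
#' The sampling rate and posture are recorded in `#`-prefixed header lines
#' that [read_recording_csv()] understands.
#'
#' @param rec a [lead_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", rec$fs), con)
  writeLines(sprintf("# posture=%s", rec$posture), con)
  df <- tibble::as_tibble(rec$signals)
  df <- dplyr::mutate(df,
    time_s = (dplyr::row_number() - 1) / rec$fs, .before = 1)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording_csv()]
#'
#' @param path CSV file with `# fs=` / `# posture=` header lines.
#' @param fs sampling rate override if the header is absent.
#' @return a [lead_recording()]. Samples that are `NA` in the file are
#'   marked invalid.
#' @export
read_recording_csv <- function(path, fs = NULL) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^#\\s*", key, "="), "", m[1]) else NA_character_
  }
  if (is.null(fs)) {
    fs <- suppressWarnings(as.numeric(get_field("fs")))
    if (is.na(fs)) stop("no `fs` header in ", path, "; pass `fs`", call. = FALSE)
  }
  posture <- get_field("posture")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  df$time_s <- NULL
  sig <- as.matrix(df)
  valid <- !is.na(sig)
  sig[!valid] <- 0
  lead_recording(sig, fs = fs, valid = valid,
                 posture = if (identical(posture, "NA")) NA_character_ else posture)
}
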
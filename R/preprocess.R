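# Raw-count scaling and the signal conditioning chain: high-pass baseline
# removal, mains notch, low-pass muscle-noise suppression, all zero-phase so
# fiducial latencies are preserved, applied segment-wise over contiguous
# valid runs so masked samples never leak into filter state.

#' ADC scale constant (microvolts per count)
#'
#' The front-end converter digitises a +/- Vref span (Vref = 2.4 V) over 24
#' bits at unity gain, so one count is `2 * 2.4 / 2^24` volts, about
#' 0.286 uV. The constant is computed, never hard-coded.
#'
#' @param vref_v reference voltage in volts.
#' @param bits converter resolution.
#' @param gain programmable front-end gain.
#' @return microvolts per count (signif to 6 digits on print).
#' @export
#' @examples
#' round(adc_scale_uv(), 3)  # 0.286
adc_scale_uv <- function(vref_v = 2.4, bits = 24, gain = 1) {
  2 * vref_v / gain / 2^bits * 1e6
}

#' Convert raw ADC counts to microvolts (and back)
#'
#' @param raw integer counts (any int32).
#' @param scale_uv microvolts per count, default [adc_scale_uv()].
#' @return numeric microvolts.
#' @export
counts_to_microvolts <- function(raw, scale_uv = adc_scale_uv()) {
  raw * scale_uv
}

#' @rdname counts_to_microvolts
#' @param uv microvolt values.
#' @details `microvolts_to_counts()` rounds half to even (banker's
#'   rounding), so the encode/decode amplitude error is bounded by half a
#'   count (~0.143 uV).
#' @export
microvolts_to_counts <- function(uv, scale_uv = adc_scale_uv()) {
  counts <- round(uv / scale_uv)
  if (any(abs(counts) >= 2^23, na.rm = TRUE))
    stop("amplitude exceeds 24-bit full scale", call. = FALSE)
  as.integer(counts)
}

#' Conditioning chain specification
#'
#' @param highpass_hz baseline/DC removal cutoff (Hz).
#' @param notch_hz mains frequency, 50 or 60 Hz.
#' @param notch_q notch quality factor (~1.7 Hz bandwidth at Q = 30).
#' @param lowpass_hz muscle-noise cutoff (Hz).
#' @param order low-pass Butterworth order (high-pass uses order 2).
#' @param zero_phase apply filters forward-backward (recommended; keeps QT
#'   fiducials unshifted).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(highpass_hz = 0.5, notch_hz = 50, notch_q = 30,
                        lowpass_hz = 125, order = 4, zero_phase = TRUE) {
  if (!(highpass_hz > 0 && highpass_hz < lowpass_hz))
    stop("need 0 < highpass_hz < lowpass_hz", call. = FALSE)
  structure(list(highpass_hz = highpass_hz, notch_hz = notch_hz,
                 notch_q = notch_q, lowpass_hz = lowpass_hz,
                 order = order, zero_phase = zero_phase),
            class = "filter_spec")
}

condition_segment <- function(x, fs, spec) {
  nyq <- fs / 2
  hp <- butter_design(2, spec$highpass_hz / nyq, "high")
  nt <- notch_design(spec$notch_hz, spec$notch_q, fs)
  lp <- butter_design(spec$order, spec$lowpass_hz / nyq, "low")
  app <- if (spec$zero_phase) filtfilt_zp else filt_forward
  x <- app(hp$b, hp$a, x)
  x <- app(nt$b, nt$a, x)
  app(lp$b, lp$a, x)
}

#' Condition a recording
#'
#' Per channel: zero-phase high-pass (DC/baseline), mains notch, low-pass.
#' Filtering is applied independently to each contiguous valid run so that
#' masked (lead-off) samples never influence valid ones; valid runs shorter
#' than 1 s are marked invalid instead of filtered (not enough support for
#' the high-pass to settle).  Invalid samples come back as `NA`.
#'
#' @param rec a [lead_recording()].
#' @param spec a [filter_spec()].
#' @return a conditioned [lead_recording()].
#' @export
condition <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "lead_recording"))
  fs <- rec$fs
  if (spec$lowpass_hz >= fs / 2 || spec$notch_hz >= fs / 2)
    stop("filter cutoffs must lie below the Nyquist frequency", call. = FALSE)
  min_run <- ceiling(fs)          # 1 s
  sig <- rec$signals
  msk <- rec$valid
  for (ch in seq_len(ncol(sig))) {
    x <- sig[, ch]
    v <- msk[, ch]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- rep(NA_real_, length(x))
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      idx <- starts[j]:ends[j]
      if (length(idx) < min_run) {
        msk[idx, ch] <- FALSE
      } else {
        out[idx] <- condition_segment(x[idx], fs, spec)
      }
    }
    sig[, ch] <- out
  }
  lead_recording(sig, fs = fs, valid = msk, posture = rec$posture)
}

#' Apply per-frame lead-off flags to a recording
#'
#' Samples whose packet flagged the source channel are invalidated, plus a
#' guard band before and after each lead-off run to exclude reconnection
#' and filter-settling artifacts.  Works on the 8 transmitted channels;
#' derived leads pick the mask up through [derive_12_from_channels()].
#'
#' @param rec an 8-channel [lead_recording()].
#' @param frames a `frame_stream` from [resync_stream()], or a logical
#'   matrix (frames x 8) of lead-off indicators.
#' @param guard_s guard band half-width in seconds (default 0.25).
#' @return the recording with an updated validity mask.
#' @export
apply_leadoff_mask <- function(rec, frames, guard_s = 0.25) {
  stopifnot(inherits(rec, "lead_recording"))
  off <- if (inherits(frames, "frame_stream")) frames$leadoff else frames
  if (!is.matrix(off) || nrow(off) != nrow(rec$signals))
    stop("frame count must match sample count", call. = FALSE)
  guard <- round(guard_s * rec$fs)
  n <- nrow(off)
  msk <- rec$valid
  for (ch in seq_len(ncol(off))) {
    bad <- off[, ch]
    if (!any(bad)) next
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      lo <- max(1L, starts[j] - guard)
      hi <- min(n, ends[j] + guard)
      msk[lo:hi, ch] <- FALSE
    }
  }
  lead_recording(rec$signals, fs = rec$fs, valid = msk, posture = rec$posture)
}
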
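# R-peak detection: a Pan-Tompkins-style chain (band-pass 5-25 Hz, square,
# moving-window integration, adaptive threshold) with the device's refractory
# rule: no two accepted peaks closer than 0.4 s; within the refractory window
# the candidate with the larger integrated amplitude wins.

#' Detect R peaks
#'
#' @param x conditioned single-lead signal in microvolts (`NA` = invalid).
#' @param fs sampling rate (Hz).
#' @param min_gap_s refractory interval: candidates strictly closer than
#'   this to an accepted peak are suppressed (default 0.4 s). A spacing of
#'   exactly `min_gap_s` is accepted.
#' @return sorted integer vector of R-peak sample indices (1-based).
#' @export
detect_r_peaks <- function(x, fs = 500, min_gap_s = 0.4) {
  n <- length(x)
  if (n < 2 * fs)
    stop("need at least 2 s of signal for R-peak detection", call. = FALSE)
  invalid <- !is.finite(x)
  x0 <- ifelse(invalid, 0, x)

  nyq <- fs / 2
  bp_hi <- butter_design(2, 5 / nyq, "high")
  bp_lo <- butter_design(2, 25 / nyq, "low")
  bp <- filtfilt_zp(bp_lo$b, bp_lo$a, filtfilt_zp(bp_hi$b, bp_hi$a, x0))
  integ <- moving_average(c(0, diff(bp))^2, round(0.15 * fs))

  # candidate local maxima of the integrated energy
  d <- diff(integ)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[integ[cand] > 0]
  if (!length(cand)) return(integer(0))

  # adaptive signal/noise levels, Pan-Tompkins style
  init <- cand[cand <= 2 * fs]
  spk <- if (length(init)) max(integ[init]) else max(integ[cand])
  npk <- spk / 10
  min_gap <- as.integer(round(min_gap_s * fs))
  acc <- integer(0)      # accepted candidate positions (integ peak)
  acc_h <- numeric(0)
  for (i in cand) {
    h <- integ[i]
    thr <- npk + 0.25 * (spk - npk)
    if (h >= thr) {
      if (length(acc) && i - acc[length(acc)] < min_gap) {
        if (h > acc_h[length(acc)]) {       # larger candidate wins the slot
          acc[length(acc)] <- i
          acc_h[length(acc)] <- h
        } else {
          npk <- 0.875 * npk + 0.125 * h
          next
        }
      } else {
        acc <- c(acc, i)
        acc_h <- c(acc_h, h)
      }
      spk <- 0.875 * spk + 0.125 * h
    } else {
      npk <- 0.875 * npk + 0.125 * h
    }
  }
  if (!length(acc)) return(integer(0))

  # refine each detection to the extremum of the band-passed signal nearby
  half <- as.integer(round(0.1 * fs))
  peaks <- vapply(acc, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))

  # enforce the refractory rule on refined locations
  keep <- integer(0)
  for (p in peaks) {
    if (length(keep) && p - keep[length(keep)] < min_gap) {
      if (abs(bp[p]) > abs(bp[keep[length(keep)]]))
        keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  # drop peaks inside masked segments
  keep[!invalid[keep]]
}

#' Rhythm metrics from R-peak locations
#'
#' RR intervals, heart rate (`60 / mean(RR)`) and SDNN (the sample standard
#' deviation of RR, N - 1 denominator, in ms).
#'
#' @param r_peaks sorted R-peak sample indices.
#' @param fs sampling rate (Hz).
#' @return a one-row tibble: `n_beats`, `hr_bpm`, `rr_mean_s`, `sdnn_ms`,
#'   with the RR sequence (seconds) in list-column `rr_s`. With fewer than
#'   2 peaks the rate fields are `NA`; SDNN needs at least 3 peaks.
#' @export
#' @examples
#' rhythm_metrics(c(1, 251, 501, 751), fs = 500)  # 120 bpm, SDNN 0
rhythm_metrics <- function(r_peaks, fs = 500) {
  n <- length(r_peaks)
  rr <- if (n >= 2) diff(r_peaks) / fs else numeric(0)
  tibble::tibble(
    n_beats = n,
    hr_bpm = if (n >= 2) 60 / mean(rr) else NA_real_,
    rr_mean_s = if (n >= 2) mean(rr) else NA_real_,
    sdnn_ms = if (n >= 3) stats::sd(rr) * 1000 else NA_real_,
    rr_s = list(rr)
  )
}
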
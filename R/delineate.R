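# Beat delineation.  Q onset and QRS offset by amplitude/slope threshold
# search around the R peak, T peak as the largest post-QRS deflection from
# the PQ baseline, and T end by the tangent method: the steepest post-peak
# tangent intersected with the isoelectric baseline.  Per-beat exclusion
# rules (insufficient T amplitude relative to noise, ambiguous morphology /
# U-wave suspicion, undetectable T end) follow the repolarization quality
# policy of the analysis pipeline.

EXCLUSION_LEVELS <- c("none", "low_t_amplitude", "ambiguous_morphology",
                      "tend_undetectable", "masked_segment")

#' Delineation thresholds
#'
#' Fixed defaults for the qualitative exclusion rules; all exposed here.
#'
#' @param q_search_ms backward Q-onset search span from R (default 80).
#' @param j_search_ms forward QRS-offset search span from R (default 150).
#' @param t_win_ms T-peak search window after the J point (default 80--400).
#' @param tangent_max_ms T end must be found within this of the T peak.
#' @param t_floor_uv minimum T amplitude in microvolts (default 50).
#' @param noise_mult T amplitude must also exceed this multiple of the
#'   noise RMS (default 3).
#' @param u_frac a same-sign deflection at least this fraction of the T
#'   amplitude shortly after the tentative T end raises U-wave suspicion.
#' @param u_win_ms U-wave search span after the tentative T end.
#' @param pq_baseline_ms isoelectric baseline window ending at Q onset.
#' @param onset_frac amplitude fraction defining wave onset/offset
#'   crossings (`exp(-2)`, the two-sigma point of a Gaussian wave).
#' @return a `delineation_config` list.
#' @export
delineation_config <- function(q_search_ms = 80, j_search_ms = 150,
                               t_win_ms = c(80, 400), tangent_max_ms = 250,
                               t_floor_uv = 50, noise_mult = 3,
                               u_frac = 0.25, u_win_ms = 200,
                               pq_baseline_ms = 40, onset_frac = exp(-2)) {
  structure(as.list(environment()), class = "delineation_config")
}

empty_annotation <- function(r_index, reason) {
  tibble::tibble(
    r_index = r_index, q_onset = NA_integer_, qrs_offset = NA_integer_,
    t_peak = NA_integer_, t_end = NA_integer_,
    p_onset = NA_integer_, p_offset = NA_integer_,
    baseline_uv = NA_real_, t_amp_uv = NA_real_,
    rr_prev_s = NA_real_, valid = FALSE,
    exclusion_reason = factor(reason, levels = EXCLUSION_LEVELS))
}

# backward (dir = -1) or forward (dir = +1) threshold-crossing search:
# first index, moving from `from` in direction `dir` up to `limit`, whose
# deflection from `bl` drops below `thr`
cross_search <- function(x, bl, from, limit, dir, thr) {
  idx <- seq(from, limit, by = dir)
  below <- abs(x[idx] - bl) < thr
  hit <- which(below)
  if (length(hit)) idx[hit[1]] else limit
}

#' Delineate one beat
#'
#' @param x conditioned single-lead signal, microvolts (`NA` = invalid).
#' @param r_index R-peak sample index (1-based).
#' @param fs sampling rate (Hz).
#' @param noise_rms noise scale in microvolts (see [estimate_noise_rms()]).
#' @param cfg a [delineation_config()].
#' @param rr_prev_s preceding RR interval in seconds, if known.
#' @param next_r next R-peak index, if known; used to keep the T/U search
#'   windows clear of the following beat.
#' @return a one-row tibble (beat annotation): fiducial indices `q_onset`,
#'   `qrs_offset` (J point), `t_peak`, `t_end`, `p_onset`, `p_offset`, the
#'   PQ `baseline_uv` and `t_amp_uv`, `rr_prev_s`, `valid`, and
#'   `exclusion_reason` (one of `none`, `low_t_amplitude`,
#'   `ambiguous_morphology`, `tend_undetectable`, `masked_segment`).
#' @export
delineate_beat <- function(x, r_index, fs = 500, noise_rms = 5,
                           cfg = delineation_config(),
                           rr_prev_s = NA_real_, next_r = NA_integer_) {
  ms <- function(v) as.integer(round(v / 1000 * fs))
  n <- length(x)
  pre <- ms(300); post <- ms(700)
  if (r_index - pre < 1L || r_index + post > n ||
      anyNA(x[(r_index - pre):(r_index + post)]))
    return(empty_annotation(r_index, "masked_segment"))

  done <- function(reason, q_on = NA_integer_, j = NA_integer_,
                   tp = NA_integer_, te = NA_integer_,
                   p_on = NA_integer_, p_off = NA_integer_,
                   bl = NA_real_, tamp = NA_real_) {
    out <- empty_annotation(r_index, reason)
    out$q_onset <- q_on; out$qrs_offset <- j
    out$t_peak <- tp; out$t_end <- te
    out$p_onset <- p_on; out$p_offset <- p_off
    out$baseline_uv <- bl; out$t_amp_uv <- tamp
    out$rr_prev_s <- rr_prev_s
    out$valid <- identical(reason, "none")
    out
  }

  # rough baseline from the PQ-ish interval, then Q onset
  bl0 <- stats::median(x[(r_index - ms(100)):(r_index - ms(60))])
  q_lim <- r_index - ms(cfg$q_search_ms)
  qseg <- x[q_lim:(r_index - 1L)]
  q_trough <- q_lim + which.min(qseg) - 1L
  q_depth <- bl0 - x[q_trough]
  r_amp <- abs(x[r_index] - bl0)
  q_on <- if (q_depth > max(10, 2 * noise_rms)) {
    cross_search(x, bl0, q_trough, q_lim, -1L, cfg$onset_frac * q_depth)
  } else {
    cross_search(x, bl0, r_index - 1L, q_lim, -1L,
                 max(10, 0.02 * r_amp))
  }

  # refined isoelectric baseline: PQ window ending at Q onset
  bl <- mean(x[(q_on - ms(cfg$pq_baseline_ms)):(q_on - 1L)])

  # QRS offset (J point)
  j_lim <- min(n, r_index + ms(cfg$j_search_ms))
  s_seg <- x[(r_index + 1L):(r_index + ms(80))]
  s_trough <- r_index + which.min(s_seg)
  s_depth <- bl - x[s_trough]
  j <- if (s_depth > max(10, 2 * noise_rms)) {
    cross_search(x, bl, s_trough, j_lim, 1L, cfg$onset_frac * s_depth)
  } else {
    cross_search(x, bl, r_index + 1L, j_lim, 1L, max(10, 0.02 * r_amp))
  }

  # P wave, searched between the previous T and the QRS
  p_lo <- max(1L, q_on - ms(240)); p_hi <- q_on - ms(30)
  p_on <- p_off <- NA_integer_
  if (p_hi > p_lo) {
    pseg <- x[p_lo:p_hi]
    p_peak <- p_lo + which.max(abs(pseg - bl)) - 1L
    p_amp <- abs(x[p_peak] - bl)
    if (p_amp > max(20, 2.5 * noise_rms)) {
      thr <- cfg$onset_frac * p_amp
      p_on <- cross_search(x, bl, p_peak, p_lo, -1L, thr)
      p_off <- cross_search(x, bl, p_peak, p_hi, 1L, thr)
    }
  }

  # T peak: largest deflection from baseline after the J point
  t_lo <- j + ms(cfg$t_win_ms[1])
  t_hi <- min(j + ms(cfg$t_win_ms[2]), n)
  if (!is.na(next_r)) t_hi <- min(t_hi, next_r - ms(100))
  if (t_hi <= t_lo)
    return(done("tend_undetectable", q_on, j, bl = bl))
  tseg <- x[t_lo:t_hi]
  tp <- t_lo + which.max(abs(tseg - bl)) - 1L
  tamp <- x[tp] - bl
  tsign <- sign(tamp)

  if (abs(tamp) < max(cfg$t_floor_uv, cfg$noise_mult * noise_rms))
    return(done("low_t_amplitude", q_on, j, tp,
                p_on = p_on, p_off = p_off, bl = bl, tamp = tamp))

  # biphasic T: a comparable opposite-polarity deflection in the T window
  opp <- max(-tsign * (tseg - bl))
  if (opp >= max(cfg$noise_mult * noise_rms, cfg$u_frac * abs(tamp)))
    return(done("ambiguous_morphology", q_on, j, tp,
                p_on = p_on, p_off = p_off, bl = bl, tamp = tamp))

  # tangent method: steepest post-peak slope toward baseline.  The
  # inflection is located on a smoothed derivative and the tangent (slope
  # and anchor value) comes from a local least-squares line fit, so noise
  # cannot systematically steepen the tangent and pull the T end early.
  seg_hi <- min(tp + ms(cfg$tangent_max_ms), n - 1L)
  if (seg_hi <= tp + 1L)
    return(done("tend_undetectable", q_on, j, tp,
                p_on = p_on, p_off = p_off, bl = bl, tamp = tamp))
  ds <- (x[(tp + 2L):(seg_hi + 1L)] - x[tp:(seg_hi - 1L)]) / 2  # centred diff
  toward <- moving_average(-tsign * ds, ms(30))
  i_m <- tp + which.max(toward)
  h <- max(2L, ms(14))
  lo <- max(tp, i_m - h); hi <- min(n, i_m + h)
  fit <- stats::lm.fit(cbind(1, (lo:hi) - i_m), x[lo:hi])
  slope <- fit$coefficients[2]
  anchor <- fit$coefficients[1]
  if (tsign * slope >= 0)
    return(done("tend_undetectable", q_on, j, tp,
                p_on = p_on, p_off = p_off, bl = bl, tamp = tamp))
  te_frac <- i_m + (bl - anchor) / slope
  te <- as.integer(round(te_frac))
  if (!is.finite(te_frac) || te <= tp || te > tp + ms(cfg$tangent_max_ms))
    return(done("tend_undetectable", q_on, j, tp,
                p_on = p_on, p_off = p_off, bl = bl, tamp = tamp))

  # U-wave suspicion: same-sign deflection soon after the tentative T end
  u_hi <- min(te + ms(cfg$u_win_ms), n)
  if (!is.na(next_r)) u_hi <- min(u_hi, next_r - ms(250))
  if (u_hi > te + 2L) {
    useg <- x[(te + 1L):u_hi]
    if (max(tsign * (useg - bl)) >= cfg$u_frac * abs(tamp))
      return(done("ambiguous_morphology", q_on, j, tp, te,
                  p_on, p_off, bl, tamp))
  }

  done("none", q_on, j, tp, te, p_on, p_off, bl, tamp)
}

#' Noise scale of a lead
#'
#' Robust noise RMS: 1.4826 x the median absolute deviation of the signal
#' in the PQ (isoelectric) segments preceding each R peak, after removing
#' each segment's own median level.
#'
#' @param x conditioned single-lead signal (microvolts).
#' @param r_peaks R-peak indices.
#' @param fs sampling rate (Hz).
#' @return noise RMS estimate in microvolts.
#' @export
estimate_noise_rms <- function(x, r_peaks, fs = 500) {
  lo <- round(0.100 * fs); hi <- round(0.060 * fs)
  res <- unlist(lapply(r_peaks, function(r) {
    if (r - lo < 1) return(NULL)
    seg <- x[(r - lo):(r - hi)]
    if (anyNA(seg)) return(NULL)
    seg - stats::median(seg)
  }))
  if (is.null(res) || !length(res)) return(NA_real_)
  stats::mad(res, center = 0)
}

#' Delineate every beat of one lead
#'
#' @inheritParams delineate_beat
#' @param r_peaks sorted R-peak indices (typically detected on lead II and
#'   shared across leads).
#' @param noise_rms noise scale; estimated from the lead's PQ segments when
#'   `NULL`.
#' @return tibble of beat annotations, one row per R peak, plus a
#'   `noise_rms_uv` attribute.
#' @export
delineate_lead <- function(x, r_peaks, fs = 500, noise_rms = NULL,
                           cfg = delineation_config()) {
  if (is.null(noise_rms)) noise_rms <- estimate_noise_rms(x, r_peaks, fs)
  if (!is.finite(noise_rms)) noise_rms <- Inf  # unmeasurable -> exclude all
  k <- length(r_peaks)
  if (k == 0L) {
    out <- empty_annotation(1L, "none")[0, ]
    attr(out, "noise_rms_uv") <- noise_rms
    return(out)
  }
  rr_prev <- c(NA_real_, diff(r_peaks) / fs)
  next_r <- c(r_peaks[-1], NA_integer_)
  out <- purrr::map_dfr(seq_len(k), function(i) {
    delineate_beat(x, r_peaks[i], fs = fs, noise_rms = noise_rms, cfg = cfg,
                   rr_prev_s = rr_prev[i], next_r = next_r[i])
  })
  attr(out, "noise_rms_uv") <- noise_rms
  out
}

#' Morphology metrics for one lead
#'
#' Per-beat measurements referenced to the PQ baseline -- T amplitude
#' (`signal(t_peak) - baseline`), ST level as the mean over J + 60..80 ms
#' minus the baseline, P duration and QRS width -- summarised as medians
#' over the valid beats.
#'
#' @param beats annotation tibble from [delineate_lead()].
#' @param x the lead's conditioned signal (microvolts).
#' @param fs sampling rate (Hz).
#' @return one-row tibble: `p_duration_ms`, `qrs_width_ms`,
#'   `t_amplitude_mv`, `st_shift_mv`, `n_beats_used`. All-`NA` (with
#'   `n_beats_used = 0`) when no beat is valid.
#' @export
morphology_metrics <- function(beats, x, fs = 500) {
  use <- dplyr::filter(beats, .data$valid)
  if (nrow(use) == 0)
    return(tibble::tibble(p_duration_ms = NA_real_, qrs_width_ms = NA_real_,
                          t_amplitude_mv = NA_real_, st_shift_mv = NA_real_,
                          n_beats_used = 0L))
  ms_per <- 1000 / fs
  st <- purrr::map_dbl(seq_len(nrow(use)), function(i) {
    j <- use$qrs_offset[i]
    seg <- x[(j + round(0.060 * fs)):(j + round(0.080 * fs))]
    mean(seg) - use$baseline_uv[i]
  })
  med <- function(v) if (all(is.na(v))) NA_real_ else
    stats::median(v, na.rm = TRUE)
  tibble::tibble(
    p_duration_ms = med((use$p_offset - use$p_onset) * ms_per),
    qrs_width_ms = med((use$qrs_offset - use$q_onset) * ms_per),
    t_amplitude_mv = med(use$t_amp_uv) / 1000,
    st_shift_mv = med(st) / 1000,
    n_beats_used = nrow(use)
  )
}
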
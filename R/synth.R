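# Ground-truth-labelled synthetic ECG.  Beats are sums of Gaussian waves
# (P, Q, R, S, T, optional U) so every fiducial has a closed form: for a
# Gaussian T wave the steepest-tangent intersection with the baseline falls
# exactly at t_peak + 2*sigma_T, and a two-sigma amplitude crossing defines
# wave onsets/offsets.  The generator therefore places the T wave so that
# (true T end - true QRS onset) equals the requested per-lead QT, making
# ground truth exact under the pipeline's own delineation conventions.

expand_per_lead <- function(v, default, what) {
  if (is.null(v)) v <- default
  if (length(v) == 1L && is.null(names(v)))
    return(stats::setNames(rep(as.numeric(v), 8L), LEADS_8))
  out <- stats::setNames(rep(as.numeric(default[1]), 8L), LEADS_8)
  if (is.null(names(v)))
    stop(what, " must be a scalar or a named per-lead vector", call. = FALSE)
  bad <- setdiff(names(v), LEADS_8)
  if (length(bad)) stop("unknown lead(s) in ", what, ": ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out[names(v)] <- v
  out
}

#' Synthetic beat morphology parameters
#'
#' Per-lead values may be given as a scalar (applied to all 8 transmitted
#' channels) or a named vector over I, II, V1--V6.
#'
#' @param pr_ms P-onset to QRS-onset interval (default 160).
#' @param p_dur_ms P-wave duration (default 100).
#' @param p_amp_mv P-wave amplitude (default 0.1).
#' @param qrs_ms QRS width (default 90).
#' @param qt_ms per-lead true QT, QRS onset to T end (default 400).
#' @param t_amp_mv per-lead T amplitude (defaults span 0.2--0.45 mV across
#'   the chest leads, a typical healthy pattern).
#' @param r_amp_mv per-lead R amplitude (defaults 0.5--1.6 mV).
#' @param st_offset_mv per-lead ST-segment offset (default 0).
#' @param u_amp_frac optional U-wave amplitude as a fraction of the T
#'   amplitude (default 0 = no U wave).
#' @return a `synth_beat_params` list with all per-lead fields expanded.
#' @export
synth_beat_params <- function(pr_ms = 160, p_dur_ms = 100, p_amp_mv = 0.1,
                              qrs_ms = 90, qt_ms = 400,
                              t_amp_mv = NULL, r_amp_mv = NULL,
                              st_offset_mv = 0, u_amp_frac = 0) {
  t_def <- c(I = 0.20, II = 0.30, V1 = 0.15, V2 = 0.40, V3 = 0.45,
             V4 = 0.40, V5 = 0.30, V6 = 0.25)
  r_def <- c(I = 0.80, II = 1.10, V1 = 0.50, V2 = 0.90, V3 = 1.30,
             V4 = 1.60, V5 = 1.30, V6 = 0.90)
  p <- list(
    pr_ms = pr_ms, p_dur_ms = p_dur_ms, p_amp_mv = p_amp_mv, qrs_ms = qrs_ms,
    qt_ms = expand_per_lead(qt_ms, 400, "qt_ms"),
    t_amp_mv = if (is.null(t_amp_mv)) t_def
               else expand_per_lead(t_amp_mv, 0.3, "t_amp_mv"),
    r_amp_mv = if (is.null(r_amp_mv)) r_def
               else expand_per_lead(r_amp_mv, 1.0, "r_amp_mv"),
    st_offset_mv = expand_per_lead(st_offset_mv, 0, "st_offset_mv"),
    u_amp_frac = u_amp_frac
  )
  if (any(p$qt_ms <= p$qrs_ms))
    stop("qt_ms must exceed qrs_ms", call. = FALSE)
  structure(p, class = "synth_beat_params")
}

#' Synthetic session parameters
#'
#' Defaults emulate the recording protocol the pipeline targets: 1-minute
#' fragments at 500 Hz, resting heart rate ~70 bpm with ~60 ms RR jitter
#' (a normal SDNN), ~8 uV additive noise, slow baseline wander and a small
#' mains component.
#'
#' @param duration_s recording length (default 60).
#' @param fs sampling rate in Hz (default 500).
#' @param hr_bpm mean heart rate (default 70).
#' @param hr_jitter_sd_ms SD of the Gaussian RR jitter (default 60).
#' @param noise_rms_uv additive white-noise RMS, scalar or per-lead named
#'   vector (default 8).
#' @param baseline_wander_uv amplitude of the sinusoidal baseline wander
#'   (default 50).
#' @param baseline_wander_hz wander frequency (default 0.2).
#' @param mains_uv amplitude of the mains interference sinusoid (default 10).
#' @param mains_hz mains frequency (default 50).
#' @param leadoff_episodes list of `list(channel =, start_s =, end_s =)`
#'   intermittent lead-off episodes; the channel is zeroed (open circuit)
#'   and its packet flag bit set for the episode.
#' @param seed integer seed fixing all randomness (`NULL` = leave RNG alone).
#' @return a `synth_session_params` list.
#' @export
synth_session_params <- function(duration_s = 60, fs = 500, hr_bpm = 70,
                                 hr_jitter_sd_ms = 60, noise_rms_uv = 8,
                                 baseline_wander_uv = 50,
                                 baseline_wander_hz = 0.2,
                                 mains_uv = 10, mains_hz = 50,
                                 leadoff_episodes = list(), seed = NULL) {
  stopifnot(duration_s > 0, fs > 0, hr_bpm > 0)
  for (ep in leadoff_episodes) {
    stopifnot(ep$channel %in% LEADS_8,
              ep$start_s >= 0, ep$end_s <= duration_s,
              ep$start_s < ep$end_s)
  }
  structure(list(
    duration_s = duration_s, fs = fs, hr_bpm = hr_bpm,
    hr_jitter_sd_ms = hr_jitter_sd_ms,
    noise_rms_uv = expand_per_lead(noise_rms_uv, 8, "noise_rms_uv"),
    baseline_wander_uv = baseline_wander_uv,
    baseline_wander_hz = baseline_wander_hz,
    mains_uv = mains_uv, mains_hz = mains_hz,
    leadoff_episodes = leadoff_episodes, seed = seed),
    class = "synth_session_params")
}

# wave geometry of one beat in one lead, ms relative to the R peak
beat_layout <- function(beat, lead) {
  q <- beat$qrs_ms
  qt <- beat$qt_ms[[lead]]
  sig_q <- 0.08 * q; sig_s <- 0.08 * q; sig_r <- 0.10 * q
  q_c <- -0.35 * q; s_c <- 0.35 * q
  q_onset <- q_c - 2 * sig_q
  j <- s_c + 2 * sig_s
  t_end <- q_onset + qt
  sig_t <- qt / 8
  t_peak <- t_end - 2 * sig_t
  p_onset <- q_onset - beat$pr_ms
  sig_p <- beat$p_dur_ms / 4
  list(
    waves = list(
      p = c(p_onset + beat$p_dur_ms / 2, sig_p, beat$p_amp_mv * 1000),
      q = c(q_c, sig_q, -0.12 * beat$r_amp_mv[[lead]] * 1000),
      r = c(0, sig_r, beat$r_amp_mv[[lead]] * 1000),
      s = c(s_c, sig_s, -0.20 * beat$r_amp_mv[[lead]] * 1000),
      t = c(t_peak, sig_t, beat$t_amp_mv[[lead]] * 1000),
      u = if (beat$u_amp_frac > 0)
        c(t_end + 120, 25, beat$u_amp_frac * beat$t_amp_mv[[lead]] * 1000)
    ),
    st = c(j + 5, t_peak - 1.5 * sig_t, beat$st_offset_mv[[lead]] * 1000),
    fid = c(p_onset = p_onset, p_offset = p_onset + beat$p_dur_ms,
            q_onset = q_onset, j = j, t_peak = t_peak, t_end = t_end,
            qt_ms = qt)
  )
}

add_gauss <- function(x, fs, center_s, sigma_ms, amp_uv) {
  sigma <- sigma_ms / 1000 * fs
  c0 <- center_s * fs + 1
  lo <- max(1L, floor(c0 - 5 * sigma)); hi <- min(length(x), ceiling(c0 + 5 * sigma))
  if (hi < lo) return(x)
  i <- lo:hi
  x[i] <- x[i] + amp_uv * exp(-((i - c0)^2) / (2 * sigma^2))
  x
}

add_st_plateau <- function(x, fs, r_s, st, ramp_ms = 20) {
  if (st[3] == 0) return(x)
  lo_s <- r_s + st[1] / 1000; hi_s <- r_s + st[2] / 1000
  if (hi_s <= lo_s) return(x)
  ramp <- ramp_ms / 1000
  i <- max(1L, floor(lo_s * fs)):min(length(x), ceiling((hi_s + ramp) * fs))
  t <- (i - 1) / fs
  w <- rep(1, length(i))
  w[t < lo_s + ramp] <- 0.5 * (1 - cos(pi * (t[t < lo_s + ramp] - lo_s) / ramp))
  w[t > hi_s] <- 0.5 * (1 + cos(pi * (t[t > hi_s] - hi_s) / ramp))
  w[t < lo_s | t > hi_s + ramp] <- 0
  x[i] <- x[i] + st[3] * w
  x
}

#' Generate a ground-truth-labelled synthetic recording
#'
#' @param beat a [synth_beat_params()].
#' @param sess a [synth_session_params()].
#' @return list with `recording` (8-channel [lead_recording()], uV),
#'   `truth` (list: `beats` -- tibble of per-beat shared fiducial indices
#'   r_index/q_onset/qrs_offset/p_onset/p_offset; `leads` -- tibble of
#'   per-(beat, lead) `t_peak`, `t_end` indices and true `qt_ms`; `rr_s`),
#'   and the echoed parameters.
#' @export
generate_recording <- function(beat = synth_beat_params(),
                               sess = synth_session_params()) {
  run <- function() {
    fs <- sess$fs
    n <- round(sess$duration_s * fs)
    rr_ms <- 60000 / sess$hr_bpm
    # R-peak schedule
    r_s <- 0.5
    repeat {
      nxt <- r_s[length(r_s)] +
        (rr_ms + stats::rnorm(1, 0, sess$hr_jitter_sd_ms)) / 1000
      if (nxt > sess$duration_s - 0.8) break
      r_s <- c(r_s, nxt)
    }
    rr_real <- diff(r_s)
    if (any(rr_real * 1000 < max(beat$qt_ms) + 250))
      stop("beats overlap: QT + margin exceeds an RR interval", call. = FALSE)

    layouts <- lapply(LEADS_8, function(ld) beat_layout(beat, ld))
    names(layouts) <- LEADS_8
    sig <- matrix(0, n, 8L, dimnames = list(NULL, LEADS_8))
    tvec <- (seq_len(n) - 1) / fs
    for (ld in LEADS_8) {
      lay <- layouts[[ld]]
      x <- numeric(n)
      for (r in r_s) {
        for (w in lay$waves) {
          if (is.null(w)) next
          x <- add_gauss(x, fs, r + w[1] / 1000, w[2], w[3])
        }
        x <- add_st_plateau(x, fs, r, lay$st)
      }
      ph <- stats::runif(2, 0, 2 * pi)
      x <- x +
        sess$baseline_wander_uv * sin(2 * pi * sess$baseline_wander_hz * tvec + ph[1]) +
        sess$mains_uv * sin(2 * pi * sess$mains_hz * tvec + ph[2]) +
        stats::rnorm(n, 0, sess$noise_rms_uv[[ld]])
      sig[, ld] <- x
    }
    # open-circuit emulation during lead-off episodes
    for (ep in sess$leadoff_episodes) {
      idx <- (floor(ep$start_s * fs) + 1L):min(n, ceiling(ep$end_s * fs))
      sig[idx, ep$channel] <- 0
    }
    idx_of <- function(r, off_ms) as.integer(round(r * fs + off_ms / 1000 * fs)) + 1L
    fid0 <- layouts[[1]]$fid           # QRS/P geometry is lead-independent
    beats <- tibble::tibble(
      beat = seq_along(r_s),
      r_index = as.integer(round(r_s * fs)) + 1L,
      q_onset = idx_of(r_s, fid0[["q_onset"]]),
      qrs_offset = idx_of(r_s, fid0[["j"]]),
      p_onset = idx_of(r_s, fid0[["p_onset"]]),
      p_offset = idx_of(r_s, fid0[["p_offset"]])
    )
    leads_truth <- purrr::map_dfr(LEADS_8, function(ld) {
      f <- layouts[[ld]]$fid
      tibble::tibble(
        beat = seq_along(r_s), lead = ld,
        t_peak = idx_of(r_s, f[["t_peak"]]),
        t_end = idx_of(r_s, f[["t_end"]]),
        qt_ms = f[["qt_ms"]]
      )
    })
    list(
      recording = lead_recording(sig, fs = fs),
      truth = list(beats = beats, leads = leads_truth, rr_s = rr_real),
      beat_params = beat, session_params = sess
    )
  }
  if (!is.null(sess$seed)) withr::with_seed(sess$seed, run()) else run()
}

#' Minimal QRS-like bump train
#'
#' A bare train of Gaussian R-wave bumps at explicit times, for exercising
#' the R-peak detector (e.g. refractory sweeps) without full beat
#' morphology.
#'
#' @param centers_s bump centre times in seconds.
#' @param duration_s signal length in seconds.
#' @param fs sampling rate (Hz).
#' @param amp_uv bump amplitude in microvolts.
#' @param sigma_ms bump width (Gaussian sigma) in ms.
#' @return numeric vector of length `duration_s * fs`.
#' @export
synth_bump_train <- function(centers_s, duration_s, fs = 500,
                             amp_uv = 1000, sigma_ms = 9) {
  x <- numeric(round(duration_s * fs))
  for (c0 in centers_s) x <- add_gauss(x, fs, c0, sigma_ms, amp_uv)
  x
}

#' Serialize a synthetic recording as a device packet stream
#'
#' Microvolts are converted to raw counts by the inverse of the ADC scale
#' (round half to even), one 40-byte packet per sample; lead-off flag bits
#' are set during the configured episodes.  The result parses back through
#' [resync_stream()] with zero discard.
#'
#' @param rec an 8-channel [lead_recording()] in microvolts.
#' @param sess the [synth_session_params()] carrying the lead-off episodes
#'   (optional; no flags when omitted).
#' @return raw vector, `40 * n_samples` bytes.
#' @export
stream_as_packets <- function(rec, sess = NULL) {
  stopifnot(inherits(rec, "lead_recording"), ncol(rec$signals) == 8L)
  counts <- matrix(microvolts_to_counts(rec$signals), nrow(rec$signals), 8L)
  flags <- integer(nrow(counts))
  if (!is.null(sess)) {
    for (ep in sess$leadoff_episodes) {
      ch_bit <- 2^(match(ep$channel, LEADS_8) - 1L)
      idx <- (floor(ep$start_s * rec$fs) + 1L):
        min(nrow(counts), ceiling(ep$end_s * rec$fs))
      flags[idx] <- bitwOr(flags[idx], as.integer(ch_bit))
    }
  }
  encode_stream(counts, flags)
}
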
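# Shared fixtures, all generated in code.

# a clean, low-noise session: no jitter, no wander, no mains unless asked
clean_session <- function(seed, duration_s = 30, hr_bpm = 60,
                          noise_rms_uv = 2, hr_jitter_sd_ms = 0,
                          baseline_wander_uv = 0, mains_uv = 0, ...) {
  synth_session_params(duration_s = duration_s, hr_bpm = hr_bpm,
                       noise_rms_uv = noise_rms_uv,
                       hr_jitter_sd_ms = hr_jitter_sd_ms,
                       baseline_wander_uv = baseline_wander_uv,
                       mains_uv = mains_uv, seed = seed, ...)
}

# conditioned lead II + detected peaks + annotations for a generated session
delineated_lead2 <- function(gen) {
  cond <- condition(derive_12_from_channels(gen$recording))
  x <- lead_signal(cond, "II")
  peaks <- detect_r_peaks(x, gen$recording$fs)
  list(cond = cond, x = x, peaks = peaks,
       beats = delineate_lead(x, peaks, gen$recording$fs))
}

ELECTRODE_COLS_test <- function() c("RA", "LA", "LL", paste0("V", 1:6, "e"))
LEADS_8_test <- function() c("I", "II", paste0("V", 1:6))

# random electrode potential frame (n samples)
random_electrodes <- function(n, sd = 100) {
  cols <- c("RA", "LA", "LL", paste0("V", 1:6, "e"))
  as.data.frame(setNames(lapply(cols, function(i) rnorm(n, sd = sd)), cols))
}

# one valid encoded packet as raw bytes
valid_packet_bytes <- function(samples = c(1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L),
                               flags = 0L) {
  encode_packet(samples, flags)$bytes
}
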
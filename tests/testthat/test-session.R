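# End-to-end session orchestration: pipeline composition, pause accounting,
# reproducibility, export round trips, degraded inputs.

local_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_recording(
        synth_beat_params(),
        synth_session_params(duration_s = 30, hr_bpm = 65,
                             hr_jitter_sd_ms = 30, noise_rms_uv = 6,
                             seed = 55))
      cache <<- list(g = g,
                     rec = run_analysis(g, posture = "sitting",
                                        recording_id = "sess-1"))
    }
    cache
  }
})

test_that("a clean synthetic session analyses all 12 leads with no pauses", {
  s <- local_session()$rec
  expect_identical(nrow(s$pauses), 0L)
  expect_identical(sort(unique(s$morphology$lead)),
                   sort(union(LEADS_8_test(), "II")))
  expect_false(any(is.na(unlist(
    dplyr::select(s$features, hr_bpm, qt_ms, qtc_ms, qtd_ms)))))
  expect_identical(s$features$posture, "sitting")
  # stage counters present and consistent
  expect_identical(s$counts$r_peaks, s$rhythm$n_beats)
})

test_that("rerunning the same input and config reproduces the features", {
  ses <- local_session()
  s2 <- run_analysis(ses$g, posture = "sitting", recording_id = "sess-1")
  expect_equal(ses$rec$features, s2$features, tolerance = 1e-9)
  expect_equal(ses$rec$repol$per_lead$qt_median_ms,
               s2$repol$per_lead$qt_median_ms, tolerance = 1e-9)
})

test_that("a packet-stream session reports its lead-off pause", {
  sess <- synth_session_params(
    duration_s = 20, hr_bpm = 65, hr_jitter_sd_ms = 20, noise_rms_uv = 6,
    leadoff_episodes = list(list(channel = "V2", start_s = 8, end_s = 10)),
    seed = 56)
  g <- generate_recording(synth_beat_params(), sess)
  bytes <- stream_as_packets(g$recording, sess)
  s <- run_analysis(bytes, recording_id = "stream-1")
  expect_identical(s$counts$frames, 10000L)
  expect_identical(s$counts$discarded_bytes, 0L)
  expect_identical(nrow(s$pauses), 1L)
  expect_identical(s$pauses$channel, "V2")
  expect_identical(s$pauses$cause, "lead_off")
  expect_equal(s$pauses$start_s, 8, tolerance = 0.01)
  expect_equal(s$pauses$end_s, 10, tolerance = 0.01)
})

test_that("total signal loss yields an all-NA record, not a crash", {
  n <- 6000L
  counts <- matrix(0L, n, 8)
  bytes <- encode_stream(counts, leadoff_flags = 255L)  # all channels off
  s <- run_analysis(bytes, recording_id = "lost-1")
  num <- dplyr::select(s$features, -recording_id, -posture)
  expect_true(all(is.na(unlist(num))))
  expect_identical(s$rhythm$n_beats, 0L)
})

test_that("unreadable input is an I/O error naming the file", {
  path <- withr::local_tempfile(fileext = ".bin")
  file.create(path)
  expect_error(run_analysis(path), path, fixed = TRUE)
})

test_that("CSV recording files round-trip through the pipeline entry", {
  g <- local_session()$g
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(g$recording, path)
  rec2 <- read_recording_csv(path)
  expect_equal(rec2$fs, 500)
  expect_equal(rec2$signals, g$recording$signals, tolerance = 1e-6)
})

test_that("JSON export round-trips every feature including NA", {
  s <- local_session()$rec
  s$features$qtd_ms <- NA_real_        # force an NA through the exporter
  path <- withr::local_tempfile(fileext = ".json")
  export_record(s, path)
  back <- read_session_json(path)
  expect_identical(back$session_id, "sess-1")
  expect_true(is.na(back$features$qtd_ms) || is.null(back$features$qtd_ms))
  expect_equal(back$features$qt_ms, s$features$qt_ms, tolerance = 1e-9)
  expect_equal(back$features$hr_bpm, s$features$hr_bpm, tolerance = 1e-9)
  expect_identical(names(back$features), names(s$features))
})

test_that("CSV feature export has the documented column contract", {
  s <- local_session()$rec
  path <- withr::local_tempfile(fileext = ".csv")
  export_record(s, path, format = "csv")
  hdr <- names(readr::read_csv(path, show_col_types = FALSE, n_max = 1))
  expect_identical(hdr, c("recording_id", "posture", "hr_bpm", "sdnn_ms",
                          "rr_mean_s", "p_duration_ms", "qrs_width_ms",
                          "t_amplitude_mv", "st_shift_mv", "qt_ms",
                          "qtc_ms", "qtd_ms"))
})

test_that("tidy and glance views of a session are consistent", {
  s <- local_session()$rec
  expect_identical(glance(s), s$features)
  tl <- tidy(s)
  expect_identical(nrow(tl), 10L)
  expect_equal(tl$value[tl$parameter == "qtc_ms"], s$features$qtc_ms)
})
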
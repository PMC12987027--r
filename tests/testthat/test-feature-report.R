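# Feature assembly, reference-range screening and T-end agreement.

na_rhythm <- function() tibble::tibble(n_beats = 0L, hr_bpm = NA_real_,
                                       rr_mean_s = NA_real_,
                                       sdnn_ms = NA_real_, rr_s = list(numeric(0)))
na_morph <- function() tibble::tibble(p_duration_ms = NA_real_,
                                      qrs_width_ms = NA_real_,
                                      t_amplitude_mv = NA_real_,
                                      st_shift_mv = NA_real_, n_beats_used = 0L)
na_repol <- function() list(qt_ms = NA_real_, qtc_ms = NA_real_,
                            qtd_ms = NA_real_)

test_that("all-NA inputs propagate to an all-NA vector with ids intact", {
  fv <- build_feature_vector(na_rhythm(), na_morph(), na_repol(),
                             posture = "sitting", recording_id = "r1")
  expect_identical(fv$recording_id, "r1")
  expect_identical(fv$posture, "sitting")
  num <- dplyr::select(fv, -recording_id, -posture)
  expect_true(all(is.na(unlist(num))))
  flags <- flag_against_reference(fv)
  expect_true(all(flags$flag == "not_assessed"))
})

test_that("reference flagging applies bounds with the right strictness", {
  fv <- build_feature_vector(na_rhythm(), na_morph(), na_repol())
  fv$qtd_ms <- 45
  f <- flag_against_reference(fv)
  expect_identical(f$flag[f$parameter == "qtd_ms"], "in_range")
  fv$qtc_ms <- 450   # exclusive male bound: 450 is out
  f <- flag_against_reference(fv)
  expect_identical(f$flag[f$parameter == "qtc_ms"], "out_high")
  f2 <- flag_against_reference(fv, sex = "female")
  expect_identical(f2$flag[f2$parameter == "qtc_ms"], "in_range")
  expect_identical(f$flag[f$parameter == "sdnn_ms"], "not_assessed")
  fv$st_shift_mv <- -0.1  # inclusive band edge
  f3 <- flag_against_reference(fv)
  expect_identical(f3$flag[f3$parameter == "st_shift_mv"], "in_range")
})

test_that("flagging is monotone in QT dispersion", {
  fv <- build_feature_vector(na_rhythm(), na_morph(), na_repol())
  ladder <- c(10, 30, 49, 50, 80, 140)
  flags <- vapply(ladder, function(v) {
    fv$qtd_ms <- v
    f <- flag_against_reference(fv)
    f$flag[f$parameter == "qtd_ms"]
  }, character(1))
  first_out <- match("out_high", flags)
  expect_false(any(flags[seq_along(flags) >= first_out] == "in_range"))
})

test_that("a healthy-profile synthetic recording screens clean", {
  g <- generate_recording(
    synth_beat_params(qt_ms = 380, t_amp_mv = 0.3),
    synth_session_params(duration_s = 60, hr_bpm = 70,
                         hr_jitter_sd_ms = 60, noise_rms_uv = 6, seed = 31))
  s <- run_analysis(g, posture = "sitting", recording_id = "healthy-1")
  f <- flag_against_reference(s$features)
  for (p in c("qtc_ms", "qtd_ms", "t_amplitude_mv", "st_shift_mv"))
    expect_identical(f$flag[f$parameter == p], "in_range", info = p)
})

test_that("a stressed repolarization profile is flagged out of range", {
  # wide per-lead QT spread with short RR: prolonged QTc, large QTd
  qts <- c(I = 450, II = 480, V1 = 420, V2 = 460, V3 = 490, V4 = 532,
           V5 = 500, V6 = 470)
  g <- generate_recording(
    synth_beat_params(qt_ms = qts),
    synth_session_params(duration_s = 60, hr_bpm = 70, hr_jitter_sd_ms = 10,
                         noise_rms_uv = 6, seed = 32))
  s <- run_analysis(g, posture = "sitting", recording_id = "stress-1")
  f <- flag_against_reference(s$features)
  expect_identical(f$flag[f$parameter == "qtc_ms"], "out_high")
  expect_identical(f$flag[f$parameter == "qtd_ms"], "out_high")
})

test_that("T-end agreement statistics match their closed forms", {
  a <- tend_agreement(rep(400, 16), rep(400, 16))
  expect_equal(unlist(a[c("mean_ms", "mae_ms", "sd_ms")]),
               c(mean_ms = 0, mae_ms = 0, sd_ms = 0))
  expect_identical(a$n_beats, 16L)
  b <- tend_agreement(c(398, 402), c(400, 400))
  expect_equal(b$mean_ms, 0)
  expect_equal(b$mae_ms, 2)
  expect_equal(b$sd_ms, 2 * sqrt(2), tolerance = 1e-3)
  set.seed(16)
  expert <- cumsum(runif(16, 600, 1000))
  auto <- expert - rnorm(16, -1, 13)
  g <- tend_agreement(expert, auto)
  d <- expert - auto
  expect_equal(g$mean_ms, sum(d) / 16, tolerance = 1e-9)
  expect_equal(g$mae_ms, sum(abs(d)) / 16, tolerance = 1e-9)
  expect_equal(g$sd_ms, sqrt(sum((d - mean(d))^2) / 15), tolerance = 1e-9)
  expect_error(tend_agreement(1:3, 1:4), "paired")
})

test_that("T-end agreement is translation-covariant", {
  set.seed(17)
  expert <- runif(16, 350, 450)
  auto <- expert + rnorm(16, 0, 10)
  a0 <- tend_agreement(expert, auto)
  a1 <- tend_agreement(expert + 25, auto)
  expect_equal(a1$mean_ms, a0$mean_ms + 25)
  expect_equal(a1$sd_ms, a0$sd_ms)
})
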
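# QT statistics: per-beat QT, robust outlier filtering, eligibility,
# dispersion NA semantics and Bazett correction.

test_that("per-beat QT is plain index arithmetic over valid beats", {
  b <- tibble::tibble(
    r_index = c(1100L, 1600L), q_onset = c(1000L, 1500L),
    qrs_offset = c(1150L, 1650L), t_peak = c(1150L, 1650L),
    t_end = c(1190L, 1501L), p_onset = NA_integer_, p_offset = NA_integer_,
    baseline_uv = 0, t_amp_uv = 300, rr_prev_s = 1,
    valid = c(TRUE, TRUE),
    exclusion_reason = factor("none", levels = wearqt:::EXCLUSION_LEVELS))
  expect_equal(beat_qt(b, 500), c(380, 2))
  b$valid[1] <- FALSE
  b$exclusion_reason[1] <- "low_t_amplitude"
  expect_equal(beat_qt(b, 500), 2)   # excluded beat contributes nothing
})

test_that("robust filtering drops gross outliers and keeps ties", {
  expect_identical(robust_filter(rep(400, 40)), rep(400, 40))
  v <- c(rep(380, 29), 600)
  expect_identical(robust_filter(v), rep(380, 29))
  # order preserved
  v2 <- c(390, 410, 600, 385, 405)
  expect_identical(robust_filter(v2), c(390, 410, 385, 405))
  # iqr mode directly
  cfg <- repol_config(outlier_method = "iqr")
  q <- quantile(v2, c(0.25, 0.75), names = FALSE)
  keep <- v2[v2 >= q[1] - 1.5 * diff(q) & v2 <= q[2] + 1.5 * diff(q)]
  expect_identical(robust_filter(v2, cfg), keep)
})

test_that("planted contamination is removed in every seeded run", {
  # 200 clean N(400, 5) values + 5 planted at 520: the planted outliers are
  # always dropped; 'exactly the planted and nothing else' holds in ~68% of
  # runs (simulated over 200 seeds) because ~0.5 clean tail values per run
  # also fall outside the 3*MAD fence.
  all_planted <- 0L; exact <- 0L
  for (s in 1:20) {
    set.seed(s)
    v <- sample(c(rnorm(200, 400, 5), rep(520, 5)))
    out <- robust_filter(v)
    if (!any(out == 520)) all_planted <- all_planted + 1L
    if (length(out) == 200 && !any(out == 520)) exact <- exact + 1L
  }
  expect_identical(all_planted, 20L)
  expect_gte(exact, 12L)
})

test_that("lead eligibility follows the N >= 30 or >= 50% rule", {
  e <- lead_qt_estimate(rep(400, 30), 100)
  expect_true(e$eligible)
  expect_equal(e$qt_median_ms, 400)
  e2 <- lead_qt_estimate(rep(400, 25), 40)   # 25 >= 20: the 50% branch
  expect_true(e2$eligible)
  e3 <- lead_qt_estimate(rep(400, 29), 100)  # both branches fail
  expect_false(e3$eligible)
  expect_true(is.na(e3$qt_median_ms))
  expect_identical(e3$ineligibility_reason, "insufficient_cycles")
})

test_that("dispersion honours the minimum eligible-lead rule", {
  mk <- function(med, elig) tibble::tibble(qt_median_ms = med, eligible = elig)
  expect_true(is.na(qt_dispersion(mk(rep(400, 8), c(rep(TRUE, 5), rep(FALSE, 3))))))
  expect_equal(qt_dispersion(mk(rep(400, 8), rep(TRUE, 8))), 0)
  meds <- c(380, 385, 388, 390, 392, 395, 402, 410)
  expect_equal(qt_dispersion(mk(meds, rep(TRUE, 8))), 30)
})

test_that("adding an eligible lead can only increase or preserve QTd", {
  set.seed(77)
  for (i in 1:20) {
    meds <- runif(8, 360, 440)
    elig <- c(rep(TRUE, 6), FALSE, FALSE)
    base <- qt_dispersion(tibble::tibble(qt_median_ms = meds, eligible = elig))
    elig[7] <- TRUE
    more <- qt_dispersion(tibble::tibble(qt_median_ms = meds, eligible = elig))
    expect_gte(more, base)
  }
})

test_that("Bazett correction matches its closed form", {
  expect_equal(bazett_qtc(380, 1.0), 380)          # QTc = QT at RR = 1 s
  expect_equal(bazett_qtc(400, 0.64), 500)
  set.seed(4)
  qt <- runif(50, 300, 500); rr <- runif(50, 0.5, 1.5)
  expect_equal(bazett_qtc(qt, rr), qt / sqrt(rr), tolerance = 1e-12)
  expect_error(bazett_qtc(400, 0), "positive")
})

test_that("full repolarization analysis recovers generated dispersion", {
  # zero true dispersion
  g <- generate_recording(
    synth_beat_params(qt_ms = 400),
    clean_session(seed = 21, duration_s = 40, hr_bpm = 60, noise_rms_uv = 5))
  s <- run_analysis(g)
  expect_equal(s$repol$qt_ms, 400, tolerance = 8 / 400)
  expect_equal(s$repol$qtc_ms, 400 / sqrt(mean(g$truth$rr_s)),
               tolerance = 10 / 400)
  expect_lte(s$repol$qtd_ms, 12)

  # 60 ms spread across leads
  qts <- c(I = 360, II = 380, V1 = 370, V2 = 390, V3 = 400, V4 = 420,
           V5 = 410, V6 = 395)
  g2 <- generate_recording(
    synth_beat_params(qt_ms = qts),
    clean_session(seed = 22, duration_s = 40, hr_bpm = 60, noise_rms_uv = 5))
  s2 <- run_analysis(g2)
  expect_equal(s2$repol$qtd_ms, 60, tolerance = 12 / 60)

  # only 5 clean leads: QTd is NA, reasons populated
  noise <- c(I = 5, II = 5, V1 = 3000, V2 = 3000, V3 = 3000, V4 = 5,
             V5 = 5, V6 = 5)
  g3 <- generate_recording(
    synth_beat_params(),
    clean_session(seed = 23, duration_s = 40, hr_bpm = 60,
                  noise_rms_uv = noise))
  s3 <- run_analysis(g3)
  expect_true(is.na(s3$repol$qtd_ms))
  expect_identical(s3$repol$n_eligible, 5L)
  tl <- tidy(s3$repol)
  expect_identical(tl$ineligibility_reason[!tl$eligible],
                   rep("insufficient_cycles", 3))
  # lead II still eligible: QT/QTc reported while QTd is NA
  expect_false(is.na(s3$repol$qt_ms))
})

test_that("per-lead QT order never affects the outputs", {
  set.seed(12)
  v <- c(rnorm(40, 400, 6), 470, 330)
  cfg <- repol_config()
  e1 <- lead_qt_estimate(robust_filter(v, cfg), 60, cfg)
  e2 <- lead_qt_estimate(robust_filter(sample(v), cfg), 60, cfg)
  expect_equal(e1$qt_median_ms, e2$qt_median_ms)
  expect_identical(e1$n_valid, e2$n_valid)
})
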
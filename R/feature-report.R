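# Feature assembly and reference-range screening.  No classifier or risk
# score is produced: the pipeline stops at the feature vector plus flags.

#' Shipped reference ranges for the extracted ECG features
#'
#' Conventional adult reference limits for the screened parameters: RR
#' 600--1000 ms, SDNN > 50 ms, QT 350--440 ms, QTc below 450 ms (men) /
#' 470 ms (women), QT dispersion below 50 ms, T amplitude 0.1--0.5 mV and
#' ST deviation within +/-0.1 mV.  One-sided `<`/`>` limits are exclusive
#' (450 ms is out of range); two-sided spans and the ST band are inclusive.
#'
#' @return tibble with columns `parameter`, `sex` (`NA` = any), `lower`,
#'   `upper`, `lower_strict`, `upper_strict`, `units`.
#' @export
reference_ranges <- function() {
  tibble::tribble(
    ~parameter,       ~sex,     ~lower, ~upper, ~lower_strict, ~upper_strict, ~units,
    "rr_mean_ms",     NA,          600,   1000, FALSE,         FALSE,         "ms",
    "sdnn_ms",        NA,           50,     NA, TRUE,          NA,            "ms",
    "qt_ms",          NA,          350,    440, FALSE,         FALSE,         "ms",
    "qtc_ms",         "male",       NA,    450, NA,            TRUE,          "ms",
    "qtc_ms",         "female",     NA,    470, NA,            TRUE,          "ms",
    "qtd_ms",         NA,           NA,     50, NA,            TRUE,          "ms",
    "t_amplitude_mv", NA,          0.1,    0.5, FALSE,         FALSE,         "mV",
    "st_shift_mv",    NA,         -0.1,    0.1, FALSE,         FALSE,         "mV"
  )
}

#' Assemble the feature vector of one posture recording
#'
#' Copies the rhythm, morphology (lead II medians) and repolarization
#' metrics into one row.  `NA` upstream stays `NA` here -- nothing is
#' imputed.
#'
#' @param rhythm one-row tibble from [rhythm_metrics()].
#' @param morph one-row tibble from [morphology_metrics()] (lead II).
#' @param repol a `repol_summary` from [analyze_repolarization()].
#' @param posture posture label carried through.
#' @param recording_id identifier carried through.
#' @return one-row tibble: `recording_id`, `posture`, `hr_bpm`, `sdnn_ms`,
#'   `rr_mean_s`, `p_duration_ms`, `qrs_width_ms`, `t_amplitude_mv`,
#'   `st_shift_mv`, `qt_ms`, `qtc_ms`, `qtd_ms`.
#' @export
build_feature_vector <- function(rhythm, morph, repol,
                                 posture = NA_character_,
                                 recording_id = NA_character_) {
  tibble::tibble(
    recording_id = recording_id,
    posture = posture,
    hr_bpm = rhythm$hr_bpm,
    sdnn_ms = rhythm$sdnn_ms,
    rr_mean_s = rhythm$rr_mean_s,
    p_duration_ms = morph$p_duration_ms,
    qrs_width_ms = morph$qrs_width_ms,
    t_amplitude_mv = morph$t_amplitude_mv,
    st_shift_mv = morph$st_shift_mv,
    qt_ms = repol$qt_ms,
    qtc_ms = repol$qtc_ms,
    qtd_ms = repol$qtd_ms
  )
}

flag_one <- function(value, row) {
  if (is.na(value)) return("not_assessed")
  low <- if (!is.na(row$lower)) {
    if (isTRUE(row$lower_strict)) value <= row$lower else value < row$lower
  } else FALSE
  high <- if (!is.na(row$upper)) {
    if (isTRUE(row$upper_strict)) value >= row$upper else value > row$upper
  } else FALSE
  if (low) "out_low" else if (high) "out_high" else "in_range"
}

#' Screen a feature vector against the reference ranges
#'
#' Pure threshold comparison; `NA` features come back `not_assessed`.  The
#' sex-dependent QTc bound is applied when `sex` is given, otherwise the
#' stricter (male) bound is used so that an unknown sex can never produce
#' false reassurance.
#'
#' @param features one-row tibble from [build_feature_vector()].
#' @param ranges reference table, default [reference_ranges()].
#' @param sex `"male"`, `"female"`, or `NULL` (unknown).
#' @return tibble: `parameter`, `value`, `flag`
#'   (`in_range` / `out_low` / `out_high` / `not_assessed`).
#' @export
flag_against_reference <- function(features, ranges = reference_ranges(),
                                   sex = NULL) {
  stopifnot(nrow(features) == 1L)
  vals <- c(
    rr_mean_ms = features$rr_mean_s * 1000,
    sdnn_ms = features$sdnn_ms,
    qt_ms = features$qt_ms,
    qtc_ms = features$qtc_ms,
    qtd_ms = features$qtd_ms,
    t_amplitude_mv = features$t_amplitude_mv,
    st_shift_mv = features$st_shift_mv
  )
  purrr::map_dfr(names(vals), function(p) {
    rows <- ranges[ranges$parameter == p, ]
    if (nrow(rows) == 0)
      stop("no reference range for parameter: ", p, call. = FALSE)
    if (nrow(rows) > 1) {       # sex-dependent bound
      pick <- if (!is.null(sex)) sex else "male"   # stricter default
      if (!pick %in% rows$sex)
        stop("no ", pick, " bound for parameter: ", p, call. = FALSE)
      rows <- rows[which(rows$sex == pick), ]
    }
    tibble::tibble(parameter = p, value = unname(vals[p]),
                   flag = flag_one(vals[[p]], rows[1, ]))
  })
}

#' Beat-level T-end agreement statistics
#'
#' Pairwise differences `expert - automatic` (positive = the expert places
#' the T end later), summarised as the mean displacement, the mean absolute
#' error and the sample standard deviation (N - 1), all in ms.
#'
#' @param expert_ms expert T-end positions (ms), paired by beat.
#' @param auto_ms automatic T-end positions (ms), same length.
#' @return one-row tibble: `n_beats`, `mean_ms`, `mae_ms`, `sd_ms`, with
#'   the individual differences in list-column `deltas_ms`.
#' @export
#' @examples
#' tend_agreement(c(398, 402), c(400, 400))  # mean 0, MAE 2, SD ~2.83
tend_agreement <- function(expert_ms, auto_ms) {
  if (length(expert_ms) != length(auto_ms))
    stop("expert and automatic positions must be paired by beat",
         call. = FALSE)
  d <- expert_ms - auto_ms
  tibble::tibble(
    n_beats = length(d),
    mean_ms = mean(d),
    mae_ms = mean(abs(d)),
    sd_ms = if (length(d) >= 2) stats::sd(d) else 0,
    deltas_ms = list(d)
  )
}
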
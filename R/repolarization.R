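# Multi-lead ventricular repolarization analysis.  QT is measured on every
# cardiac cycle (Q onset to T end); per lead, robust outlier filtering
# (MAD with IQR fallback) precedes the median QT estimate; a lead enters
# the dispersion calculation only with enough valid cycles (N >= 30 or
# >= 50% of all cycles in the fragment); QT dispersion = max - min of the
# eligible per-lead medians, reported only when at least 6 leads qualify,
# otherwise NA.  QTc uses Bazett's correction with the fragment-mean RR.

#' Repolarization analysis configuration
#'
#' @param min_valid_cycles a lead is eligible with at least this many
#'   retained QT values (default 30)...
#' @param min_valid_fraction ...or with at least this fraction of all
#'   cycles in the fragment retained (default 0.5). Either branch suffices.
#' @param min_eligible_leads dispersion is `NA` with fewer eligible leads
#'   (default 6).
#' @param outlier_method `"mad"` (default; falls back to IQR when the MAD
#'   is zero) or `"iqr"`.
#' @param mad_k MAD-rule multiplier (default 3): drop `x` with
#'   `|x - median| > mad_k * 1.4826 * MAD`.
#' @param iqr_k Tukey-fence multiplier (default 1.5).
#' @param leads_considered leads entering the dispersion calculation
#'   (default the transmitted set I, II, V1--V6).
#' @return a `repol_config` list.
#' @export
repol_config <- function(min_valid_cycles = 30L, min_valid_fraction = 0.5,
                         min_eligible_leads = 6L,
                         outlier_method = c("mad", "iqr"),
                         mad_k = 3, iqr_k = 1.5,
                         leads_considered = LEADS_8) {
  outlier_method <- match.arg(outlier_method)
  stopifnot(min_valid_cycles > 0, min_valid_fraction > 0,
            min_eligible_leads > 0, mad_k > 0, iqr_k > 0)
  structure(list(min_valid_cycles = as.integer(min_valid_cycles),
                 min_valid_fraction = min_valid_fraction,
                 min_eligible_leads = as.integer(min_eligible_leads),
                 outlier_method = outlier_method,
                 mad_k = mad_k, iqr_k = iqr_k,
                 leads_considered = leads_considered),
            class = "repol_config")
}

#' Per-beat QT intervals
#'
#' `(t_end - q_onset) / fs * 1000` for every valid annotated beat; excluded
#' beats yield no value (absence, not an error).
#'
#' @param beats annotation tibble from [delineate_lead()].
#' @param fs sampling rate (Hz).
#' @return numeric vector of QT values in ms (one per valid beat).
#' @export
beat_qt <- function(beats, fs = 500) {
  use <- beats$valid & !is.na(beats$q_onset) & !is.na(beats$t_end)
  (beats$t_end[use] - beats$q_onset[use]) / fs * 1000
}

#' Robust outlier filtering of per-beat QT values
#'
#' MAD rule: drop `x` with `|x - median(x)| > mad_k * 1.4826 * MAD`; when
#' the MAD collapses to zero, fall back to the IQR (Tukey fence) rule:
#' keep `x` within `[Q1 - iqr_k * IQR, Q3 + iqr_k * IQR]`. Order preserved.
#'
#' @param qt_values numeric vector (ms).
#' @param cfg a [repol_config()].
#' @return the retained subsequence.
#' @export
#' @examples
#' robust_filter(c(rep(380, 29), 600))  # the 600 ms outlier is dropped
robust_filter <- function(qt_values, cfg = repol_config()) {
  if (!length(qt_values)) return(qt_values)
  method <- cfg$outlier_method
  if (method == "mad") {
    m <- stats::median(qt_values)
    s <- stats::mad(qt_values)           # already scaled by 1.4826
    if (s > 0)
      return(qt_values[abs(qt_values - m) <= cfg$mad_k * s])
    # MAD degenerate -> IQR fallback
  }
  q <- stats::quantile(qt_values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  qt_values[qt_values >= q[1] - cfg$iqr_k * iqr &
            qt_values <= q[2] + cfg$iqr_k * iqr]
}

#' Per-lead QT estimate with eligibility
#'
#' A lead is eligible when the retained cycle count reaches
#' `min_valid_cycles` **or** `min_valid_fraction` of all cycles in the
#' fragment; the estimate is the median of the retained values.
#'
#' @param qt_values retained per-beat QT values (ms), i.e. the output of
#'   [robust_filter()].
#' @param n_total_cycles total cardiac cycles in the analysed fragment.
#' @param cfg a [repol_config()].
#' @return one-row tibble: `qt_median_ms` (or `NA`), `n_valid`, `n_total`,
#'   `eligible`, `ineligibility_reason` (`"none"` / `"insufficient_cycles"`).
#' @export
lead_qt_estimate <- function(qt_values, n_total_cycles,
                             cfg = repol_config()) {
  stopifnot(n_total_cycles >= 1)
  n_valid <- length(qt_values)
  eligible <- n_valid >= cfg$min_valid_cycles ||
    n_valid >= cfg$min_valid_fraction * n_total_cycles
  tibble::tibble(
    qt_median_ms = if (eligible) stats::median(qt_values) else NA_real_,
    n_valid = n_valid,
    n_total = as.integer(n_total_cycles),
    eligible = eligible,
    ineligibility_reason = if (eligible) "none" else "insufficient_cycles"
  )
}

#' QT dispersion across eligible leads
#'
#' `max - min` of the eligible per-lead QT medians; `NA` whenever fewer
#' than `min_eligible_leads` leads qualify, so a dispersion value is never
#' produced from insufficiently reliable data.
#'
#' @param per_lead tibble with columns `eligible` and `qt_median_ms` (one
#'   row per considered lead), e.g. rows of [lead_qt_estimate()].
#' @param cfg a [repol_config()].
#' @return QTd in ms, or `NA`.
#' @export
qt_dispersion <- function(per_lead, cfg = repol_config()) {
  el <- per_lead$qt_median_ms[per_lead$eligible]
  el <- el[!is.na(el)]
  if (length(el) < cfg$min_eligible_leads) return(NA_real_)
  max(el) - min(el)
}

#' Bazett heart-rate correction
#'
#' `QTc = QT / sqrt(RR)` with RR in seconds; QTc equals QT at RR = 1 s.
#'
#' @param qt_ms QT interval (ms).
#' @param rr_mean_s mean RR interval over the analysed fragment (s, > 0).
#' @return QTc in ms.
#' @export
#' @examples
#' bazett_qtc(400, 0.64)  # 500 ms
bazett_qtc <- function(qt_ms, rr_mean_s) {
  if (any(rr_mean_s <= 0, na.rm = TRUE))
    stop("RR must be positive for Bazett correction", call. = FALSE)
  qt_ms / sqrt(rr_mean_s)
}

#' Full repolarization analysis of one recording
#'
#' Composes per-beat QT measurement, robust filtering, the per-lead
#' eligibility/median estimate, and QT dispersion over the considered
#' leads.  The recording-level QT is the lead II median; the RR used for
#' Bazett's correction is the mean RR of the fragment (from the supplied
#' rhythm summary or recomputed from lead II peaks).  Postures are never
#' pooled: one summary describes one posture recording.
#'
#' @param rec a conditioned [lead_recording()] containing at least the
#'   considered leads.
#' @param beats_by_lead named list of annotation tibbles (one per
#'   considered lead), e.g. from [delineate_lead()].
#' @param rr_mean_s fragment-mean RR in seconds (from lead II rhythm).
#' @param cfg a [repol_config()].
#' @return a `repol_summary`: list with `per_lead` (tibble: lead,
#'   qt_median_ms, n_valid, n_total, eligible, ineligibility_reason, and
#'   retained values in list-column `qt_values_ms`), and scalars `qt_ms`,
#'   `qtc_ms`, `qtd_ms`, `rr_mean_s`, `n_eligible`.
#' @export
analyze_repolarization <- function(rec, beats_by_lead, rr_mean_s,
                                   cfg = repol_config()) {
  leads <- cfg$leads_considered
  missing <- setdiff(leads, names(beats_by_lead))
  if (length(missing))
    stop("no annotations for lead(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  per_lead <- purrr::map_dfr(leads, function(ld) {
    b <- beats_by_lead[[ld]]
    qt <- robust_filter(beat_qt(b, rec$fs), cfg)
    est <- lead_qt_estimate(qt, max(1L, nrow(b)), cfg)
    dplyr::mutate(est, lead = ld, qt_values_ms = list(qt), .before = 1)
  })
  qtd <- qt_dispersion(per_lead, cfg)
  qt_ms <- per_lead$qt_median_ms[per_lead$lead == "II"]
  qt_ms <- if (length(qt_ms)) qt_ms[1] else NA_real_
  qtc <- if (!is.na(qt_ms) && !is.na(rr_mean_s) && rr_mean_s > 0)
    bazett_qtc(qt_ms, rr_mean_s) else NA_real_
  structure(
    list(per_lead = per_lead, qt_ms = qt_ms, qtc_ms = qtc, qtd_ms = qtd,
         rr_mean_s = rr_mean_s, n_eligible = sum(per_lead$eligible),
         config = cfg),
    class = "repol_summary")
}

#' @export
print.repol_summary <- function(x, ...) {
  cat("<repol_summary>\n")
  cat(sprintf("  QT (lead II): %s ms   QTc (Bazett): %s ms   QTd: %s ms\n",
              fmt_na(x$qt_ms), fmt_na(x$qtc_ms), fmt_na(x$qtd_ms)))
  cat(sprintf("  eligible leads: %d of %d considered\n",
              x$n_eligible, nrow(x$per_lead)))
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", v)

#' Tidy / glance methods for repolarization summaries
#'
#' `tidy()` returns the per-lead table (one row per considered lead);
#' `glance()` the one-row recording-level summary.
#'
#' @param x a `repol_summary` from [analyze_repolarization()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.repol_summary <- function(x, ...) {
  dplyr::select(x$per_lead, "lead", "qt_median_ms", "n_valid", "n_total",
                "eligible", "ineligibility_reason")
}

#' @rdname tidy.repol_summary
#' @export
glance.repol_summary <- function(x, ...) {
  tibble::tibble(qt_ms = x$qt_ms, qtc_ms = x$qtc_ms, qtd_ms = x$qtd_ms,
                 rr_mean_s = x$rr_mean_s, n_eligible = x$n_eligible)
}
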
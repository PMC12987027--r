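# Session orchestration: decode -> lead-off mask -> derive -> condition ->
# detect -> delineate -> repolarization -> feature vector, with stage
# counters and no silent drops (every excluded beat and ineligible lead
# carries a reason in the record).

#' Analysis configuration for a session
#'
#' @param fs sampling rate in Hz (default 500).
#' @param mains_hz mains frequency for the notch, 50 or 60 (default 50).
#' @param filter a [filter_spec()]; the notch defaults to `mains_hz`.
#' @param delineation a [delineation_config()].
#' @param repol a [repol_config()].
#' @param leadoff_guard_s guard band around lead-off runs (s).
#' @return an `analysis_config` list; the complete snapshot is stored in
#'   every session record so a run can be reproduced exactly.
#' @export
analysis_config <- function(fs = 500, mains_hz = 50,
                            filter = filter_spec(notch_hz = mains_hz),
                            delineation = delineation_config(),
                            repol = repol_config(),
                            leadoff_guard_s = 0.25) {
  structure(list(fs = fs, mains_hz = mains_hz, filter = filter,
                 delineation = delineation, repol = repol,
                 leadoff_guard_s = leadoff_guard_s),
            class = "analysis_config")
}

leadoff_pauses <- function(off, fs) {
  if (is.null(off) || !any(off)) {
    return(tibble::tibble(channel = character(0), start_s = numeric(0),
                          end_s = numeric(0), cause = character(0)))
  }
  purrr::map_dfr(colnames(off), function(ch) {
    r <- rle(off[, ch])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    tibble::tibble(channel = ch,
                   start_s = (starts[on] - 1) / fs,
                   end_s = ends[on] / fs,
                   cause = "lead_off")
  })
}

#' Run the full analysis pipeline on one posture recording
#'
#' Accepts a raw packet stream (raw vector or binary file path), a CSV
#' sample matrix written by [write_recording_csv()], a [lead_recording()],
#' or the output of [generate_recording()].  Executes decode, lead-off
#' masking, 12-lead derivation, conditioning, R-peak detection, per-lead
#' delineation, repolarization analysis and feature assembly, and returns
#' a self-describing session record.  Total signal loss yields an all-`NA`
#' feature vector, never an error.
#'
#' @param input see above.
#' @param config an [analysis_config()].
#' @param posture posture label (postures are analysed separately, never
#'   pooled).
#' @param recording_id identifier stored in the record (default a
#'   timestamp-derived string).
#' @return a `session_record`: list with `features` (one-row tibble),
#'   `repol` (a `repol_summary`), `rhythm`, `morphology` (per-lead tibble),
#'   `beats` (all annotations, `lead` column), `pauses`, `counts` (stage
#'   counters incl. per-reason exclusion tallies), `config`, `source`,
#'   `posture`, `session_id`.
#' @export
run_analysis <- function(input, config = analysis_config(),
                         posture = NA_character_, recording_id = NULL) {
  counts <- list()
  source_desc <- "recording"
  frames <- NULL

  if (is.character(input)) {
    if (!file.exists(input) || file.size(input) == 0)
      stop("unreadable or empty input file: ", input, call. = FALSE)
    source_desc <- input
    input <- if (grepl("\\.csv$", input, ignore.case = TRUE))
      read_recording_csv(input) else read_stream_file(input)
  }
  if (is.list(input) && !inherits(input, "lead_recording") &&
      !is.null(input$recording)) {
    source_desc <- "synthetic"
    input <- input$recording
  }
  if (is.raw(input)) {
    if (source_desc == "recording") source_desc <- "stream"
    frames <- resync_stream(input)
    counts$frames <- nrow(frames$counts)
    counts$discarded_bytes <- frames$discard_count
    if (counts$frames == 0)
      stop("no decodable frames in stream input", call. = FALSE)
    rec <- lead_recording(
      counts_to_microvolts(frames$counts), fs = config$fs)
    rec <- apply_leadoff_mask(rec, frames, guard_s = config$leadoff_guard_s)
  } else if (inherits(input, "lead_recording")) {
    rec <- input
  } else {
    stop("unsupported input type", call. = FALSE)
  }
  pauses <- leadoff_pauses(if (!is.null(frames)) frames$leadoff, config$fs)

  rec12 <- if (all(LEADS_12 %in% lead_names(rec))) rec
           else derive_12_from_channels(rec)
  cond <- condition(rec12, config$filter)

  lead2 <- lead_signal(cond, "II")
  peaks <- tryCatch(detect_r_peaks(lead2, fs = config$fs),
                    error = function(e) integer(0))
  counts$r_peaks <- length(peaks)
  rhythm <- rhythm_metrics(peaks, fs = config$fs)

  leads_used <- union(config$repol$leads_considered, "II")
  beats_by_lead <- lapply(stats::setNames(leads_used, leads_used),
                          function(ld) {
    delineate_lead(lead_signal(cond, ld), peaks, fs = config$fs,
                   cfg = config$delineation)
  })
  beats_all <- purrr::map_dfr(leads_used, function(ld)
    dplyr::mutate(beats_by_lead[[ld]], lead = ld, .before = 1))
  counts$exclusions <- if (nrow(beats_all))
    as.list(table(beats_all$exclusion_reason[!beats_all$valid])) else list()

  repol <- analyze_repolarization(cond, beats_by_lead,
                                  rr_mean_s = rhythm$rr_mean_s,
                                  cfg = config$repol)
  morph_by_lead <- purrr::map_dfr(leads_used, function(ld)
    dplyr::mutate(
      morphology_metrics(beats_by_lead[[ld]], lead_signal(cond, ld),
                         fs = config$fs),
      lead = ld, .before = 1))
  morph2 <- dplyr::filter(morph_by_lead, .data$lead == "II")

  if (is.null(recording_id))
    recording_id <- format(Sys.time(), "session-%Y%m%d-%H%M%OS3")
  features <- build_feature_vector(rhythm, morph2, repol,
                                   posture = posture,
                                   recording_id = recording_id)
  structure(
    list(session_id = recording_id, posture = posture,
         source = source_desc, features = features, repol = repol,
         rhythm = rhythm, morphology = morph_by_lead, beats = beats_all,
         pauses = pauses, counts = counts, config = config),
    class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s (%s)\n", x$session_id, x$source))
  cat(sprintf("  beats: %d   pauses: %d\n",
              x$rhythm$n_beats, nrow(x$pauses)))
  f <- x$features
  cat(sprintf("  HR %s bpm  QT %s ms  QTc %s ms  QTd %s ms\n",
              fmt_na(f$hr_bpm), fmt_na(f$qt_ms), fmt_na(f$qtc_ms),
              fmt_na(f$qtd_ms)))
  invisible(x)
}

#' @rdname run_analysis
#' @param x a `session_record`.
#' @param ... unused.
#' @export
glance.session_record <- function(x, ...) x$features

#' @rdname run_analysis
#' @export
tidy.session_record <- function(x, ...) {
  tidyr::pivot_longer(x$features, -c("recording_id", "posture"),
                      names_to = "parameter", values_to = "value",
                      values_transform = as.numeric)
}

#' Export / import a session record
#'
#' `format = "json"` writes the full record (features, per-lead
#' repolarization details, beats, pauses, counters, config snapshot) with
#' `NA` rendered as `null`; `format = "csv"` writes the feature vector with
#' `NA` as empty cells.  `read_session_json()` restores the JSON export
#' (as plain lists/tibbles) with `NA` intact.
#'
#' @param record a `session_record` from [run_analysis()].
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_record <- function(record, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "session_record"))
  if (format == "csv") {
    readr::write_csv(record$features, path, na = "")
  } else {
    payload <- list(
      session_id = record$session_id,
      posture = record$posture,
      source = record$source,
      features = record$features,
      per_lead = record$repol$per_lead,
      qtd_ms = record$repol$qtd_ms,
      rhythm = record$rhythm[, c("n_beats", "hr_bpm", "rr_mean_s", "sdnn_ms")],
      morphology = record$morphology,
      pauses = record$pauses,
      counts = record$counts,
      config = unclass_deep(record$config)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
  }
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname export_record
#' @export
read_session_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
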
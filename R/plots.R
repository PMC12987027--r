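#' Plot a multichannel recording
#'
#' One facet per lead, time on the x axis, microvolts on the y axis;
#' invalid samples are left as gaps.
#'
#' @param object a [lead_recording()].
#' @param leads leads to show (default all).
#' @param t_lim optional `c(from_s, to_s)` time window.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lead_recording <- function(object, leads = lead_names(object),
                                    t_lim = NULL, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, .data$lead %in% leads)
  if (!is.null(t_lim))
    df <- dplyr::filter(df, .data$time_s >= t_lim[1], .data$time_s <= t_lim[2])
  df$uv[!df$valid] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$uv)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lead), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot one lead with its beat fiducials
#'
#' The conditioned signal with Q onset, J point, T peak and T end marked
#' for every annotated beat; excluded beats are shown in a muted colour.
#'
#' @param rec a conditioned [lead_recording()].
#' @param beats annotation tibble from [delineate_lead()].
#' @param lead lead name.
#' @param t_lim optional time window in seconds.
#' @return a ggplot object.
#' @export
plot_beats <- function(rec, beats, lead = "II", t_lim = NULL) {
  x <- lead_signal(rec, lead)
  df <- tibble::tibble(time_s = (seq_along(x) - 1) / rec$fs, uv = x)
  fid <- tidyr::pivot_longer(
    beats[, c("r_index", "q_onset", "qrs_offset", "t_peak", "t_end", "valid")],
    -"valid", names_to = "fiducial", values_to = "index")
  fid <- dplyr::filter(fid, !is.na(.data$index))
  fid$time_s <- (fid$index - 1) / rec$fs
  fid$uv <- x[fid$index]
  if (!is.null(t_lim)) {
    df <- dplyr::filter(df, .data$time_s >= t_lim[1], .data$time_s <= t_lim[2])
    fid <- dplyr::filter(fid, .data$time_s >= t_lim[1], .data$time_s <= t_lim[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$uv)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_point(
      data = fid,
      ggplot2::aes(colour = .data$fiducial, alpha = .data$valid),
      size = 1.6, na.rm = TRUE) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::labs(x = "time (s)", y = sprintf("%s (µV)", lead)) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot per-lead QT estimates of a repolarization summary
#'
#' Eligible leads carry their median QT; ineligible leads are greyed out.
#' The QTd span (max - min over eligible leads) is shaded when reported.
#'
#' @param object a `repol_summary` from [analyze_repolarization()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.repol_summary <- function(object, ...) {
  df <- object$per_lead
  df$lead <- factor(df$lead, levels = df$lead)
  p <- ggplot2::ggplot(df,
    ggplot2::aes(.data$lead, .data$qt_median_ms, fill = .data$eligible)) +
    ggplot2::geom_col(na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "per-lead QT median (ms)",
                  subtitle = sprintf("QT %s ms, QTc %s ms, QTd %s ms",
                                     fmt_na(object$qt_ms),
                                     fmt_na(object$qtc_ms),
                                     fmt_na(object$qtd_ms))) +
    ggplot2::theme_minimal(base_size = 9)
  el <- df$qt_median_ms[df$eligible]
  if (!is.na(object$qtd_ms) && length(el))
    p <- p + ggplot2::geom_hline(yintercept = range(el),
                                 linetype = "dashed", colour = "grey40")
  p
}
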
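#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ECG trace
#'
#' @param object an [ecg_record()].
#' @param from_s,to_s time window to display (defaults to the first 10 s).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ecg_record
#' @export
autoplot.ecg_record <- function(object, from_s = NULL, to_s = NULL, ...) {
  from_s <- from_s %||% object$time_s[1]
  to_s <- to_s %||% min(max(object$time_s), from_s + 10)
  dat <- dplyr::filter(object, .data$time_s >= from_s, .data$time_s <= to_s)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_s, .data$ecg_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "ECG (mV)") +
    ggplot2::theme_minimal()
}

#' Direction pattern matrix
#'
#' The participants x parameters direction matrix for one or all segments,
#' colour-coded increase/decrease/equality — the per-participant pattern
#' view that the cohort percentages summarise.
#'
#' @param x an [analyze_cohort()] result, an `ecg_score_report`, or a tidy
#'   direction tibble `participant, segment, parameter, direction`.
#' @param segments segment ids to include (default all).
#' @return a ggplot.
#' @export
plot_direction_matrix <- function(x, segments = NULL) {
  dm <- if (inherits(x, "ecg_cohort_analysis")) x$report$direction_matrix
  else if (inherits(x, "ecg_score_report")) x$direction_matrix
  else x
  if (!is.null(segments)) dm <- dm[dm$segment %in% segments, ]
  dm <- dplyr::mutate(dm,
    parameter = factor(.data$parameter, levels = stat_parameters()),
    direction = factor(.data$direction, levels = c("I", "D", "E")))
  ggplot2::ggplot(dm, ggplot2::aes(.data$parameter,
                                   factor(.data$participant),
                                   fill = .data$direction)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~segment) +
    ggplot2::scale_fill_manual(
      values = c(I = "#d95f02", D = "#1b9e77", E = "#cccccc"),
      drop = FALSE) +
    ggplot2::labs(x = "statistical parameter", y = "participant",
                  fill = "direction") +
    ggplot2::theme_minimal()
}

#' @rdname plot_direction_matrix
#' @param object an [analyze_cohort()] result.
#' @param ... passed to [plot_direction_matrix()].
#' @method autoplot ecg_cohort_analysis
#' @export
autoplot.ecg_cohort_analysis <- function(object, ...) {
  plot_direction_matrix(object, ...)
}

#' @rdname plot_direction_matrix
#' @method autoplot ecg_score_report
#' @export
autoplot.ecg_score_report <- function(object, ...) {
  plot_direction_matrix(object, ...)
}

#' Paired G/NG spectra overlay
#'
#' Welch PSD of the G and NG series of one segment, one panel per
#' participant.
#'
#' @param segments long segment tibble.
#' @param segment segment id to plot.
#' @param participants participants to include (default all).
#' @param config a [welch_config()].
#' @return a ggplot.
#' @export
plot_psd_overlay <- function(segments, segment = "RR-I", participants = NULL,
                             config = welch_config()) {
  dat <- segments[segments$segment == segment, ]
  if (!is.null(participants))
    dat <- dat[dat$participant %in% participants, ]
  psd <- cohort_psd(dat, config)
  ggplot2::ggplot(psd, ggplot2::aes(.data$frequency, .data$power,
                                    colour = .data$session)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~participant, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(G = "#2166ac", NG = "#d6a820")) +
    ggplot2::labs(title = paste("Welch PSD,", segment),
                  x = "frequency", y = "power") +
    ggplot2::theme_minimal()
}

#' Paired G/NG boxplots of segment series
#'
#' @param segments long segment tibble.
#' @param participant participant id to display.
#' @param segs segment ids (default the three headline series).
#' @return a ggplot.
#' @export
plot_paired_box <- function(segments, participant,
                            segs = c("RR-I", "HR", "ST")) {
  dat <- segments[segments$participant == participant &
                    segments$segment %in% segs, ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$session, .data$value,
                                    fill = .data$session)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_wrap(~segment, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
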
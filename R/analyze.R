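#' Full paired-cohort analysis
#'
#' Runs the complete analysis chain on a long segment table containing the G
#' and NG series of every participant: per-session boxplot summaries, paired
#' deltas with direction labels, inter-segment correlations of the glucose
#' session, Welch spectral peak directions, and the cohort scoring layer
#' (direction tallies, status bands, change decisions, sensitivities).
#'
#' @param segments long tibble `participant, session, beat_index, time_s,
#'   segment, value` with sessions `"G"` and `"NG"`.
#' @param equal_tol equality band for delta directions; `NULL` uses each
#'   segment's measurement resolution.
#' @param welch a [welch_config()].
#' @param spectral compute the spectral comparison (default `TRUE`).
#' @param correlations compute inter-segment correlations (default `TRUE`).
#' @return object of class `ecg_cohort_analysis`: a list with `summaries`,
#'   `deltas`, `spectral`, `correlations` and `report` (an
#'   `ecg_score_report`).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(2, session_config(duration_s = 600))
#' fit <- analyze_cohort(cohort_segments(cohort))
#' tidy(fit)
#' }
#' @export
analyze_cohort <- function(segments, equal_tol = NULL,
                           welch = welch_config(), spectral = TRUE,
                           correlations = TRUE) {
  summaries <- summarize_segments(segments)
  deltas <- paired_deltas(summaries, equal_tol)
  spec <- if (spectral) spectral_directions(segments, welch) else NULL
  corr <- if (correlations) correlate_segments(segments) else NULL
  report <- build_report(deltas, spec, corr)
  structure(list(summaries = summaries, deltas = deltas, spectral = spec,
                 correlations = corr, report = report,
                 n_participants = dplyr::n_distinct(segments$participant)),
            class = "ecg_cohort_analysis")
}

#' @export
print.ecg_cohort_analysis <- function(x, ...) {
  cat("Paired ECG cohort analysis (", x$n_participants, " participants)\n",
      sep = "")
  print(x$report)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the change decisions of a cohort analysis
#'
#' One row per segment and analysis type, with the decision evidence: the
#' moderate+strong occurrence score (statistical) or the dominant-pattern
#' percentage (spectral), and the Yes/No change call.
#'
#' @param x an [analyze_cohort()] result.
#' @param ... unused.
#' @return tibble `segment, analysis, pattern, score, pct, status, change`.
#' @method tidy ecg_cohort_analysis
#' @export
tidy.ecg_cohort_analysis <- function(x, ...) {
  rep <- x$report
  stat <- rep$stat_decisions %>%
    dplyr::mutate(analysis = "statistical", pattern = NA_character_,
                  pct = NA_real_, status = NA_character_) %>%
    dplyr::select("segment", "analysis", "pattern", score = "total",
                  "pct", "status", "change")
  out <- stat
  if (!is.null(rep$spectral_table)) {
    spec <- rep$spectral_table %>%
      dplyr::mutate(analysis = "spectral", score = NA_integer_,
                    pct = round_half_up(.data$pct)) %>%
      dplyr::select("segment", "analysis", "pattern", "score", "pct",
                    "status", "change")
    out <- dplyr::bind_rows(stat, spec)
  }
  dplyr::arrange(out, .data$analysis, .data$segment)
}

#' One-line summary of a cohort analysis
#'
#' @inheritParams tidy.ecg_cohort_analysis
#' @return one-row tibble: participants, segments analysed and how many were
#'   called affected by each analysis.
#' @method glance ecg_cohort_analysis
#' @export
glance.ecg_cohort_analysis <- function(x, ...) {
  rep <- x$report
  tibble::tibble(
    n_participants = x$n_participants,
    n_segments = dplyr::n_distinct(rep$stat_decisions$segment),
    n_stat_yes = sum(rep$stat_decisions$change == "Yes"),
    n_spectral_yes = if (is.null(rep$spectral_table)) NA_integer_
    else sum(rep$spectral_table$change == "Yes")
  )
}

#' Segments called affected by glucose
#'
#' @param x an [analyze_cohort()] result.
#' @param analysis `"statistical"`, `"spectral"` or `"both"` (intersection).
#' @return character vector of segment ids with a `"Yes"` change decision.
#' @export
affected_segments <- function(x, analysis = c("statistical", "spectral",
                                              "both")) {
  analysis <- match.arg(analysis)
  rep <- x$report
  stat <- rep$stat_decisions$segment[rep$stat_decisions$change == "Yes"]
  if (analysis == "statistical") return(sort(stat))
  if (is.null(rep$spectral_table)) stop("no spectral analysis in this object")
  spec <- rep$spectral_table$segment[rep$spectral_table$change == "Yes"]
  if (analysis == "spectral") return(sort(spec))
  sort(intersect(stat, spec))
}
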
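#' Tally per-participant directions
#'
#' Counts increase/decrease/equality labels across a cohort and computes the
#' percentage of each direction (count over the total observable change,
#' times 100). Equality labels are counted in the denominator. Percentages
#' are returned exact; reports round them half-up to integers (13/16 prints
#' as 81%).
#'
#' @param directions character vector of `"I"`, `"D"`, `"E"` labels, one per
#'   participant.
#' @return one-row tibble: `n_I, n_D, n_E, n, pct_I, pct_D, pct_E`.
#' @export
tally_directions <- function(directions) {
  stopifnot(length(directions) >= 1, all(directions %in% c("I", "D", "E")))
  n <- length(directions)
  n_i <- sum(directions == "I")
  n_d <- sum(directions == "D")
  n_e <- n - n_i - n_d
  tibble::tibble(n_I = n_i, n_D = n_d, n_E = n_e, n = n,
                 pct_I = 100 * n_i / n, pct_D = 100 * n_d / n,
                 pct_E = 100 * n_e / n)
}

#' Classify a cohort percentage into a status band
#'
#' `"h"` (strong pattern) for percentages in \[80, 100\], `"m"` (moderate,
#' above-average occurrence) in \[60, 80), `"l"` (weak) otherwise. Boundaries
#' are inclusive at 80 and 60. Classification uses the exact percentage, not
#' its rounded display value.
#'
#' @param percent numeric vector in \[0, 100\].
#' @return character vector of `"h"`, `"m"`, `"l"`.
#' @export
classify_status <- function(percent) {
  stopifnot(all(percent >= 0 & percent <= 100))
  dplyr::case_when(percent >= 80 ~ "h", percent >= 60 ~ "m", TRUE ~ "l")
}

# dominant direction of a tally: the direction with the highest percentage,
# ties broken D, then I, then E (decrease listed first, as in the published
# tables)
dominant_direction <- function(tally) {
  pcts <- c(D = tally$pct_D, I = tally$pct_I, E = tally$pct_E)
  lab <- names(pcts)[which.max(pcts)]
  tibble::tibble(pattern = lab, pct = unname(pcts[lab]))
}

#' Statistical change decision for one segment
#'
#' Counts the moderate and strong statuses among the six scored boxplot
#' parameters; the segment is declared affected (`"Yes"`) when the total
#' occurrence score reaches 4 of the maximum 6. When `patterns` is supplied,
#' only parameters whose dominant pattern is directional (I or D) contribute
#' to the score: an equality-dominated parameter signals no change.
#'
#' @param statuses character vector of exactly 6 status labels
#'   (`"h"`/`"m"`/`"l"`), one per scored parameter.
#' @param patterns optional character vector of the parameters' dominant
#'   patterns (`"I"`/`"D"`/`"E"`).
#' @return one-row tibble: `n_m`, `n_h`, `total`, `change` (`"Yes"`/`"No"`).
#' @export
statistical_change_decision <- function(statuses, patterns = NULL) {
  if (length(statuses) != 6)
    stop("expected 6 parameter statuses, got ", length(statuses))
  stopifnot(all(statuses %in% c("h", "m", "l")))
  directional <- if (is.null(patterns)) rep(TRUE, 6)
  else patterns %in% c("I", "D")
  n_m <- sum(statuses == "m" & directional)
  n_h <- sum(statuses == "h" & directional)
  total <- n_m + n_h
  tibble::tibble(n_m = n_m, n_h = n_h, total = total,
                 change = if (total >= 4) "Yes" else "No")
}

#' Spectral change decision for one segment
#'
#' The segment is declared affected when the occurrence percentage of its
#' dominant directional pattern (increase or decrease) reaches 60%
#' (inclusive).
#'
#' @param tally a [tally_directions()] row of spectral-peak directions.
#' @return one-row tibble: `pattern`, `pct`, `status`, `change`.
#' @export
spectral_change_decision <- function(tally) {
  pct_dir <- max(tally$pct_I, tally$pct_D)
  pattern <- if (tally$pct_D >= tally$pct_I) "D" else "I"
  tibble::tibble(pattern = pattern, pct = pct_dir,
                 status = classify_status(pct_dir),
                 change = if (pct_dir >= 60) "Yes" else "No")
}

#' Sensitivity of a set of status labels
#'
#' The share of statuses carrying each label (strong/moderate/low), as
#' percentages rounded half-up to one decimal (5/6 prints as 83.3%). The
#' three shares sum to 100 before rounding.
#'
#' @param statuses character vector of `"h"`/`"m"`/`"l"`, length >= 1.
#' @return one-row tibble: `n`, `S_l`, `S_m`, `S_h` (percent).
#' @export
sensitivity <- function(statuses) {
  stopifnot(length(statuses) >= 1, all(statuses %in% c("h", "m", "l")))
  n <- length(statuses)
  tibble::tibble(
    n = n,
    S_l = round_half_up(100 * sum(statuses == "l") / n, 1),
    S_m = round_half_up(100 * sum(statuses == "m") / n, 1),
    S_h = round_half_up(100 * sum(statuses == "h") / n, 1))
}

#' Build the cohort score report
#'
#' Aggregates per-participant direction labels into the cohort-level score
#' tables: per-parameter direction tallies with status bands, the
#' statistical change decisions (score of moderate+strong statuses out of
#' 6), the spectral peak-direction table with its >= 60% change rule, the
#' per-pattern sensitivity tables for both analyses, and the participant x
#' parameter direction matrix.
#'
#' @param stat_directions tibble `participant, segment, parameter,
#'   direction` (e.g. from [paired_deltas()]).
#' @param spectral_directions optional tibble `participant, segment,
#'   direction` (from [spectral_directions()]).
#' @param correlations optional tibble from [correlate_segments()].
#' @return list of class `ecg_score_report` with elements `stat_tally`,
#'   `stat_decisions`, `stat_sensitivity`, `spectral_table`,
#'   `spectral_sensitivity`, `correlation_pct`, `direction_matrix`.
#' @export
build_report <- function(stat_directions, spectral_directions = NULL,
                         correlations = NULL) {
  stat_tally <- stat_directions %>%
    dplyr::group_by(.data$segment, .data$parameter) %>%
    dplyr::group_modify(function(.x, .y) {
      t <- tally_directions(.x$direction)
      dom <- dominant_direction(t)
      dplyr::bind_cols(t, dom) %>%
        dplyr::mutate(status = classify_status(.data$pct))
    }) %>%
    dplyr::ungroup()

  stat_decisions <- stat_tally %>%
    dplyr::group_by(.data$segment) %>%
    dplyr::group_modify(~ statistical_change_decision(.x$status, .x$pattern)) %>%
    dplyr::ungroup()

  stat_sensitivity <- stat_tally %>%
    dplyr::group_by(.data$segment, .data$pattern) %>%
    dplyr::group_modify(~ sensitivity(.x$status)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$segment, .data$pattern)

  spectral_table <- NULL
  spectral_sensitivity <- NULL
  if (!is.null(spectral_directions)) {
    spectral_table <- spectral_directions %>%
      dplyr::group_by(.data$segment) %>%
      dplyr::group_modify(function(.x, .y) {
        t <- tally_directions(.x$direction)
        dec <- spectral_change_decision(t)
        dplyr::bind_cols(t, dec)
      }) %>%
      dplyr::ungroup()
    spectral_sensitivity <- spectral_table %>%
      dplyr::group_by(.data$pattern) %>%
      dplyr::group_modify(~ sensitivity(.x$status)) %>%
      dplyr::ungroup()
  }

  correlation_pct <- if (!is.null(correlations))
    correlation_percentage(correlations) else NULL

  direction_matrix <- stat_directions %>%
    dplyr::select("participant", "segment", "parameter", "direction")

  structure(list(stat_tally = stat_tally,
                 stat_decisions = stat_decisions,
                 stat_sensitivity = stat_sensitivity,
                 spectral_table = spectral_table,
                 spectral_sensitivity = spectral_sensitivity,
                 correlation_pct = correlation_pct,
                 direction_matrix = direction_matrix),
            class = "ecg_score_report")
}

#' @export
print.ecg_score_report <- function(x, ...) {
  cat("ECG cohort score report\n")
  cat("Statistical change decisions:\n")
  print(x$stat_decisions, n = Inf)
  if (!is.null(x$spectral_table)) {
    cat("Spectral change decisions:\n")
    print(dplyr::select(x$spectral_table, "segment", "pattern", "pct",
                        "status", "change"), n = Inf)
  }
  invisible(x)
}
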
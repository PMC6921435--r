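#' Boxplot summary of one segment series
#'
#' The distribution of a per-beat segment series is described by six
#' statistics: mode, mean, median, first and third quartiles and the
#' interquartile range. Quartiles use linear interpolation between order
#' statistics (Q1 at rank 1 + (n-1)/4). Because the series are continuous
#' measurements, the mode is computed on values quantised to the segment's
#' measurement resolution ([segment_resolution()]): the most frequent
#' quantised value, ties broken towards the smallest.
#'
#' @param values numeric vector, at least 4 values.
#' @param segment segment id (sets the mode resolution); one of
#'   [segment_ids()].
#' @return one-row tibble: `segment`, `n`, `md`, `mn`, `mdn`, `q1`, `q3`, `iq`.
#' @examples
#' boxplot_summary(c(1, 2, 3, 4, 5), "QT")
#' @export
boxplot_summary <- function(values, segment) {
  if (length(values) < 4) stop("boxplot summary needs at least 4 values")
  stopifnot(is.numeric(values), !anyNA(values))
  res <- segment_resolution(segment)
  rounded <- round_half_up(values / res) * res
  counts <- table(rounded)
  best <- which(counts == max(counts))
  md <- min(as.numeric(names(counts)[best]))
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(segment = segment, n = length(values), md = md,
                 mn = mean(values), mdn = qs[2], q1 = qs[1], q3 = qs[3],
                 iq = qs[3] - qs[1])
}

#' Classify the direction of a paired delta
#'
#' Increase (`"I"`) when the glucose-minus-control delta exceeds the equality
#' band, decrease (`"D"`) when it falls below its negative, equality (`"E"`)
#' inside the band.
#'
#' @param delta numeric vector of G-minus-NG differences.
#' @param equal_tol half-width of the equality band, in the quantity's units.
#' @return character vector of `"I"`, `"D"`, `"E"`.
#' @export
classify_direction <- function(delta, equal_tol = 1e-9) {
  dplyr::case_when(delta >= equal_tol ~ "I",
                   delta <= -equal_tol ~ "D",
                   TRUE ~ "E")
}

#' Paired glucose-minus-control deltas of the boxplot statistics
#'
#' Computes the eight delta quantities between a glucose-session summary and
#' its matched control: the G-minus-NG differences of mode, mean, median, Q3
#' and Q1, the two within-session interquartile ranges, and their difference
#' (the IQR delta). A direction label is assigned to each of the six scored
#' parameters (md, mn, mdn, Q3, Q1, Q).
#'
#' @param g,ng one-row summaries from [boxplot_summary()] for the same
#'   segment (G and NG sessions respectively).
#' @param equal_tol equality band for direction classification; defaults to
#'   the segment's measurement resolution, below which two sessions are not
#'   considered to differ.
#' @return one-row tibble of class `delta_summary` with columns `segment`,
#'   the deltas `d_md`, `d_mn`, `d_mdn`, `d_q3`, `d_q1`, `iq_g`, `iq_ng`,
#'   `d_q`, and directions `dir_md`, `dir_mn`, `dir_mdn`, `dir_q3`,
#'   `dir_q1`, `dir_q`.
#' @export
delta_summary <- function(g, ng, equal_tol = NULL) {
  stopifnot(nrow(g) == 1, nrow(ng) == 1)
  if (!identical(g$segment, ng$segment))
    stop("summaries are for different segments: ", g$segment, " vs ", ng$segment)
  tol <- equal_tol %||% segment_resolution(g$segment)
  iq_g <- g$q3 - g$q1
  iq_ng <- ng$q3 - ng$q1
  out <- tibble::tibble(
    segment = g$segment,
    d_md = g$md - ng$md,
    d_mn = g$mn - ng$mn,
    d_mdn = g$mdn - ng$mdn,
    d_q3 = g$q3 - ng$q3,
    d_q1 = g$q1 - ng$q1,
    iq_g = iq_g, iq_ng = iq_ng,
    d_q = iq_g - iq_ng
  )
  for (p in stat_parameters())
    out[[paste0("dir_", tolower(p))]] <-
      classify_direction(out[[paste0("d_", tolower(p))]], tol)
  class(out) <- c("delta_summary", class(out))
  out
}

#' The six scored statistical parameters
#'
#' The boxplot parameters whose paired deltas are scored at cohort level:
#' mode, mean, median, third quartile, first quartile and the interquartile
#' range difference.
#' @return character vector `c("md","mn","mdn","q3","q1","q")`.
#' @export
stat_parameters <- function() c("md", "mn", "mdn", "q3", "q1", "q")

#' Per-session boxplot summaries of a long segment table
#'
#' @param segments long tibble `participant, session, beat_index, time_s,
#'   segment, value`.
#' @return tibble with one row per participant x session x segment.
#' @export
summarize_segments <- function(segments) {
  segments %>%
    dplyr::group_by(.data$participant, .data$session, .data$segment) %>%
    dplyr::group_modify(~ boxplot_summary(.x$value, .y$segment) %>%
                          dplyr::select(-"segment")) %>%
    dplyr::ungroup()
}

#' Paired deltas for a whole cohort, in long form
#'
#' Joins the G and NG summaries of every participant x segment and emits one
#' row per scored parameter.
#'
#' @param summaries output of [summarize_segments()] containing both
#'   sessions for every participant and segment.
#' @inheritParams delta_summary
#' @return tibble `participant, segment, parameter, delta, direction`.
#' @export
paired_deltas <- function(summaries, equal_tol = NULL) {
  have <- summaries %>%
    dplyr::group_by(.data$participant, .data$segment) %>%
    dplyr::summarise(ok = all(c("G", "NG") %in% .data$session),
                     .groups = "drop") %>%
    dplyr::filter(!.data$ok)
  if (nrow(have))
    stop("missing G or NG session for participant ", have$participant[1],
         " segment ", have$segment[1])
  wide <- summaries %>%
    tidyr::pivot_wider(id_cols = c("participant", "segment"),
                       names_from = "session",
                       values_from = c("md", "mn", "mdn", "q1", "q3"))
  missing <- wide[!stats::complete.cases(wide), ]
  if (nrow(missing))
    stop("missing G or NG session for participant ", missing$participant[1],
         " segment ", missing$segment[1])
  wide %>%
    dplyr::group_by(.data$participant, .data$segment) %>%
    dplyr::group_modify(function(.x, .y) {
      mk <- function(s) tibble::tibble(
        segment = .y$segment, md = .x[[paste0("md_", s)]],
        mn = .x[[paste0("mn_", s)]], mdn = .x[[paste0("mdn_", s)]],
        q1 = .x[[paste0("q1_", s)]], q3 = .x[[paste0("q3_", s)]])
      d <- delta_summary(mk("G"), mk("NG"), equal_tol)
      tibble::tibble(
        parameter = stat_parameters(),
        delta = unlist(d[paste0("d_", stat_parameters())], use.names = FALSE),
        direction = unlist(d[paste0("dir_", stat_parameters())],
                           use.names = FALSE))
    }) %>%
    dplyr::ungroup()
}

#' Correlation between two segment series
#'
#' Pearson correlation between two per-beat series of the same session,
#' paired by beat index over the intersection of beats retained in both.
#' The class is `"P"` (positive), `"N"` (negative) or `"Z"` (within the
#' zero band, or undefined when either series has zero variance).
#'
#' @param a,b long segment tibbles (single participant/session/segment each)
#'   with `beat_index` and `value`, or plain numeric vectors of equal length.
#' @param zero_tol half-width of the zero-correlation band.
#' @return one-row tibble: `segment_a`, `segment_b`, `n`, `r`, `class`.
#' @export
correlate <- function(a, b, zero_tol = 1e-9) {
  if (is.numeric(a)) a <- tibble::tibble(beat_index = seq_along(a), value = a,
                                         segment = NA_character_)
  if (is.numeric(b)) b <- tibble::tibble(beat_index = seq_along(b), value = b,
                                         segment = NA_character_)
  j <- dplyr::inner_join(a[c("beat_index", "value")],
                         b[c("beat_index", "value")],
                         by = "beat_index", suffix = c("_a", "_b"))
  if (nrow(j) < 3) stop("correlation needs at least 3 aligned beats")
  va <- stats::var(j$value_a); vb <- stats::var(j$value_b)
  if (va == 0 || vb == 0) {
    r <- NA_real_; cls <- "Z"
  } else {
    r <- stats::cor(j$value_a, j$value_b)
    cls <- dplyr::case_when(r > zero_tol ~ "P", r < -zero_tol ~ "N",
                            TRUE ~ "Z")
  }
  tibble::tibble(segment_a = a$segment[1], segment_b = b$segment[1],
                 n = nrow(j), r = r, class = cls)
}

#' Inter-segment correlations across a cohort
#'
#' For each participant, correlates every `a_segments` x `b_segments` pair of
#' glucose-session series (the layout of the published correlation matrix:
#' rows ST/QTC/QT, columns PRQ/QRS/P-H/R-H/HRV/HR).
#'
#' @param segments long segment tibble.
#' @param a_segments,b_segments segment ids to pair (RR-I is the HRV series).
#' @param session which session to correlate (default the glucose session).
#' @inheritParams correlate
#' @return tibble `participant, segment_a, segment_b, n, r, class`.
#' @export
correlate_segments <- function(segments,
                               a_segments = c("ST", "QTC", "QT"),
                               b_segments = c("PRQ", "QRS", "P-H", "R-H",
                                              "RR-I", "HR"),
                               session = "G", zero_tol = 1e-9) {
  dat <- segments %>% dplyr::filter(.data$session == .env$session)
  pairs <- tidyr::expand_grid(segment_a = a_segments, segment_b = b_segments)
  dat %>%
    dplyr::group_by(.data$participant) %>%
    dplyr::group_modify(function(.x, .y) {
      purrr::pmap_dfr(pairs, function(segment_a, segment_b) {
        correlate(.x[.x$segment == segment_a, ],
                  .x[.x$segment == segment_b, ], zero_tol)
      })
    }) %>%
    dplyr::ungroup()
}

#' Cohort correlation percentages
#'
#' The share of participants whose correlation class is positive
#' (respectively negative) for each segment pair, as integer percentages
#' (half-up rounding, the convention of the published tables: 13/16 prints
#' as 81%).
#'
#' @param correlations output of [correlate_segments()].
#' @return tibble `segment_a, segment_b, n, pct_P, pct_N`.
#' @export
correlation_percentage <- function(correlations) {
  correlations %>%
    dplyr::group_by(.data$segment_a, .data$segment_b) %>%
    dplyr::summarise(
      n = dplyr::n(),
      pct_P = round_half_up(100 * sum(.data$class == "P") / dplyr::n()),
      pct_N = round_half_up(100 * sum(.data$class == "N") / dplyr::n()),
      .groups = "drop")
}
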
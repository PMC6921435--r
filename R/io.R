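#' Read and write ECG CSV
#'
#' The on-disk ECG format is a two-column CSV `time_s,ecg_mV`, one row per
#' sample. The reader tolerates a header row and an optional leading index
#' column (as written by some acquisition exports).
#'
#' @param path file path.
#' @param sampling_rate_hz optional; inferred from the time column when
#'   omitted.
#' @return an [ecg_record()].
#' @export
read_ecg_csv <- function(path, sampling_rate_hz = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- names(df)
  if (!all(c("time_s", "ecg_mV") %in% cols)) {
    # headerless or index-prefixed export: take the last two numeric columns
    num <- df[vapply(df, is.numeric, logical(1))]
    if (ncol(num) < 2) stop("cannot find time and voltage columns in ", path)
    df <- stats::setNames(num[, (ncol(num) - 1):ncol(num)],
                          c("time_s", "ecg_mV"))
  } else if (cols[1] != "time_s") {
    df <- df[c("time_s", "ecg_mV")]
  }
  fs <- sampling_rate_hz %||% (1 / stats::median(diff(df$time_s)))
  ecg_record(df$ecg_mV, fs, start_time_s = df$time_s[1])
}

#' @rdname read_ecg_csv
#' @param record an [ecg_record()].
#' @export
write_ecg_csv <- function(record, path) {
  readr::write_csv(record[c("time_s", "ecg_mV")], path, progress = FALSE)
  invisible(path)
}

#' Read and write long segment-series CSV
#'
#' Format: `participant,session,beat_index,time_s,segment,value`.
#'
#' @param path file path.
#' @return segment tibble.
#' @export
read_segments_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    participant = readr::col_character(),
                    session = readr::col_character(),
                    beat_index = readr::col_integer(),
                    time_s = readr::col_double(),
                    segment = readr::col_character(),
                    value = readr::col_double()))
}

#' @rdname read_segments_csv
#' @param segments long segment tibble.
#' @export
write_segments_csv <- function(segments, path) {
  readr::write_csv(segments, path, progress = FALSE)
  invisible(path)
}

#' Read and write per-beat ground-truth CSV
#'
#' One row per generated beat: fiducial sample indices and the nine true
#' segment values.
#'
#' @param path file path.
#' @return ground-truth tibble as produced by [generate_session_pair()].
#' @export
read_ground_truth_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_ground_truth_csv
#' @param ground_truth per-beat ground-truth tibble.
#' @export
write_ground_truth_csv <- function(ground_truth, path) {
  readr::write_csv(ground_truth, path, progress = FALSE)
  invisible(path)
}

#' Read a flat key/value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` are ignored. Values that parse as numbers are returned
#' numeric; `true`/`false` become logical.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
    else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
    else val
  }
  out
}

#' Write the score report to disk
#'
#' Writes each score table as CSV plus a single JSON report, mirroring the
#' published summary-table layout.
#'
#' @param report an `ecg_score_report` (see [build_report()]) or an
#'   [analyze_cohort()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (inherits(report, "ecg_cohort_analysis")) report <- report$report
  stopifnot(inherits(report, "ecg_score_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("stat_tally", "stat_decisions", "stat_sensitivity",
               "spectral_table", "spectral_sensitivity", "correlation_pct",
               "direction_matrix")) {
    tab <- report[[nm]]
    if (is.null(tab)) next
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tab, p, progress = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(lapply(Filter(Negate(is.null), unclass(report)),
                              as.data.frame),
                       jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
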
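#' Simulate a cohort to disk
#'
#' Generates a paired synthetic cohort and writes, per participant and
#' session, the ECG trace CSV (`ecg_p<participant>_<session>.csv`) and the
#' per-beat ground-truth CSV (`truth_p<participant>_<session>.csv`), plus a
#' `manifest.json` recording the configuration and seed. Re-running with the
#' same configuration reproduces every file byte-for-byte.
#'
#' @param out_dir output directory (created if missing).
#' @param n_participants cohort size.
#' @param config a [session_config()].
#' @param effect a [glucose_effect()].
#' @param signal write raw ECG traces (`TRUE`) or ground truth only.
#' @return invisibly, a tibble `participant, session, ecg_path, truth_path`.
#' @export
run_simulate <- function(out_dir, n_participants = 16,
                         config = session_config(),
                         effect = glucose_effect(), signal = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2) != 0)
    stop("output directory is not writable: ", out_dir)
  cohort <- generate_cohort(n_participants, config, effect, signal = signal)
  files <- purrr::pmap_dfr(
    cohort[c("participant", "session", "record", "ground_truth")],
    function(participant, session, record, ground_truth) {
      stem <- sprintf("p%02d_%s", participant, session)
      ecg_path <- NA_character_
      if (!is.null(record)) {
        ecg_path <- file.path(out_dir, paste0("ecg_", stem, ".csv"))
        write_ecg_csv(record, ecg_path)
      }
      truth_path <- file.path(out_dir, paste0("truth_", stem, ".csv"))
      write_ground_truth_csv(ground_truth, truth_path)
      tibble::tibble(participant = participant, session = session,
                     ecg_path = ecg_path, truth_path = truth_path)
    })
  jsonlite::write_json(
    list(stage = "simulate", n_participants = n_participants,
         config = unclass(config), effect = unclass(effect),
         signal = signal, package_version = as.character(
           utils::packageVersion("ecgdelta"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Analyse a cohort end-to-end
#'
#' Orchestrates the analysis stages in order: (raw-ecg mode) R-peak
#' detection, delineation and segment extraction per session; artifact
#' cleaning; paired statistics, correlations and spectral comparison; cohort
#' scoring. Intermediate tables and the score report are written under
#' `out_dir` when given.
#'
#' @param input either a long segment tibble / path to a segment CSV
#'   (`mode = "segment-series"`), or a cohort layout tibble
#'   `participant, session, path` pointing at ECG CSVs
#'   (`mode = "raw-ecg"`). Both sessions must be present for every
#'   participant.
#' @param mode input mode.
#' @param out_dir optional output directory for intermediates and the report.
#' @param equal_tol,welch passed to [analyze_cohort()].
#' @param sampling_rate_hz sampling rate of raw ECG inputs (inferred from
#'   the time column when `NULL`).
#' @return an [analyze_cohort()] result, invisibly when `out_dir` is given.
#' @export
run_analyze <- function(input, mode = c("segment-series", "raw-ecg"),
                        out_dir = NULL, equal_tol = NULL,
                        welch = welch_config(), sampling_rate_hz = NULL) {
  mode <- match.arg(mode)
  t0 <- Sys.time()
  if (mode == "segment-series") {
    segments <- if (is.character(input)) read_segments_csv(input) else input
  } else {
    layout <- input
    stopifnot(all(c("participant", "session", "path") %in% names(layout)))
    missing_pair <- layout %>%
      dplyr::count(.data$participant) %>% dplyr::filter(.data$n < 2)
    if (nrow(missing_pair))
      stop("missing G or NG session for participant ",
           missing_pair$participant[1])
    if (!all(file.exists(layout$path)))
      stop("missing input file: ", layout$path[!file.exists(layout$path)][1])
    segments <- purrr::pmap_dfr(layout, function(participant, session, path,
                                                 ...) {
      rec <- read_ecg_csv(path, sampling_rate_hz)
      fid <- delineate(rec, detect_r_peaks(rec))
      message(sprintf("participant %s session %s: %d beats, %d dropped",
                      participant, session, nrow(fid),
                      attr(fid, "n_dropped")))
      extract_segments(fid, sampling_rate(rec), participant, session)
    })
  }
  segments <- clean_series(segments)
  removed <- attr(segments, "n_removed")
  fit <- analyze_cohort(segments, equal_tol = equal_tol, welch = welch)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_segments_csv(segments, file.path(out_dir, "segments_clean.csv"))
    readr::write_csv(fit$summaries, file.path(out_dir, "summaries.csv"),
                     progress = FALSE)
    readr::write_csv(fit$deltas, file.path(out_dir, "deltas.csv"),
                     progress = FALSE)
    if (!is.null(fit$correlations))
      readr::write_csv(fit$correlations,
                       file.path(out_dir, "correlations.csv"),
                       progress = FALSE)
    if (!is.null(fit$spectral))
      readr::write_csv(fit$spectral,
                       file.path(out_dir, "spectral_directions.csv"),
                       progress = FALSE)
    write_report(fit, out_dir)
    jsonlite::write_json(
      list(stage = "analyze", mode = mode,
           welch = unclass(welch),
           equal_tol = equal_tol %||% "segment resolution",
           n_participants = fit$n_participants,
           beats_removed = if (!is.null(removed)) sum(removed$n_removed)
           else 0L,
           elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
           package_version = as.character(
             utils::packageVersion("ecgdelta"))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(fit))
  }
  fit
}
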
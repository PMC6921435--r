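#' Welch estimator configuration
#'
#' Settings of the averaged-periodogram (Welch) estimator applied to the
#' beat-indexed segment series: nominal sampling frequency 0.8 (scales the
#' frequency axis only), frame length 256 samples, 10 points of overlap
#' between successive frames, rectangular window. `demean` subtracts the
#' series mean before estimation so the peak reflects oscillatory content
#' rather than the large constant offset of interval series; `include_dc`
#' keeps the zero-frequency bin in the peak search.
#'
#' @param sampling_frequency nominal sampling frequency of the series.
#' @param frame_length frame length M (>= 8).
#' @param overlap_points points of overlap between frames (0 <= overlap < M).
#' @param demean subtract the series mean first (default `TRUE`).
#' @param include_dc include the zero-frequency bin in [peak_power()].
#' @return list of class `welch_config`.
#' @export
welch_config <- function(sampling_frequency = 0.8, frame_length = 256,
                         overlap_points = 10, demean = TRUE,
                         include_dc = FALSE) {
  stopifnot(frame_length >= 8, overlap_points >= 0,
            overlap_points < frame_length, sampling_frequency > 0)
  structure(list(sampling_frequency = sampling_frequency,
                 frame_length = as.integer(frame_length),
                 overlap_points = as.integer(overlap_points),
                 demean = isTRUE(demean), include_dc = isTRUE(include_dc)),
            class = "welch_config")
}

#' Welch power spectral density of a segment series
#'
#' Partitions the series into K = floor((N - M) / R) + 1 frames of length M
#' at step R = M - overlap (trailing samples not filling a frame are
#' discarded), applies the rectangular window, computes each frame's
#' periodogram |DFT|^2 / M and averages across frames. The one-sided
#' spectrum is returned on the grid omega_k = k fs / M, k = 0..M/2.
#'
#' @param values numeric vector (one per-beat segment series), length >= M.
#' @param config a [welch_config()].
#' @return tibble of class `psd_estimate` with columns `frequency`, `power`;
#'   attributes `frames` (K) and `config`.
#' @export
welch_psd <- function(values, config = welch_config()) {
  stopifnot(is.numeric(values), !anyNA(values))
  m <- config$frame_length
  if (length(values) < m)
    stop("series length (", length(values), ") is shorter than the frame ",
         "length M = ", m, "; lower frame_length")
  if (config$demean) values <- values - mean(values)
  step <- m - config$overlap_points
  k_frames <- floor((length(values) - m) / step) + 1L
  half <- m %/% 2
  acc <- numeric(half + 1L)
  for (f in seq_len(k_frames)) {
    frame <- values[(f - 1L) * step + seq_len(m)]
    p <- Mod(stats::fft(frame))^2 / m
    acc <- acc + p[seq_len(half + 1L)]
  }
  out <- tibble::tibble(
    frequency = (0:half) * config$sampling_frequency / m,
    power = acc / k_frames
  )
  attr(out, "frames") <- k_frames
  attr(out, "config") <- config
  class(out) <- c("psd_estimate", class(out))
  out
}

#' Peak spectral power
#'
#' The maximum of the power spectral density, by default excluding the
#' zero-frequency bin (the DC level of a segment series is compared by the
#' paired boxplot statistics, not by the spectrum).
#'
#' @param psd a [welch_psd()] estimate.
#' @param include_dc overrides the config's DC handling if not `NULL`.
#' @return scalar peak power.
#' @export
peak_power <- function(psd, include_dc = NULL) {
  cfg <- attr(psd, "config")
  inc <- include_dc %||% (if (is.null(cfg)) FALSE else cfg$include_dc)
  p <- if (inc) psd$power else psd$power[psd$frequency > 0]
  max(p)
}

#' Direction of spectral change
#'
#' Compares the peak power of the glucose and control estimates: increase
#' when H(G) > H(NG), decrease when H(G) < H(NG), equality within a relative
#' tolerance.
#'
#' @param g,ng [welch_psd()] estimates computed with the same configuration.
#' @param equal_tol relative equality tolerance on the peak powers.
#' @return `"I"`, `"D"` or `"E"`.
#' @export
spectral_direction <- function(g, ng, equal_tol = 1e-9) {
  hg <- peak_power(g)
  hng <- peak_power(ng)
  scale <- max(hg, hng, .Machine$double.xmin)
  if (abs(hg - hng) <= equal_tol * scale) "E"
  else if (hg > hng) "I"
  else "D"
}

#' Welch spectra for a whole cohort
#'
#' @param segments long segment tibble.
#' @param config a [welch_config()].
#' @return tibble `participant, session, segment, frequency, power`.
#' @export
cohort_psd <- function(segments, config = welch_config()) {
  segments %>%
    dplyr::arrange(.data$participant, .data$session, .data$segment,
                   .data$beat_index) %>%
    dplyr::group_by(.data$participant, .data$session, .data$segment) %>%
    dplyr::group_modify(~ welch_psd(.x$value, config)) %>%
    dplyr::ungroup()
}

#' Per-participant spectral directions
#'
#' Computes the Welch peak of each G and NG series and classifies the
#' direction of change for every participant x segment.
#'
#' @inheritParams cohort_psd
#' @param equal_tol relative equality tolerance on peak powers.
#' @return tibble `participant, segment, h_g, h_ng, direction`.
#' @export
spectral_directions <- function(segments, config = welch_config(),
                                equal_tol = 1e-9) {
  segments %>%
    dplyr::arrange(.data$participant, .data$segment, .data$session,
                   .data$beat_index) %>%
    dplyr::group_by(.data$participant, .data$segment) %>%
    dplyr::group_modify(function(.x, .y) {
      g <- welch_psd(.x$value[.x$session == "G"], config)
      ng <- welch_psd(.x$value[.x$session == "NG"], config)
      tibble::tibble(h_g = peak_power(g), h_ng = peak_power(ng),
                     direction = spectral_direction(g, ng, equal_tol))
    }) %>%
    dplyr::ungroup()
}
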
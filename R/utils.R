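#' @importFrom rlang .data .env
#' @importFrom dplyr %>%
NULL

# Gaussian onset/offset constant: a wave is considered to start/end where its
# bump falls to 5% of peak amplitude, i.e. at center +/- k*width with
# k = sqrt(2*log(20)). Shared by the generator's ground truth and the
# delineator's baseline-return rule so the two agree by construction.
ONSET_K <- sqrt(2 * log(20))

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all reported percentages, so that
#' 81.25 prints as 81 and 44.45 as 44.5, matching the convention of the score
#' tables rather than banker's rounding.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Segment identifiers
#'
#' The nine per-beat ECG segment series analysed by the package, in canonical
#' order: RR interval (the HRV series), heart rate, R and P wave heights, QRS
#' duration, PRQ (P onset to R peak), QT, heart-rate-corrected QT and ST
#' (S to T onset).
#'
#' @return character vector of the nine segment ids.
#' @export
segment_ids <- function() {
  c("RR-I", "HR", "R-H", "P-H", "QRS", "PRQ", "QT", "QTC", "ST")
}

# internal column names used for the wide per-beat ground-truth/segments table
segment_columns <- function() {
  c(`RR-I` = "rr_ms", HR = "hr_bpm", `R-H` = "rh_mV", `P-H` = "ph_mV",
    QRS = "qrs_ms", PRQ = "prq_ms", QT = "qt_ms", QTC = "qtc_ms", ST = "st_ms")
}

#' Measurement resolution of a segment series
#'
#' The grid on which values of a segment are considered distinct: 1 ms for
#' interval series, 1 bpm for heart rate, 0.01 mV for wave heights. Used both
#' to quantise values before mode counting and as the default equality band
#' when classifying the direction of a paired delta.
#'
#' @param segment one of [segment_ids()].
#' @return numeric scalar resolution in the segment's native units.
#' @export
segment_resolution <- function(segment) {
  res <- c(`RR-I` = 1, HR = 1, `R-H` = 0.01, `P-H` = 0.01, QRS = 1,
           PRQ = 1, QT = 1, QTC = 1, ST = 1)
  out <- unname(res[segment])
  if (anyNA(out)) stop("unknown segment id: ",
                       paste(setdiff(segment, names(res)), collapse = ", "))
  out
}

# derive a reproducible child seed from a parent seed and a stream index,
# kept strictly inside 32-bit integer range
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
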
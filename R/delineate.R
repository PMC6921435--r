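#' Detect R peaks
#'
#' Pan-Tompkins style QRS detector: zero-phase 5-15 Hz Butterworth band-pass,
#' differentiation, squaring, 150 ms moving-window integration, then an
#' adaptive signal/noise threshold with a 200 ms refractory period. Detected
#' QRS candidates are refined to the local maximum of the raw signal.
#'
#' @param record an [ecg_record()] (or data frame with `ecg_mV`; pass
#'   `sampling_rate_hz` via the attribute or a `time_s` column).
#' @return integer vector of R-peak sample indices (possibly empty for a
#'   signal with no QRS energy).
#' @export
detect_r_peaks <- function(record) {
  x <- record$ecg_mV
  fs <- sampling_rate(record)
  win <- max(2L, round(0.15 * fs))
  if (length(x) < win)
    stop("record (", length(x), " samples) is shorter than the ",
         win, "-sample integration window")
  if (stats::sd(x) == 0) return(integer(0))

  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bp, x)
  sq <- c(0, diff(filt))^2
  integ <- stats::filter(sq, rep(1 / win, win), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  n <- length(integ)
  cand <- which(diff(sign(diff(integ))) < 0) + 1L     # local maxima
  cand <- cand[integ[cand] > 0]
  if (!length(cand)) return(integer(0))

  refr <- round(0.2 * fs)
  init <- seq_len(min(n, round(2 * fs)))
  spki <- 0.6 * max(integ[init])
  npki <- stats::median(integ[init])
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[i] > thr) {
      if (i - last >= refr) {
        peaks <- c(peaks, i)
        last <- i
        spki <- 0.125 * integ[i] + 0.875 * spki
      } else if (integ[i] > integ[last]) {
        peaks[length(peaks)] <- i
        last <- i
        spki <- 0.125 * integ[i] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
  }
  if (!length(peaks)) return(integer(0))

  # refine each detection to the raw-signal maximum nearby
  half <- round(0.1 * fs)
  half <- as.integer(half)
  r <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  r <- sort(unique(r))
  # enforce the refractory period on the refined indices
  if (length(r) > 1) {
    keep <- rep(TRUE, length(r))
    j <- 1L
    for (i in seq(2, length(r))) {
      if (r[i] - r[j] < refr) {
        if (x[r[i]] > x[r[j]]) { keep[j] <- FALSE; j <- i } else keep[i] <- FALSE
      } else j <- i
    }
    r <- r[keep]
  }
  r
}

# first index, searching outward from `peak` by `step` (+/-1), where the
# signal returns within `frac` of the local baseline; NA if not reached
# within `max_off` samples or the record edge
edge_search <- function(x, peak, step, frac, baseline, max_off) {
  h <- abs(x[peak] - baseline)
  thr <- frac * h
  i <- peak
  lim <- peak + step * max_off
  while (i != lim) {
    i <- i + step
    if (i < 1L || i > length(x)) return(NA_integer_)
    if (abs(x[i] - baseline) <= thr) return(i)
  }
  NA_integer_
}

#' Delineate fiducial points
#'
#' Locates the P, Q, S and T landmarks around each detected R peak. Q and S
#' are the nearest local minima within 80 ms before/after R; the P peak is
#' the maximum in (R-250 ms, R-80 ms) and the T peak the maximum in
#' (R+120 ms, R+min(450 ms, 0.7 RR)). Wave onsets and ends are found by
#' searching outward from each peak for the first sample back within 5% of
#' the local baseline. The first and last beats (incomplete search windows)
#' are dropped; a landmark whose search fails, or whose wave has no
#' discernible prominence, is recorded as `NA` so that only the series
#' depending on it lose the beat.
#'
#' @param record an [ecg_record()].
#' @param r_peaks integer vector of R sample indices (>= 2).
#' @return tibble with one row per retained beat: `beat`, `time_s`, sample
#'   indices `p_on`, `p_peak`, `q`, `r`, `s`, `t_on`, `t_peak`, `t_end`
#'   (`NA` where a search failed) and the signal heights `r_mV`, `p_mV`.
#'   Attribute `n_dropped` counts beats with any failed landmark.
#' @export
delineate <- function(record, r_peaks) {
  if (length(r_peaks) < 2) stop("delineation needs at least 2 R peaks")
  x <- record$ecg_mV
  fs <- sampling_rate(record)
  ms <- function(t) round(t / 1000 * fs)
  n <- length(x)

  rows <- vector("list", length(r_peaks))
  for (b in seq_along(r_peaks)) {
    if (b == 1L || b == length(r_peaks)) next   # incomplete search windows
    r <- r_peaks[b]
    rr <- (r_peaks[b + 1] - r) / fs * 1000
    if (r - ms(260) < 1 || r + ms(460) > n) next

    # local baseline from the quiet span before the P wave
    base_lo <- r - ms(min(420, 0.45 * rr))
    base_hi <- r - ms(265)
    baseline <- if (base_lo < base_hi && base_lo >= 1)
      stats::median(x[base_lo:base_hi]) else 0
    r_h <- x[r] - 0  # heights are raw signal values (no baseline subtraction)

    w_q <- (r - ms(80)):(r - 1L)
    q <- w_q[local_min(x[w_q])]
    w_s <- (r + 1L):(r + ms(80))
    s <- w_s[local_min(x[w_s])]
    prominence <- 0.05 * abs(x[r] - baseline)
    if (!is.na(q) && abs(x[q] - baseline) < prominence) q <- NA_integer_
    if (!is.na(s) && abs(x[s] - baseline) < prominence) s <- NA_integer_

    w_p <- (r - ms(250)):(r - ms(80))
    p_peak <- w_p[which.max(x[w_p])]
    if (abs(x[p_peak] - baseline) < prominence) p_peak <- NA_integer_
    w_t <- (r + ms(120)):(r + ms(min(450, 0.7 * rr)))
    t_peak <- w_t[which.max(x[w_t])]
    if (abs(x[t_peak] - baseline) < prominence) t_peak <- NA_integer_

    p_on <- if (is.na(p_peak)) NA_integer_ else
      edge_search(x, p_peak, -1L, 0.05, baseline, ms(140))
    t_on <- if (is.na(t_peak)) NA_integer_ else
      edge_search(x, t_peak, -1L, 0.05, baseline, ms(250))
    t_end <- if (is.na(t_peak)) NA_integer_ else
      edge_search(x, t_peak, +1L, 0.05, baseline, ms(250))

    rows[[b]] <- tibble::tibble(
      beat = b, time_s = (r - 1) / fs,
      p_on = p_on, p_peak = p_peak, q = q, r = r, s = s,
      t_on = t_on, t_peak = t_peak, t_end = t_end,
      r_mV = r_h, p_mV = if (is.na(p_peak)) NA_real_ else x[p_peak]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    landmark_cols <- c("p_on", "p_peak", "q", "s", "t_on", "t_peak", "t_end")
    attr(out, "n_dropped") <-
      sum(!stats::complete.cases(out[landmark_cols]))
  } else attr(out, "n_dropped") <- 0L
  out
}

# index of the local minimum nearest the end of the window facing R;
# falls back to the global minimum of the window
local_min <- function(v) {
  if (length(v) < 3) return(which.min(v))
  interior <- which(v[2:(length(v) - 1)] < v[1:(length(v) - 2)] &
                      v[2:(length(v) - 1)] <= v[3:length(v)]) + 1L
  if (!length(interior)) return(which.min(v))
  interior[which.min(v[interior])]
}

#' Extract the nine segment series
#'
#' Converts a fiducial table into the nine per-beat segment series:
#' RR-I (ms between successive R peaks, the HRV series), HR (60000/RR-I),
#' R-H and P-H (signal heights in mV), QRS (Q-to-S span), PRQ (P onset to R
#' peak), QT (Q to T end), QTC (Bazett: QT / sqrt(RR in s)) and ST (S to T
#' onset). A beat missing a landmark is omitted only from the series that
#' need it.
#'
#' @param fiducials output of [delineate()] (or a compatible tibble).
#' @param sampling_rate_hz sampling rate used to convert indices to ms.
#' @param participant,session labels attached to the output.
#' @return long tibble `participant, session, beat_index, time_s, segment,
#'   value`.
#' @export
extract_segments <- function(fiducials, sampling_rate_hz,
                             participant = NA, session = NA_character_) {
  f <- fiducials
  if (nrow(f) < 2) stop("at least 2 beats are required (RR undefined)")
  to_ms <- function(d) d / sampling_rate_hz * 1000
  rr <- c(to_ms(diff(f$r)), NA_real_)       # RR of the last beat undefined
  qt <- to_ms(f$t_end - f$q)
  vals <- tibble::tibble(
    beat_index = f$beat, time_s = f$time_s,
    `RR-I` = rr,
    HR = 60000 / rr,
    `R-H` = f$r_mV,
    `P-H` = f$p_mV,
    QRS = to_ms(f$s - f$q),
    PRQ = to_ms(f$r - f$p_on),
    QT = qt,
    QTC = qt / sqrt(rr / 1000),
    ST = to_ms(f$t_on - f$s)
  )
  tidyr::pivot_longer(vals, cols = dplyr::all_of(segment_ids()),
                      names_to = "segment", values_to = "value") %>%
    dplyr::filter(is.finite(.data$value)) %>%
    dplyr::mutate(participant = participant, session = session) %>%
    dplyr::select("participant", "session", "beat_index", "time_s",
                  "segment", "value")
}

#' Clean segment series of artifacts
#'
#' Removes physiologically impossible values (non-positive intervals, HR
#' outside (20, 250) bpm) and outliers beyond 5 median-absolute-deviations
#' from the per-series median (the MAD rule is skipped when the MAD is 0).
#' Emits a warning when more than 20% of a series is removed.
#'
#' @param segments long segment tibble (see [extract_segments()]).
#' @return filtered tibble; attribute `n_removed` gives the per-series
#'   removal counts.
#' @export
clean_series <- function(segments) {
  interval_ids <- c("RR-I", "QRS", "PRQ", "QT", "QTC", "ST")
  flagged <- segments %>%
    dplyr::group_by(.data$participant, .data$session, .data$segment) %>%
    dplyr::mutate(.bad = !is.finite(.data$value) |
                    (.data$segment %in% interval_ids & .data$value <= 0) |
                    (.data$segment == "HR" &
                       (.data$value <= 20 | .data$value >= 250)),
                  .med = stats::median(.data$value[!.bad]),
                  .mad = stats::mad(.data$value[!.bad]),
                  .bad = .data$.bad | (!is.na(.data$.mad) & .data$.mad > 0 &
                    abs(.data$value - .data$.med) > 5 * .data$.mad)) %>%
    dplyr::ungroup()
  removed <- flagged %>%
    dplyr::group_by(.data$participant, .data$session, .data$segment) %>%
    dplyr::summarise(n = dplyr::n(), n_removed = sum(.data$.bad),
                     .groups = "drop")
  worst <- removed %>% dplyr::filter(.data$n_removed > 0.2 * .data$n)
  if (nrow(worst))
    warning("more than 20% of beats removed in ", nrow(worst),
            " series (e.g. ", worst$segment[1], ", participant ",
            worst$participant[1], ")")
  out <- flagged %>% dplyr::filter(!.data$.bad) %>%
    dplyr::select(-".bad", -".med", -".mad")
  attr(out, "n_removed") <- removed
  out
}
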
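#' Beat morphology description
#'
#' A cardiac cycle is modelled as the sum of five Gaussian bumps, one per
#' wave (P, Q, R, S, T). Each wave has a signed amplitude in millivolts, a
#' width (the Gaussian standard deviation, in ms) and a centre offset in ms
#' relative to the R peak. Wave onsets and ends are defined at
#' centre +/- k*width with k = sqrt(2*log(20)), i.e. where the bump falls to
#' 5% of its peak.
#'
#' @param amplitude_mV named numeric, signed peak amplitude per wave.
#' @param width_ms named numeric, Gaussian sd per wave (> 0).
#' @param offset_ms named numeric, wave centre relative to the R peak; P and
#'   Q are negative, R is 0, S and T positive.
#' @return a tibble with one row per wave and class `beat_morphology`.
#' @examples
#' beat_morphology()
#' @export
beat_morphology <- function(
    amplitude_mV = c(P = 0.15, Q = -0.12, R = 1.10, S = -0.22, T = 0.35),
    width_ms     = c(P = 18,   Q = 8,     R = 7,    S = 8,     T = 30),
    offset_ms    = c(P = -160, Q = -28,   R = 0,    S = 28,    T = 240)) {
  waves <- c("P", "Q", "R", "S", "T")
  m <- tibble::tibble(
    wave = waves,
    amplitude_mV = unname(amplitude_mV[waves]),
    width_ms = unname(width_ms[waves]),
    offset_ms = unname(offset_ms[waves])
  )
  validate_morphology(m)
}

validate_morphology <- function(m) {
  stopifnot(is.data.frame(m), nrow(m) == 5L,
            all(c("wave", "amplitude_mV", "width_ms", "offset_ms") %in% names(m)))
  amp <- stats::setNames(m$amplitude_mV, m$wave)
  off <- stats::setNames(m$offset_ms, m$wave)
  if (any(m$width_ms <= 0)) stop("all wave widths must be positive")
  if (!(amp["R"] > 0) && any(m$amplitude_mV != 0))
    stop("R amplitude must be positive")
  if (any(m$amplitude_mV != 0) &&
      any(abs(amp[c("P", "Q", "S", "T")]) >= abs(amp["R"])))
    stop("R must have strictly the largest absolute amplitude")
  if (!(off["P"] < off["Q"] && off["Q"] < 0 && off["R"] == 0 &&
        0 < off["S"] && off["S"] < off["T"]))
    stop("wave offsets must satisfy P < Q < 0 = R < S < T")
  class(m) <- c("beat_morphology", class(m))
  m
}

#' Session configuration
#'
#' Recording-level parameters of one synthetic session. Defaults reflect a
#' 120-minute seated resting recording at 500 Hz with a resting heart rate of
#' 66 bpm, beat-to-beat RR jitter of 40 ms and a respiratory sinus-arrhythmia
#' modulation of 25 ms at 0.25 Hz.
#'
#' @param duration_s session length in seconds (> 0).
#' @param sampling_rate_hz sampling rate, at least 100 Hz.
#' @param baseline_hr_bpm resting heart rate, within \[40, 180\].
#' @param hrv_sd_ms sd of the zero-mean beat-to-beat RR jitter (>= 0).
#' @param resp_amp_ms amplitude of the sinusoidal respiratory RR modulation.
#' @param resp_freq_hz respiratory modulation frequency.
#' @param noise_sd_mV sd of additive white Gaussian measurement noise.
#' @param random_seed master seed; all session randomness derives from it.
#' @return list of class `session_config`.
#' @export
session_config <- function(duration_s = 7200, sampling_rate_hz = 500,
                           baseline_hr_bpm = 66, hrv_sd_ms = 40,
                           resp_amp_ms = 25, resp_freq_hz = 0.25,
                           noise_sd_mV = 0.02, random_seed = 1L) {
  stopifnot(duration_s > 0, sampling_rate_hz >= 100,
            baseline_hr_bpm >= 40, baseline_hr_bpm <= 180,
            hrv_sd_ms >= 0, resp_amp_ms >= 0, resp_freq_hz > 0,
            noise_sd_mV >= 0)
  structure(list(duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 baseline_hr_bpm = baseline_hr_bpm,
                 hrv_sd_ms = hrv_sd_ms,
                 resp_amp_ms = resp_amp_ms,
                 resp_freq_hz = resp_freq_hz,
                 noise_sd_mV = noise_sd_mV,
                 random_seed = as.integer(random_seed)),
            class = "session_config")
}

#' Glucose effect profile
#'
#' Describes the injected glucose response of the G session: from `onset_s`
#' (default 30 minutes, when the glucose solution is ingested) each gain is
#' ramped in linearly over `ramp_s` seconds and then sustained. A gain of 1
#' means no injected effect on that parameter. `hr_gain` (> 1 raises HR) and
#' `rr_gain` (< 1 shortens RR) both act on the RR series, the generator
#' parameter from which both segments derive: the applied RR multiplier is
#' `rr_gain / hr_gain`.
#'
#' @param onset_s effect onset, seconds from session start (>= 0).
#' @param ramp_s seconds from onset to full effect.
#' @param hr_gain,rr_gain,qt_gain,st_gain,prq_gain,qrs_gain,ph_gain,rh_gain
#'   positive multipliers applied to the corresponding generator parameter
#'   after onset.
#' @return list of class `glucose_effect`.
#' @export
glucose_effect <- function(onset_s = 1800, ramp_s = 300,
                           hr_gain = 1, rr_gain = 1, qt_gain = 1,
                           st_gain = 1, prq_gain = 1, qrs_gain = 1,
                           ph_gain = 1, rh_gain = 1) {
  gains <- c(hr_gain, rr_gain, qt_gain, st_gain, prq_gain, qrs_gain,
             ph_gain, rh_gain)
  stopifnot(onset_s >= 0, ramp_s >= 0, all(gains > 0))
  structure(list(onset_s = onset_s, ramp_s = ramp_s,
                 hr_gain = hr_gain, rr_gain = rr_gain, qt_gain = qt_gain,
                 st_gain = st_gain, prq_gain = prq_gain, qrs_gain = qrs_gain,
                 ph_gain = ph_gain, rh_gain = rh_gain),
            class = "glucose_effect")
}

#' Construct an ECG record
#'
#' @param ecg_mV numeric vector of sampled voltages (millivolts), length >= 2,
#'   no missing values.
#' @param sampling_rate_hz sampling rate (> 0).
#' @param start_time_s time of the first sample.
#' @return tibble with columns `time_s`, `ecg_mV` and attribute
#'   `sampling_rate_hz`.
#' @export
ecg_record <- function(ecg_mV, sampling_rate_hz, start_time_s = 0) {
  stopifnot(length(ecg_mV) >= 2, sampling_rate_hz > 0, !anyNA(ecg_mV))
  out <- tibble::tibble(
    time_s = start_time_s + (seq_along(ecg_mV) - 1) / sampling_rate_hz,
    ecg_mV = as.numeric(ecg_mV)
  )
  attr(out, "sampling_rate_hz") <- sampling_rate_hz
  class(out) <- c("ecg_record", class(out))
  out
}

#' Sampling rate of an ECG record
#' @param record an [ecg_record()] or a plain `time_s`/`ecg_mV` data frame.
#' @return sampling rate in Hz.
#' @export
sampling_rate <- function(record) {
  fs <- attr(record, "sampling_rate_hz")
  if (is.null(fs)) fs <- 1 / stats::median(diff(record$time_s))
  fs
}

# effective per-parameter multiplier at time t (vectorised over t)
effect_multiplier <- function(gain, t, onset_s, ramp_s) {
  if (ramp_s <= 0) frac <- as.numeric(t >= onset_s)
  else frac <- pmin(1, pmax(0, (t - onset_s) / ramp_s))
  1 + (gain - 1) * frac
}

#' Generate a single cardiac cycle
#'
#' Renders one beat of the sum-of-Gaussians model and the sample indices of
#' its fiducial points. The cycle spans one RR interval, with the P-wave
#' onset of the beat placed at the first sample.
#'
#' @param morphology a [beat_morphology()].
#' @param rr_ms cycle length in ms; must exceed the P-onset-to-T-end span.
#' @param sampling_rate_hz sampling rate in Hz.
#' @return list with `signal` (numeric vector, mV) and `fiducials`
#'   (one-row tibble of 1-based sample indices: `p_on`, `p_peak`, `q`, `r`,
#'   `s`, `t_on`, `t_peak`, `t_end`).
#' @examples
#' beat <- generate_beat(beat_morphology(), rr_ms = 800, sampling_rate_hz = 500)
#' length(beat$signal)
#' @export
generate_beat <- function(morphology, rr_ms, sampling_rate_hz) {
  morphology <- validate_morphology(tibble::as_tibble(morphology))
  fs <- sampling_rate_hz
  off <- stats::setNames(morphology$offset_ms, morphology$wave)
  wid <- stats::setNames(morphology$width_ms, morphology$wave)
  amp <- stats::setNames(morphology$amplitude_mV, morphology$wave)
  p_on_off <- off["P"] - ONSET_K * wid["P"]
  t_end_off <- off["T"] + ONSET_K * wid["T"]
  span <- t_end_off - p_on_off
  if (rr_ms <= span)
    stop(sprintf(paste0("rr_ms (%.1f ms) is shorter than the P-onset-to-",
                        "T-end span (%.1f ms) of the configured morphology"),
                 rr_ms, span))
  n <- max(2L, round(rr_ms / 1000 * fs))
  # R centre, ms from first sample; snapped to the sample grid so the peak
  # sample carries the full configured amplitude
  t_r <- round(-p_on_off / 1000 * fs) / fs * 1000
  tms <- (seq_len(n) - 1) / fs * 1000
  sig <- numeric(n)
  for (w in morphology$wave) {
    if (amp[w] != 0)
      sig <- sig + amp[w] * exp(-((tms - (t_r + off[w]))^2) / (2 * wid[w]^2))
  }
  idx <- function(t) pmin(n, pmax(1L, as.integer(round(t / 1000 * fs)) + 1L))
  fid <- tibble::tibble(
    p_on = idx(t_r + p_on_off),
    p_peak = idx(t_r + off["P"]),
    q = idx(t_r + off["Q"]),
    r = idx(t_r),
    s = idx(t_r + off["S"]),
    t_on = idx(t_r + off["T"] - ONSET_K * wid["T"]),
    t_peak = idx(t_r + off["T"]),
    t_end = idx(t_r + t_end_off)
  )
  list(signal = sig, fiducials = fid)
}

# draw a participant-specific morphology and baseline HR multiplier
draw_participant <- function(participant_seed) {
  set.seed(child_seed(participant_seed, 7L))
  base <- beat_morphology()
  amp <- base$amplitude_mV * exp(stats::rnorm(5, 0, 0.08))
  wid <- base$width_ms * exp(stats::rnorm(5, 0, 0.05))
  off <- base$offset_ms
  off[c(1, 2, 4, 5)] <- off[c(1, 2, 4, 5)] * exp(stats::rnorm(4, 0, 0.04))
  # keep the invariant R strictly dominant
  amp[3] <- max(abs(amp)) * 1.2 * sign(amp[3])
  m <- validate_morphology(tibble::tibble(
    wave = base$wave, amplitude_mV = amp, width_ms = wid, offset_ms = off))
  list(morphology = m, hr_mult = exp(stats::rnorm(1, 0, 0.05)))
}

# core single-session generator; gains are all 1 for the NG session
generate_session <- function(config, effect, morphology, hr_mult,
                             session_seed, apply_effect, signal = TRUE) {
  fs <- config$sampling_rate_hz
  off <- stats::setNames(morphology$offset_ms, morphology$wave)
  wid <- stats::setNames(morphology$width_ms, morphology$wave)
  amp <- stats::setNames(morphology$amplitude_mV, morphology$wave)

  base_rr <- 60000 / (config$baseline_hr_bpm * hr_mult)
  qrs0 <- off["S"] - off["Q"]
  prq0 <- -(off["P"] - ONSET_K * wid["P"])
  qt0 <- off["T"] + ONSET_K * wid["T"] - off["Q"]
  st0 <- off["T"] - ONSET_K * wid["T"] - off["S"]

  set.seed(session_seed)
  n_max <- ceiling(config$duration_s / (base_rr / 1000) * 1.6) + 16L
  rr_jit <- stats::rnorm(n_max, 0, config$hrv_sd_ms)
  qt_jit <- stats::rnorm(n_max, 0, 4)
  st_jit <- stats::rnorm(n_max, 0, 3)
  prq_jit <- stats::rnorm(n_max, 0, 3)
  qrs_jit <- stats::rnorm(n_max, 0, 2)
  amp_jit <- exp(stats::rnorm(n_max, 0, 0.03))
  resp_phase <- stats::runif(1, 0, 2 * pi)

  g <- function(gain, t) {
    if (!apply_effect) return(rep(1, length(t)))
    effect_multiplier(gain, t, effect$onset_s, effect$ramp_s)
  }

  # beat placement: sequential because each RR depends on the beat's time
  t_end_span <- qt0 * max(1, effect$qt_gain) + abs(off["Q"]) + 50
  t_r <- numeric(n_max)
  rr <- numeric(n_max)
  t_cur <- max(0.6, (prq0 + 3 * ONSET_K * wid["P"]) / 1000)
  k <- 0L
  while (TRUE) {
    tk <- t_cur
    if (tk + t_end_span / 1000 > config$duration_s) break
    k <- k + 1L
    resp <- config$resp_amp_ms * sin(2 * pi * config$resp_freq_hz * tk + resp_phase)
    rr_mult <- g(effect$rr_gain, tk) / g(effect$hr_gain, tk)
    rr_k <- max(400, base_rr * rr_mult + resp + rr_jit[k])
    t_r[k] <- tk
    rr[k] <- rr_k
    t_cur <- tk + rr_k / 1000
  }
  if (k < 2L) stop("session too short to contain two beats")
  # snap R times to the sample grid so each R sample carries the full
  # configured height (ground truth is defined at sample resolution)
  t_r <- round(t_r[seq_len(k)] * fs) / fs
  rr <- rr[seq_len(k)]

  amp_fac <- amp_jit[seq_len(k)] *
    (1 + 0.04 * sin(2 * pi * config$resp_freq_hz * t_r + resp_phase))
  qt_k <- pmax(qt0 * 0.5, qt0 * g(effect$qt_gain, t_r) + qt_jit[seq_len(k)])
  st_k <- pmax(st0 * 0.4, st0 * g(effect$st_gain, t_r) + st_jit[seq_len(k)])
  prq_k <- pmax(prq0 * 0.5, prq0 * g(effect$prq_gain, t_r) + prq_jit[seq_len(k)])
  qrs_k <- pmax(qrs0 * 0.5, qrs0 * g(effect$qrs_gain, t_r) + qrs_jit[seq_len(k)])
  rh_k <- amp["R"] * g(effect$rh_gain, t_r) * amp_fac
  ph_k <- amp["P"] * g(effect$ph_gain, t_r) * amp_fac

  # realise wave geometry from the per-beat target spans
  q_off <- off["Q"] * qrs_k / qrs0
  s_off <- off["S"] * qrs_k / qrs0
  p_scale <- prq_k / prq0
  p_off <- off["P"] * p_scale
  p_wid <- wid["P"] * p_scale
  t_off <- (qt_k + q_off + st_k + s_off) / 2
  t_kw <- (qt_k + q_off - st_k - s_off) / 2   # = ONSET_K * T width
  t_wid <- pmax(4, t_kw / ONSET_K)

  t_r_ms <- t_r * 1000
  idx <- function(t_ms) as.integer(round(t_ms / 1000 * fs)) + 1L
  gt <- tibble::tibble(
    beat = seq_len(k),
    time_s = t_r,
    idx_p_on = idx(t_r_ms + p_off - ONSET_K * p_wid),
    idx_p_peak = idx(t_r_ms + p_off),
    idx_q = idx(t_r_ms + q_off),
    idx_r = idx(t_r_ms),
    idx_s = idx(t_r_ms + s_off),
    idx_t_on = idx(t_r_ms + t_off - t_kw),
    idx_t_peak = idx(t_r_ms + t_off),
    idx_t_end = idx(t_r_ms + t_off + t_kw),
    rr_ms = rr,
    hr_bpm = 60000 / rr,
    rh_mV = unname(rh_k),
    ph_mV = unname(ph_k),
    qrs_ms = unname(qrs_k),
    prq_ms = unname(prq_k),
    qt_ms = unname(qt_k),
    qtc_ms = unname(qt_k / sqrt(rr / 1000)),
    st_ms = unname(st_k)
  )

  record <- NULL
  if (signal) {
    n_samp <- as.integer(round(config$duration_s * fs))
    sig <- numeric(n_samp)
    add_wave <- function(sig, centre_ms, sd_ms, a) {
      c_smp <- centre_ms / 1000 * fs + 1
      sd_smp <- sd_ms / 1000 * fs
      for (b in seq_along(c_smp)) {
        lo <- max(1L, as.integer(floor(c_smp[b] - 4.5 * sd_smp[b])))
        hi <- min(n_samp, as.integer(ceiling(c_smp[b] + 4.5 * sd_smp[b])))
        if (lo > hi) next
        i <- lo:hi
        sig[i] <- sig[i] + a[b] * exp(-((i - c_smp[b])^2) / (2 * sd_smp[b]^2))
      }
      sig
    }
    sig <- add_wave(sig, t_r_ms + p_off, p_wid, ph_k)
    sig <- add_wave(sig, t_r_ms + q_off, rep(wid["Q"], k), amp["Q"] * amp_fac)
    sig <- add_wave(sig, t_r_ms, rep(wid["R"], k), rh_k)
    sig <- add_wave(sig, t_r_ms + s_off, rep(wid["S"], k), amp["S"] * amp_fac)
    sig <- add_wave(sig, t_r_ms + t_off, t_wid, amp["T"] * amp_fac)
    if (config$noise_sd_mV > 0)
      sig <- sig + stats::rnorm(n_samp, 0, config$noise_sd_mV)
    record <- ecg_record(sig, fs)
  }
  list(record = record, ground_truth = gt)
}

#' Generate a paired glucose / non-glucose session
#'
#' Both sessions share the participant's beat morphology and baseline heart
#' rate (drawn from `participant_seed`); beat-to-beat randomness is drawn
#' independently per session. In the G session only, the effect multipliers
#' are ramped in linearly from `effect$onset_s` over `effect$ramp_s` and then
#' sustained. Fully reproducible from `(participant_seed, config$random_seed)`.
#'
#' @param config a [session_config()].
#' @param effect a [glucose_effect()].
#' @param participant_seed integer identifying the participant.
#' @param signal if `FALSE`, skip waveform synthesis and return ground truth
#'   only (fast path for statistical studies).
#' @return list with elements `G` and `NG`, each a list of `record` (an
#'   [ecg_record()], or `NULL` when `signal = FALSE`) and `ground_truth`
#'   (per-beat tibble of fiducial sample indices and the nine true segment
#'   values).
#' @export
generate_session_pair <- function(config = session_config(),
                                  effect = glucose_effect(),
                                  participant_seed = 1L, signal = TRUE) {
  stopifnot(inherits(config, "session_config"), inherits(effect, "glucose_effect"))
  part <- draw_participant(child_seed(config$random_seed, participant_seed))
  seed_g <- child_seed(config$random_seed, 2L * participant_seed + 1L)
  seed_ng <- child_seed(config$random_seed, 2L * participant_seed + 2L)
  list(
    G = generate_session(config, effect, part$morphology, part$hr_mult,
                         seed_g, apply_effect = TRUE, signal = signal),
    NG = generate_session(config, effect, part$morphology, part$hr_mult,
                          seed_ng, apply_effect = FALSE, signal = signal)
  )
}

#' Generate a cohort of paired sessions
#'
#' @inheritParams generate_session_pair
#' @param n_participants number of participants (>= 1).
#' @return tibble with columns `participant`, `session` ("G"/"NG"), `record`
#'   (list column) and `ground_truth` (list column), two rows per participant.
#' @export
generate_cohort <- function(n_participants = 16, config = session_config(),
                            effect = glucose_effect(), signal = FALSE) {
  stopifnot(n_participants >= 1)
  purrr::map_dfr(seq_len(n_participants), function(p) {
    pair <- generate_session_pair(config, effect, participant_seed = p,
                                  signal = signal)
    tibble::tibble(
      participant = p,
      session = c("G", "NG"),
      record = list(pair$G$record, pair$NG$record),
      ground_truth = list(pair$G$ground_truth, pair$NG$ground_truth)
    )
  })
}

#' Ground-truth segment series of a cohort in long format
#'
#' Reshapes the per-beat ground truth of [generate_cohort()] into the
#' package's standard long segment table.
#'
#' @param cohort output of [generate_cohort()].
#' @return tibble `participant, session, beat_index, time_s, segment, value`.
#' @export
cohort_segments <- function(cohort) {
  cols <- segment_columns()
  purrr::pmap_dfr(
    cohort[c("participant", "session", "ground_truth")],
    function(participant, session, ground_truth) {
      gt <- ground_truth[c("beat", "time_s", cols)]
      names(gt) <- c("beat_index", "time_s", names(cols))
      gt$participant <- participant
      gt$session <- session
      tidyr::pivot_longer(gt, cols = dplyr::all_of(names(cols)),
                          names_to = "segment", values_to = "value") %>%
        dplyr::select("participant", "session", "beat_index", "time_s",
                      "segment", "value")
    })
}
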
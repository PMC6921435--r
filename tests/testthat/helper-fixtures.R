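# shared fixtures: small, fast configurations used across test files

quick_config <- function(duration_s = 60, noise_sd_mV = 0, seed = 1,
                         baseline_hr_bpm = 66, hrv_sd_ms = 40,
                         resp_amp_ms = 25) {
  session_config(duration_s = duration_s, sampling_rate_hz = 500,
                 baseline_hr_bpm = baseline_hr_bpm, hrv_sd_ms = hrv_sd_ms,
                 resp_amp_ms = resp_amp_ms, noise_sd_mV = noise_sd_mV,
                 random_seed = seed)
}

# long segment tibble from a plain numeric vector
as_series <- function(values, segment = "QT", participant = 1,
                      session = "G") {
  tibble::tibble(participant = participant, session = session,
                 beat_index = seq_along(values),
                 time_s = seq_along(values) * 0.8,
                 segment = segment, value = values)
}

# brute-force quartile oracle: linear interpolation between order
# statistics at rank 1 + (n-1)p, written independently of stats::quantile
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- 1 + (length(x) - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# direct Eq-style Pearson oracle from the sum formula
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# literal DFT-sum periodogram of one frame: |sum x[n] e^(-i 2 pi n k / M)|^2 / M
oracle_periodogram <- function(x) {
  m <- length(x)
  ks <- 0:(m %/% 2)
  vapply(ks, function(k) {
    n <- 0:(m - 1)
    re <- sum(x * cos(-2 * pi * n * k / m))
    im <- sum(x * sin(-2 * pi * n * k / m))
    (re^2 + im^2) / m
  }, numeric(1))
}
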
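test_that("a zero-amplitude morphology yields a flat trace with fiducials", {
  m <- beat_morphology(amplitude_mV = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  beat <- generate_beat(m, rr_ms = 800, sampling_rate_hz = 500)
  expect_true(all(beat$signal == 0))
  expect_equal(nrow(beat$fiducials), 1)
  expect_false(anyNA(beat$fiducials))
})

test_that("the R sample equals the configured amplitude for a lone R wave", {
  m <- beat_morphology(amplitude_mV = c(P = 0, Q = 0, R = 1.0, S = 0, T = 0),
                       width_ms = c(P = 18, Q = 8, R = 12, S = 8, T = 30))
  beat <- generate_beat(m, rr_ms = 800, sampling_rate_hz = 500)
  r_idx <- beat$fiducials$r
  expect_equal(beat$signal[r_idx], 1.0, tolerance = 1e-6)
  expect_equal(max(beat$signal), 1.0, tolerance = 1e-6)
})

test_that("ground-truth QT of a beat equals the configured offset span", {
  m <- beat_morphology()
  beat <- generate_beat(m, rr_ms = 800, sampling_rate_hz = 500)
  qt_true <- (m$offset_ms[m$wave == "T"] +
                sqrt(2 * log(20)) * m$width_ms[m$wave == "T"]) -
    m$offset_ms[m$wave == "Q"]
  qt_emitted <- (beat$fiducials$t_end - beat$fiducials$q) / 500 * 1000
  expect_lt(abs(qt_emitted - qt_true), 2 / 500 * 1000 + 1e-9)
})

test_that("a too-short cycle is rejected with the conflicting spans named", {
  expect_error(generate_beat(beat_morphology(), rr_ms = 300,
                             sampling_rate_hz = 500),
               "shorter than the P-onset-to-T-end span")
})

test_that("session generation is fully reproducible from its seeds", {
  cfg <- quick_config(duration_s = 30, noise_sd_mV = 0.02, seed = 11)
  p1 <- generate_session_pair(cfg, glucose_effect(), 3, signal = TRUE)
  p2 <- generate_session_pair(cfg, glucose_effect(), 3, signal = TRUE)
  expect_identical(p1$G$record$ecg_mV, p2$G$record$ecg_mV)
  expect_identical(p1$NG$ground_truth, p2$NG$ground_truth)
  p3 <- generate_session_pair(cfg, glucose_effect(), 4, signal = FALSE)
  expect_false(identical(p1$G$ground_truth$rr_ms, p3$G$ground_truth$rr_ms))
})

test_that("fiducial indices increase within each beat and across beats", {
  cfg <- quick_config(duration_s = 60, seed = 5)
  gt <- generate_session_pair(cfg, glucose_effect(), 1,
                              signal = FALSE)$G$ground_truth
  idx <- as.matrix(gt[, c("idx_p_on", "idx_p_peak", "idx_q", "idx_r",
                          "idx_s", "idx_t_on", "idx_t_peak", "idx_t_end")])
  expect_true(all(apply(idx, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(diff(gt$idx_r) > 0))
  expect_true(all(gt$idx_p_on[-1] > gt$idx_t_end[-nrow(gt)]))
})

test_that("ground truth satisfies the segment definitions by construction", {
  cfg <- quick_config(duration_s = 120, seed = 9)
  eff <- glucose_effect(onset_s = 30, ramp_s = 20, rr_gain = 0.9,
                        qt_gain = 0.95, st_gain = 0.9)
  gt <- generate_session_pair(cfg, eff, 2, signal = FALSE)$G$ground_truth
  expect_equal(gt$hr_bpm, 60000 / gt$rr_ms)
  expect_equal(gt$qtc_ms, gt$qt_ms / sqrt(gt$rr_ms / 1000))
  expect_true(all(gt$qt_ms > gt$st_ms))
  expect_true(all(gt$rr_ms > 0 & gt$qrs_ms > 0 & gt$prq_ms > 0))
})

test_that("an rr_gain of 0.9 scales the post-onset mean RR by 0.9 within 1%", {
  cfg <- quick_config(duration_s = 7200, seed = 21)
  eff <- glucose_effect(onset_s = 1800, ramp_s = 300, rr_gain = 0.9)
  pair <- generate_session_pair(cfg, eff, 6, signal = FALSE)
  post <- function(gt) mean(gt$rr_ms[gt$time_s > 2100])
  ratio <- post(pair$G$ground_truth) / post(pair$NG$ground_truth)
  expect_lt(abs(ratio - 0.9), 0.01 * 0.9)
})

test_that("a 7200 s session at 66 bpm produces about 7920 beats", {
  cfg <- quick_config(duration_s = 7200, seed = 33)
  gt <- generate_session_pair(cfg, glucose_effect(), 10,
                              signal = FALSE)$G$ground_truth
  # consistency with the session's own mean cycle length
  expect_lt(abs(nrow(gt) - 7200 / (mean(gt$rr_ms) / 1000)), 3)
  # scale set by the configured baseline, within participant variation
  expect_lt(abs(nrow(gt) - 7920) / 7920, 0.15)
})

test_that("with all gains 1 the paired sessions show no systematic direction", {
  signs <- vapply(1:20, function(r) {
    cfg <- quick_config(duration_s = 300, seed = 100 + r)
    pair <- generate_session_pair(cfg, glucose_effect(), r, signal = FALSE)
    sign(median(pair$G$ground_truth$rr_ms) -
           median(pair$NG$ground_truth$rr_ms))
  }, numeric(1))
  n_pos <- sum(signs > 0)
  expect_gte(n_pos, 4)   # two-sided: a fair coin over 20 replicates
  expect_lte(n_pos, 16)
})

test_that("the effect is confined to the post-onset glucose session", {
  # pre-onset G window and the NG session are exchangeable: compare medians
  # across seeded replicates under a strong injected effect
  eff <- glucose_effect(onset_s = 150, ramp_s = 30, rr_gain = 0.85)
  deltas <- vapply(1:20, function(r) {
    cfg <- quick_config(duration_s = 300, seed = 400 + r)
    pair <- generate_session_pair(cfg, eff, r, signal = FALSE)
    g <- pair$G$ground_truth; ng <- pair$NG$ground_truth
    median(g$rr_ms[g$time_s < 150]) - median(ng$rr_ms[ng$time_s < 150])
  }, numeric(1))
  n_pos <- sum(deltas > 0)
  expect_gte(n_pos, 4)
  expect_lte(n_pos, 16)
  # while the post-onset window carries the full effect in every replicate
  cfg <- quick_config(duration_s = 300, seed = 401)
  pair <- generate_session_pair(cfg, eff, 1, signal = FALSE)
  g <- pair$G$ground_truth
  expect_lt(median(g$rr_ms[g$time_s > 200]), median(g$rr_ms[g$time_s < 150]))
})

test_that("cohorts are deterministic and singletons match the pair generator", {
  cfg <- quick_config(duration_s = 30, seed = 77)
  c1 <- generate_cohort(3, cfg, glucose_effect())
  c2 <- generate_cohort(3, cfg, glucose_effect())
  expect_identical(c1$ground_truth, c2$ground_truth)
  single <- generate_cohort(1, cfg, glucose_effect())
  pair <- generate_session_pair(cfg, glucose_effect(), 1, signal = FALSE)
  expect_identical(single$ground_truth[[1]], pair$G$ground_truth)
  expect_identical(single$ground_truth[[2]], pair$NG$ground_truth)
})

test_that("cohort_segments reshapes ground truth losslessly", {
  cfg <- quick_config(duration_s = 30, seed = 8)
  coh <- generate_cohort(2, cfg, glucose_effect())
  seg <- cohort_segments(coh)
  expect_setequal(unique(seg$segment), segment_ids())
  gt <- coh$ground_truth[[1]]
  qt <- seg$value[seg$participant == 1 & seg$session == "G" &
                    seg$segment == "QT"]
  expect_equal(qt, gt$qt_ms)
})
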
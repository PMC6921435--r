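test_that("boxplot summary matches hand-enumerated order statistics", {
  s <- boxplot_summary(c(1, 2, 3, 4, 5), "QT")
  expect_equal(s$q1, 2)
  expect_equal(s$mdn, 3)
  expect_equal(s$q3, 4)
  expect_equal(s$mn, 3)
  expect_equal(s$iq, 2)
  expect_equal(boxplot_summary(c(1, 1, 2, 9), "QT")$md, 1)
  expect_error(boxplot_summary(c(1, 2, 3), "QT"), "at least 4")
})

test_that("a degenerate distribution collapses every statistic", {
  s <- boxplot_summary(rep(7.25, 10), "R-H")
  expect_equal(s$md, 7.25)
  expect_equal(s$mn, 7.25)
  expect_equal(s$mdn, 7.25)
  expect_equal(s$iq, 0)
})

test_that("quartiles agree with a brute-force rank-interpolation oracle", {
  set.seed(42)
  for (i in 1:1000) {
    x <- stats::runif(sample(4:40, 1), 0, 1000)
    s <- boxplot_summary(x, "QT")
    expect_equal(s$q1, oracle_quantile(x, 0.25))
    expect_equal(s$mdn, oracle_quantile(x, 0.50))
    expect_equal(s$q3, oracle_quantile(x, 0.75))
    expect_equal(s$mn, sum(x) / length(x))
  }
})

test_that("mode ties break towards the smallest quantised value", {
  expect_equal(boxplot_summary(c(4, 4, 9, 9), "QT")$md, 4)
  # heights are quantised at 0.01 mV before counting
  expect_equal(boxplot_summary(c(1.112, 1.108, 1.3, 1.52), "R-H")$md, 1.11)
})

test_that("paired deltas follow the G-minus-NG definitions", {
  g <- boxplot_summary(c(800, 810, 820, 830, 840), "QT")
  ng <- boxplot_summary(c(780, 790, 800, 810, 820), "QT")
  d <- delta_summary(g, ng)
  expect_equal(d$d_mdn, 20)
  expect_equal(d$dir_mdn, "I")
  expect_equal(d$d_q, d$iq_g - d$iq_ng)
  # identical summaries: all deltas zero, all directions E
  d0 <- delta_summary(g, g)
  expect_true(all(unlist(d0[paste0("d_", stat_parameters())]) == 0))
  expect_true(all(unlist(d0[paste0("dir_", stat_parameters())]) == "E"))
  expect_error(delta_summary(g, boxplot_summary(1:5, "ST")), "different segments")
})

test_that("a narrower glucose interquartile range classifies as decrease", {
  g <- tibble::tibble(segment = "QT", md = 0, mn = 0, mdn = 0,
                      q1 = 0, q3 = 50)
  ng <- tibble::tibble(segment = "QT", md = 0, mn = 0, mdn = 0,
                       q1 = 0, q3 = 80)
  d <- delta_summary(g, ng)
  expect_equal(d$d_q, -30)
  expect_equal(d$dir_q, "D")
})

test_that("delta is antisymmetric in its sessions", {
  set.seed(7)
  for (i in 1:50) {
    a <- boxplot_summary(stats::rnorm(30, 800, 40), "QT")
    b <- boxplot_summary(stats::rnorm(30, 800, 40), "QT")
    ab <- delta_summary(a, b)
    ba <- delta_summary(b, a)
    for (p in stat_parameters()) {
      expect_equal(ab[[paste0("d_", p)]], -ba[[paste0("d_", p)]])
      expect_equal(ab[[paste0("dir_", p)]],
                   chartr("ID", "DI", ba[[paste0("dir_", p)]]))
    }
    expect_equal(ab$d_q, ab$iq_g - ab$iq_ng)
  }
})

test_that("directions inside the measurement resolution read as equality", {
  expect_equal(classify_direction(c(0.5, -0.5, 1, -1, 0), equal_tol = 1),
               c("E", "E", "I", "D", "E"))
  expect_equal(classify_direction(c(1e-8, -1e-8, 0)),
               c("I", "D", "E"))
})

test_that("correlation matches the sum-formula oracle and classifies sign", {
  a <- c(1, 2, 3); b <- c(1, 3, 2)
  r <- correlate(a, b)
  expect_equal(r$r, 0.5)
  expect_equal(r$r, oracle_pearson(a, b))
  expect_equal(r$class, "P")
  x <- stats::rnorm(40)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, 2 * x + 1)$class, "P")
  expect_equal(correlate(x, -x)$r, -1)
  expect_equal(correlate(x, -x)$class, "N")
  set.seed(13)
  for (i in 1:25) {
    a <- stats::rnorm(20); b <- stats::rnorm(20)
    expect_equal(correlate(a, b)$r, oracle_pearson(a, b))
  }
})

test_that("correlation is symmetric and affine-invariant", {
  set.seed(5)
  a <- stats::rnorm(30); b <- stats::rnorm(30)
  expect_equal(correlate(a, b)$r, correlate(b, a)$r)
  expect_equal(correlate(3 * a + 2, b)$r, correlate(a, b)$r)
  expect_equal(correlate(a, 0.1 * b - 7)$r, correlate(a, b)$r)
})

test_that("zero-variance series are flagged undefined with class Z", {
  r <- correlate(rep(1, 10), stats::rnorm(10))
  expect_true(is.na(r$r))
  expect_equal(r$class, "Z")
  expect_error(correlate(c(1, 2), c(1, 2)), "at least 3")
})

test_that("series are aligned on the intersection of retained beats", {
  a <- as_series(c(1, 2, 3, 4, 5), "QT")
  b <- as_series(c(10, 30, 20, 50), "ST")
  b$beat_index <- c(1, 3, 4, 6)       # beats 2 and 5 dropped upstream
  r <- correlate(a, b)
  expect_equal(r$n, 3)
  expect_equal(r$r, oracle_pearson(c(1, 3, 4), c(10, 30, 20)))
})

test_that("correlation percentages use half-up integer rounding", {
  res <- tibble::tibble(
    participant = 1:16, segment_a = "QT", segment_b = "RR-I",
    n = 100, r = c(rep(-0.5, 13), rep(0.4, 3)),
    class = c(rep("N", 13), rep("P", 3)))
  pct <- correlation_percentage(res)
  expect_equal(pct$pct_N, 81)   # 13/16 = 81.25
  expect_equal(pct$pct_P, 19)
  res$class <- c(rep("N", 11), rep("P", 5))
  expect_equal(correlation_percentage(res)$pct_N, 69)  # 11/16 = 68.75
})
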
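test_that("direction tallies count and percentage per the cohort rule", {
  t1 <- tally_directions(c(rep("D", 13), rep("I", 3)))
  expect_equal(t1$n_D, 13)
  expect_equal(t1$pct_D, 1300 / 16)
  expect_equal(round_half_up(t1$pct_D), 81)     # 81.25 prints as 81
  expect_equal(round_half_up(t1$pct_I), 19)
  expect_equal(t1$pct_I + t1$pct_D + t1$pct_E, 100)
  t2 <- tally_directions(rep("E", 16))
  expect_equal(t2$pct_E, 100)
  t3 <- tally_directions(c(rep("D", 8), rep("I", 8)))
  expect_equal(t3$pct_D, 50)
  expect_equal(t3$pct_I, 50)
})

test_that("percentages over the three directions always sum to 100", {
  set.seed(2)
  for (i in 1:50) {
    d <- sample(c("I", "D", "E"), sample(1:40, 1), replace = TRUE)
    t <- tally_directions(d)
    expect_equal(t$pct_I + t$pct_D + t$pct_E, 100)
    expect_equal(t$n_I + t$n_D + t$n_E, t$n)
  }
})

test_that("status bands follow the inclusive 80/60 boundaries", {
  expect_equal(classify_status(c(81, 75, 56)), c("h", "m", "l"))
  expect_equal(classify_status(c(100, 80, 79.99, 60, 59.99, 0)),
               c("h", "h", "m", "m", "l", "l"))
})

test_that("status classification is monotone in the percentage", {
  ord <- c(l = 1, m = 2, h = 3)
  pcts <- sort(stats::runif(200, 0, 100))
  expect_true(all(diff(ord[classify_status(pcts)]) >= 0))
})

test_that("the statistical change decision scores moderate+strong of six", {
  d <- statistical_change_decision(c("h", "h", "h", "h", "m", "m"))
  expect_equal(d$total, 6)
  expect_equal(d$change, "Yes")
  d0 <- statistical_change_decision(rep("l", 6))
  expect_equal(d0$total, 0)
  expect_equal(d0$change, "No")
  d3 <- statistical_change_decision(c("m", "m", "h", "l", "l", "l"))
  expect_equal(d3$total, 3)
  expect_equal(d3$change, "No")
  expect_error(statistical_change_decision(c("h", "m")), "6 parameter")
})

test_that("equality-dominated parameters do not count towards the score", {
  st <- c("h", "h", "h", "h", "m", "m")
  pat <- c("D", "D", "E", "E", "E", "E")
  expect_equal(statistical_change_decision(st, pat)$total, 2)
  expect_equal(statistical_change_decision(st, pat)$change, "No")
})

test_that("the spectral change rule is inclusive at 60%", {
  mk <- function(n_d, n_i) tally_directions(c(rep("D", n_d), rep("I", n_i)))
  expect_equal(spectral_change_decision(mk(12, 4))$change, "Yes")   # 75%
  expect_equal(spectral_change_decision(mk(9, 7))$change, "No")     # 56.25%
  expect_equal(spectral_change_decision(mk(12, 8))$change, "Yes")   # 60% exact
  d <- spectral_change_decision(mk(12, 4))
  expect_equal(d$pattern, "D")
  expect_equal(d$status, "m")
})

test_that("sensitivities are shares of the status labels, one decimal", {
  s <- sensitivity(c(rep("h", 5), "l"))
  expect_equal(s$S_h, 83.3)
  expect_equal(s$S_m, 0)
  expect_equal(s$S_l, 16.7)
  s2 <- sensitivity(c(rep("h", 4), rep("m", 2)))
  expect_equal(s2$S_h, 66.7)
  expect_equal(s2$S_m, 33.3)
  expect_equal(sensitivity(rep("h", 3))$S_h, 100)
})

test_that("sensitivity shares sum to 100 before rounding", {
  set.seed(11)
  for (i in 1:50) {
    st <- sample(c("h", "m", "l"), sample(1:30, 1), replace = TRUE)
    n <- length(st)
    raw <- c(sum(st == "l"), sum(st == "m"), sum(st == "h")) / n * 100
    expect_equal(sum(raw), 100)
  }
})

test_that("the report reproduces the published affected-segment set", {
  # the spectral summary table fed in verbatim: dominant patterns and
  # percentages as printed, complements computed consistently
  printed <- tibble::tibble(
    segment = c("ST", "QTC", "QT", "PRQ", "QRS", "P-H", "R-H", "HR", "HRV"),
    n_d = c(12, 9, 10, 11, 9, 8, 9, 12, 13),
    n_i = 16 - c(12, 9, 10, 11, 9, 8, 9, 12, 13))
  decisions <- purrr::pmap_dfr(printed, function(segment, n_d, n_i) {
    t <- tally_directions(c(rep("D", n_d), rep("I", n_i)))
    dplyr::bind_cols(tibble::tibble(segment = segment),
                     spectral_change_decision(t))
  })
  expect_setequal(decisions$segment[decisions$change == "Yes"],
                  c("ST", "QT", "PRQ", "HR", "HRV"))
  expect_equal(decisions$status[decisions$segment == "HRV"], "h")   # 81%
  expect_equal(decisions$status[decisions$segment == "QTC"], "l")   # 56%
})

test_that("single-participant percentages are only 0 or 100", {
  dirs <- tibble::tibble(participant = 1, segment = "QT",
                         parameter = stat_parameters(),
                         direction = c("I", "I", "D", "E", "I", "D"))
  rep1 <- build_report(dirs)
  expect_true(all(rep1$stat_tally$pct_I %in% c(0, 100)))
  expect_true(all(rep1$stat_tally$pct %in% c(0, 100)))
})

test_that("build_report assembles tallies, decisions and sensitivities", {
  set.seed(4)
  dirs <- tidyr::expand_grid(participant = 1:16,
                             segment = c("QT", "QRS"),
                             parameter = stat_parameters())
  # QT: strong decrease for everyone; QRS: random coin flips
  dirs$direction <- ifelse(dirs$segment == "QT", "D",
                           sample(c("I", "D"), nrow(dirs), replace = TRUE))
  rep <- build_report(dirs)
  expect_equal(nrow(rep$stat_tally), 12)
  qt <- rep$stat_decisions[rep$stat_decisions$segment == "QT", ]
  expect_equal(qt$total, 6)
  expect_equal(qt$change, "Yes")
  sens_qt <- rep$stat_sensitivity[rep$stat_sensitivity$segment == "QT", ]
  expect_equal(sens_qt$pattern, "D")
  expect_equal(sens_qt$S_h, 100)
  expect_equal(nrow(rep$direction_matrix), nrow(dirs))
})
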
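test_that("cumulative life events form a running sum", {
  expect_equal(cumulative_life_events(c(5, 0, 2)), c(5, 5, 7))
  expect_equal(cumulative_life_events(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(cumulative_life_events(4), 4)
  expect_error(cumulative_life_events(c(3, -1)), "nonnegative")
})

test_that("log scaling reproduces the published boundary correspondence", {
  expect_equal(log_scale(0), 0)
  expect_equal(round(log_scale(13), 2), 2.64)
  expect_equal(round(log_scale(93), 2), 4.54)
  expect_error(log_scale(-1), "nonnegative")
})

test_that("median split labels, ties and rendering", {
  r <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(r$labels), c("Low", "Low", "High", "High"))
  expect_equal(r$map$boundary, 2.5)
  # ties at the median go Low
  r2 <- median_split(c(1, 2, 2, 3))
  expect_equal(as.character(r2$labels), c("Low", "Low", "Low", "High"))
  expect_error(median_split(rep(5, 10)), "degenerate")
  expect_error(median_split(3), "two non-missing")
  # rendered span in the published style
  stiff <- c(1543, 2000, 2330, 3000, 4518)
  r3 <- median_split(stiff, "stiffness", digits = 0)
  expect_equal(r3$map$render,
               "1,543-2,330 (Low)  >2,330-4,518 (High)")
})

test_that("median split balance property", {
  set.seed(4)
  for (k in 1:10) {
    # tie-free data: the split is balanced up to the odd middle value
    x <- stats::runif(49 + (k %% 2))
    r <- median_split(x)
    ties <- sum(x == r$map$boundary)
    expect_lte(abs(sum(r$labels == "Low") - sum(r$labels == "High")),
               max(ties, 0L))
    expect_true(all(x[r$labels == "Low"] <= r$map$boundary))
    expect_true(all(x[r$labels == "High"] > r$map$boundary))
  }
})

test_that("bagged-tree imputation recovers a noisy linear signal", {
  set.seed(2)
  x <- rnorm(1000)
  y <- 2 * x + rnorm(1000, sd = 0.1)
  d <- data.frame(x = x, y = y)
  masked <- sample(1000, 100)
  truth <- d$y[masked]
  d$y[masked] <- NA
  done <- impute_bagged_trees(d, seed = 5)
  expect_false(anyNA(done$y))
  expect_gte(mean(abs(done$y[masked] - truth) < 3 * 0.1), 0.9)
  # observed entries untouched
  expect_identical(done$y[-masked], y[-masked])
  # determinism
  expect_identical(impute_bagged_trees(d, seed = 5), done)
  # complete table passes through unchanged
  expect_identical(impute_bagged_trees(data.frame(a = 1:5, b = 6:10)),
                   data.frame(a = 1:5, b = 6:10))
  expect_error(impute_bagged_trees(data.frame(a = c(NA_real_, NA_real_),
                                              b = c(1, 2))),
               "entirely missing")
})

test_that("two-time-slice table has the right rows and no reversed pairs", {
  co <- cached_imputed_cohort()
  tb <- build_2tbn_table(co)
  d <- tb$data
  # 136 participants with T1-T3 contribute 2 rows, 121 with T1-T2 one row
  expect_equal(nrow(d), 2 * 136 + 121)
  expect_setequal(unique(d$pair), c("T1_T2", "T2_T3"))
  counts <- table(table(d$participant))
  expect_equal(unname(counts[["1"]]), 121)
  expect_equal(unname(counts[["2"]]), 136)
  # dropouts contribute nothing
  all_ids <- unique(co$participant)
  expect_false(any(setdiff(all_ids, injurybn:::retained_ids(co)) %in%
                     d$participant))
  # every analysis variable is binary Low/High except the categoricals
  for (v in c("nle_1", "stiffness_2", "hrv_1", "balance_2"))
    expect_setequal(levels(d[[v]]), c("Low", "High"))
  expect_false(anyNA(d))
})

test_that("discretisation uses per-time-point boundaries for nle", {
  co <- cached_imputed_cohort()
  disc <- discretise_cohort(co)
  expect_true(all(c("nle_1", "nle_2", "nle_3") %in% names(disc$maps)))
  # cumulative log scores push later boundaries upward
  expect_gt(disc$maps$nle_3$boundary, disc$maps$nle_1$boundary)
  expect_match(disc$maps$stiffness_1$render, "\\(Low\\)  >")
})

test_that("change table is standardised with an any-injury outcome", {
  co <- cached_imputed_cohort()
  chg <- build_change_table(co)
  d <- chg$data
  expect_equal(nrow(d), 2 * 136 + 121)
  for (v in grep("^d_", names(d), value = TRUE)) {
    expect_lt(abs(mean(d[[v]])), 1e-8)
    expect_lt(abs(stats::sd(d[[v]]) - 1), 1e-8)
  }
  expect_setequal(levels(d$injured), c("healthy", "injured"))
  expect_false("baseline_nle" %in% names(d))
  # a participant injured in any interval is flagged on every row
  inj_by_pid <- tapply(co$injured == "injured", co$participant,
                       function(x) any(x, na.rm = TRUE))
  for (pid in unique(d$participant)[1:25]) {
    expect_equal(unique(as.character(d$injured[d$participant == pid])),
                 if (inj_by_pid[[as.character(pid)]]) "injured" else
                   "healthy")
  }
})
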
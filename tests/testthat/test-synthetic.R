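test_that("ground truth model satisfies its invariants", {
  m <- default_ground_truth()
  expect_s3_class(m, "cohort_model")
  for (p in m$discrete) expect_lt(abs(sum(p) - 1), 1e-9)
  expect_error(default_ground_truth(-0.5), "nonnegative")
  # zero effect scale: injury probability constant in its parents
  m0 <- default_ground_truth(0)
  p00 <- injury_probability(m0, 0, 0, 0)
  expect_equal(injury_probability(m0, 500, 20, 400), p00)
  # positive effect scale: exact ordering of the logistic model
  m1 <- default_ground_truth(1)
  expect_gt(injury_probability(m1, 400, 10), injury_probability(m1, -400, -10))
  expect_true(all(injury_probability(m1, c(-1e4, 0, 1e4), 0) > 0))
  expect_true(all(injury_probability(m1, c(-1e4, 0, 1e4), 0) < 1))
})

test_that("cohort sampling honours the recruitment pattern", {
  co <- small_cohort(seed = 7)
  d <- cohort_descriptives(co)
  expect_equal(d$n_recruited, 351)
  expect_equal(d$n_retained, 257)
  expect_equal(d$n_t1_only, 94)
  expect_equal(d$n_measurements, 650)
  # dropouts have a single T1 row
  tp_counts <- table(co$participant)
  expect_equal(sum(tp_counts == 1), 94)
  # injury status never reported at T1
  expect_true(all(is.na(co$injured[co$time == "T1"])))
  expect_true(all(!is.na(co$injured[co$time == "T4"])))
})

test_that("cohort sampling is deterministic and handles n = 0", {
  m <- default_ground_truth()
  sp <- cohort_spec(seed = 123)
  expect_identical(sample_cohort(m, sp), sample_cohort(m, sp))
  sp2 <- cohort_spec(seed = 124)
  expect_false(identical(sample_cohort(m, sp), sample_cohort(m, sp2)))
  empty <- sample_cohort(m, cohort_spec(n_recruited = 0, n_t1_only = 0,
                                        n_t2_only = 0))
  expect_equal(nrow(empty), 0)
  expect_setequal(names(empty), names(sample_cohort(m, sp)))
})

test_that("missingness injection matches the requested rates", {
  co <- small_cohort(seed = 21, miss_stiff = 0, miss_hrv = 0)
  # rate zero: identity
  expect_identical(co$stiffness, sample_cohort(
    default_ground_truth(),
    cohort_spec(seed = 21, missing_rate_stiffness = 0,
                missing_rate_hrv = 0))$stiffness)
  d <- cohort_descriptives(co)
  expect_equal(d$n_missing_stiffness, 0)
  # study rates: binomial check around 31 / 650 and 70 / 650
  co2 <- small_cohort(seed = 22)
  d2 <- cohort_descriptives(co2)
  se_s <- sqrt(650 * 0.0477 * (1 - 0.0477))
  se_h <- sqrt(650 * 0.1077 * (1 - 0.1077))
  expect_lt(abs(d2$n_missing_stiffness - 31), 3 * se_s)
  expect_lt(abs(d2$n_missing_hrv - 70), 3 * se_h)
  # rate one: everything masked
  co3 <- small_cohort(seed = 23, miss_stiff = 1, miss_hrv = 1)
  meas <- co3$time %in% c("T1", "T2", "T3") &
    co3$participant %in% injurybn:::retained_ids(co3)
  expect_true(all(is.na(co3$stiffness[meas])))
  expect_error(inject_missingness(co3, cohort_spec()), "already")
})

test_that("null injury model yields the base rate empirically", {
  m0 <- default_ground_truth(0)
  sp <- cohort_spec(n_recruited = 4000, n_t1_only = 0, n_t2_only = 0,
                    missing_rate_stiffness = 0, missing_rate_hrv = 0,
                    seed = 31)
  co <- sample_cohort(m0, sp)
  reports <- co$injured[!is.na(co$injured)]
  n <- length(reports)  # 3 reports x 4000 participants
  expect_equal(n, 12000)
  base <- stats::plogis(m0$injury$intercept)
  se <- sqrt(base * (1 - base) / n)
  expect_lt(abs(mean(reports == "injured") - base), 3 * se)
})

test_that("life-event scores are right-skewed with many zeros", {
  co <- small_cohort(seed = 41)
  later <- co$nle[co$time %in% c("T2", "T3") & !is.na(co$nle)]
  expect_gt(mean(later == 0), 0.15)
  expect_lt(mean(later == 0), 0.40)
  expect_gt(mean(later), stats::median(later))  # right skew
})

test_that("synthetic ibi series hit the requested rmssd", {
  flat <- generate_ibi_series(800, 0, 660)
  expect_equal(unname(compute_rmssd(flat)["rmssd"]), 0)
  s <- generate_ibi_series(800, 50, 660)
  expect_lt(abs(compute_rmssd(s)["rmssd"] - 50), 2.5)
  # artifacts: filtering brings rmssd back toward the target
  sa <- generate_ibi_series(800, 50, 660, seed = 3, artifact_rate = 0.05)
  raw <- unname(compute_rmssd(sa)["rmssd"])
  filt <- unname(compute_rmssd(filter_ibi(sa, 0.2))["rmssd"])
  expect_lt(abs(filt - 50), abs(raw - 50))
  expect_error(generate_ibi_series(800, 50, 200), "5-min")
})
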
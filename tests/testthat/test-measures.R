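test_that("life-event scoring follows the sum rules", {
  r <- rep(NA_real_, 69)
  r[1:3] <- c(-3, 2, -1)
  expect_equal(score_lesca(r), c(nle = 4, ple = 2, tle = 6))
  expect_equal(score_lesca(rep(NA_real_, 69)), c(nle = 0, ple = 0, tle = 0))
  expect_equal(unname(score_lesca(rep(-4, 69))["nle"]), 276)
  expect_error(score_lesca(rep(NA_real_, 68)), "69 items")
  bad <- rep(NA_real_, 69); bad[1] <- 5
  expect_error(score_lesca(bad), "-4..4")
})

test_that("life-event scores are permutation invariant and additive", {
  set.seed(1)
  for (k in 1:20) {
    r <- rep(NA_real_, 69)
    idx <- sample(69, sample(0:69, 1))
    r[idx] <- sample(c(-4:-1, 1:4), length(idx), replace = TRUE)
    s <- score_lesca(r)
    expect_equal(unname(s["tle"]), unname(s["nle"] + s["ple"]))
    expect_equal(score_lesca(sample(r)), s)
  }
})

test_that("personality subscale sums respect their bounds", {
  map <- rstpq_default_map()
  expect_length(map, 51)
  expect_equal(sum(map == "BIS"), 17)  # pinned by the 17-68 score span
  lo <- score_rstpq(rep(1L, 51))
  hi <- score_rstpq(rep(4L, 51))
  counts <- table(map)[names(lo)]
  expect_equal(unname(lo), as.vector(counts))
  expect_equal(unname(hi), as.vector(4 * counts))
  expect_equal(unname(hi["BIS"]), 68)
  expect_error(score_rstpq(rep(0L, 51)), "1..4")
  expect_error(score_rstpq(rep(1L, 50)), "length")
})

test_that("artifact filter removes ectopic beats and is idempotent", {
  clean <- rep(800, 100)
  expect_equal(filter_ibi(clean), clean)
  dirty <- clean; dirty[50] <- 2000
  expect_equal(filter_ibi(dirty, 0.2), clean[-50])
  mild <- clean; mild[50] <- 1500  # 87.5% off the local median
  expect_equal(filter_ibi(mild, 0.999), mild)  # near-vacuous threshold
  set.seed(2)
  wob <- rnorm(300, 800, 20)
  once <- filter_ibi(wob, 0.2)
  expect_equal(filter_ibi(once, 0.2), once)
  expect_true(all(once %in% wob))
  expect_error(filter_ibi(c(100, 100000, 100000, 100), 0.0001), "rejected")
})

test_that("rmssd of trimmed window matches hand computations", {
  expect_equal(unname(compute_rmssd(rep(800, 800))["rmssd"]), 0)
  alt <- rep(c(800, 850), 400)
  expect_equal(unname(compute_rmssd(alt)["rmssd"]), 50)
  # ln scale consistency with the published Low/High boundary: a window
  # with rmssd exp(4.01) has ln_rmssd 4.01
  alt2 <- rep(c(800, 800 + exp(4.01)), 400)
  expect_equal(unname(compute_rmssd(alt2)["ln_rmssd"]), 4.01,
               tolerance = 1e-9)
  expect_error(compute_rmssd(rep(800, 10)), "fewer than 2")
})

test_that("rmssd ignores beats wholly inside the trimmed regions", {
  base <- rep(c(800, 850), 400)
  # pads of whole alternating periods keep every successive difference at
  # +-50 ms, so the trimmed-window RMSSD must be exactly 50 regardless
  padded <- c(rep(c(800, 850), 12), base, rep(c(800, 850), 12))
  expect_equal(unname(compute_rmssd(base)["rmssd"]),
               unname(compute_rmssd(padded)["rmssd"]))
})

test_that("stiffness totals use the site medians and CV gate", {
  sites <- rep(list(rep(300, 5)), 8)
  r <- total_stiffness(sites)
  expect_equal(r$total, 2400)
  expect_length(r$flagged, 0)
  sites[[3]] <- c(290, 295, 300, 305, 400)
  r2 <- total_stiffness(sites)
  expect_true("site3" %in% r2$flagged)  # CV > 3%
  expect_equal(unname(r2$site_values[3]), 300)  # median robust to outlier
  expect_equal(unname(total_stiffness(c(list(c(1, 2, 3, 4, 100)),
                                        rep(list(rep(1, 5)), 7)))$site_values[1]),
               3)
  expect_error(total_stiffness(sites[1:7]), "8 sites")
  sites[[1]] <- 1:4
  expect_error(total_stiffness(sites), "5 impulses")
})

test_that("stiffness total is permutation invariant across sites", {
  set.seed(3)
  sites <- lapply(1:8, function(i) rnorm(5, 300, 2))
  expect_equal(total_stiffness(sites)$total,
               total_stiffness(rev(sites))$total)
})

test_that("balance error scoring caps, sums and measures asymmetry", {
  zero <- c(dl_firm = 0, ndl_firm = 0, ts_firm = 0, dl_foam = 0,
            ndl_foam = 0, ts_foam = 0)
  expect_equal(score_bess(zero), c(total = 0, asymmetry = 0))
  expect_equal(unname(score_bess(zero + 10)["total"]), 60)
  tr <- c(dl_firm = 4, ndl_firm = 2, ts_firm = 1, dl_foam = 4,
          ndl_foam = 2, ts_foam = 3)
  r <- score_bess(tr)
  expect_equal(unname(r["total"]), 16)
  expect_equal(unname(r["asymmetry"]), 100 * abs(8 - 4) / 6)
  expect_error(score_bess(zero + 11), "0..10")
  expect_error(score_bess(zero[-1]), "missing")
})

test_that("ibi text files round-trip, tolerating a header", {
  f <- tempfile(fileext = ".txt")
  x <- c(812, 795, 803.5)
  write_ibi(x, f)
  expect_equal(read_ibi(f), x)
  writeLines(c("Polar export", "812", "795"), f)
  expect_equal(read_ibi(f), c(812, 795))
  writeLines(c("812", "oops", "795"), f)
  expect_error(read_ibi(f), "non-numeric")
})
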
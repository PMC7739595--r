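test_that("empty-graph BIC matches the closed form", {
  # two independent binary columns with exact 50/50 splits at n = 100:
  # each family scores 100 log(1/2) - (1/2) log(100)
  d <- data.frame(a = factor(rep(c("l", "h"), 50)),
                  b = factor(rep(c("l", "h"), each = 50)))
  expected_family <- 100 * log(0.5) - 0.5 * log(100)
  expect_equal(bic_score(dag(c("a", "b")), d), 2 * expected_family)
  # decomposability: empty-graph score is the sum of marginal families
  ctx <- injurybn:::score_context(d)
  expect_equal(bic_score(dag(c("a", "b")), d),
               injurybn:::family_score(ctx, "a", character(0)) +
                 injurybn:::family_score(ctx, "b", character(0)))
})

test_that("an arc between independent variables lowers the score", {
  set.seed(10)
  n <- 10000
  d <- data.frame(a = factor(sample(c("l", "h"), n, TRUE)),
                  b = factor(sample(c("l", "h"), n, TRUE)))
  s0 <- bic_score(dag(c("a", "b")), d)
  s1 <- bic_score(dag(c("a", "b"), rbind(c("a", "b"))), d)
  expect_gt(s0, s1)
})

test_that("score equivalence: both orientations of one arc score alike", {
  set.seed(11)
  for (k in 1:5) {
    net <- random_discrete_net(2, seed = 50 + k, arc_prob = 1)
    d <- sample_net_data(net, 400, seed = k)
    s_ab <- bic_score(dag(c("a", "b"), rbind(c("a", "b"))), d)
    s_ba <- bic_score(dag(c("a", "b"), rbind(c("b", "a"))), d)
    expect_equal(s_ab, s_ba, tolerance = 1e-12)
  }
})

test_that("score is decomposable under single-arc moves", {
  net <- random_discrete_net(5, seed = 77, arc_prob = 0.5)
  d <- sample_net_data(net, 300, seed = 2)
  g0 <- dag(names(d), rbind(c("a", "b"), c("c", "b")))
  g1 <- dag(names(d), rbind(c("a", "b"), c("c", "b"), c("d", "e")))
  ctx <- injurybn:::score_context(d)
  # adding d -> e changes only e's family score
  delta <- bic_score(g1, d) - bic_score(g0, d)
  fam_delta <- injurybn:::family_score(ctx, "e", "d") -
    injurybn:::family_score(ctx, "e", character(0))
  expect_equal(delta, fam_delta)
})

test_that("conditional-Gaussian families are scored and fitted sanely", {
  set.seed(12)
  n <- 2000
  x <- rnorm(n)
  y <- 2 + 3 * x + rnorm(n, sd = 0.5)
  d <- data.frame(x = x, y = y)
  # the true arc beats independence and the reverse scores equivalently
  s_arc <- bic_score(dag(c("x", "y"), rbind(c("x", "y"))), d)
  s_ind <- bic_score(dag(c("x", "y")), d)
  expect_gt(s_arc, s_ind)
  fit <- fit_parameters(dag(c("x", "y"), rbind(c("x", "y"))), d)
  co <- fit$nodes$y$coef
  se_slope <- 0.5 / sqrt(n)
  expect_lt(abs(co[1, "(Intercept)"] - 2), 3 * 0.5 / sqrt(n))
  expect_lt(abs(co[1, "x"] - 3), 3 * se_slope)
  expect_lt(abs(fit$nodes$y$sd[1] - 0.5), 3 * 0.5 / sqrt(2 * n))
  # a discrete child may never have a continuous parent
  d2 <- data.frame(x = x, z = factor(sample(c("l", "h"), n, TRUE)))
  expect_equal(bic_score(dag(c("x", "z"), rbind(c("x", "z"))), d2), -Inf)
})

test_that("parameter-space counting follows the stated convention", {
  expect_equal(parameter_space_size(10, 2), 100)
  expect_equal(parameter_space_size(10, 3), 1000)
})

test_that("scoring rejects incomplete or mismatched data", {
  d <- data.frame(a = factor(c("l", NA, "h")))
  expect_error(bic_score(dag("a"), d), "missing")
  expect_error(bic_score(dag(c("a", "zz")),
                         data.frame(a = factor("l"))), "lacks columns")
})
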
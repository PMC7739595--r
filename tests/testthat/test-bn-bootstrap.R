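test_that("whitelisted arcs have strength one; noise stays weak", {
  set.seed(40)
  n <- 300
  d <- data.frame(a = factor(sample(c("l", "h"), n, TRUE)),
                  b = factor(sample(c("l", "h"), n, TRUE)),
                  c = factor(sample(c("l", "h"), n, TRUE)))
  cons <- constraints(whitelist = rbind(c("a", "b")))
  st <- bootstrap_strength(d, cons,
                           search_params(bootstrap_reps = 100, seed = 2))
  wl_row <- st[st$from == "a" & st$to == "b", ]
  expect_equal(wl_row$strength, 1)
  expect_equal(wl_row$direction, 1)
  others <- st[!(st$from == "a" & st$to == "b"), ]
  if (nrow(others)) expect_true(all(others$strength < 0.3))
})

test_that("a single replicate gives zero-one strengths", {
  net <- random_discrete_net(4, seed = 41, strong = TRUE, arc_prob = 0.6)
  d <- sample_net_data(net, 400, seed = 3)
  st <- bootstrap_strength(d, params = search_params(bootstrap_reps = 1,
                                                     seed = 4))
  expect_true(all(st$strength %in% c(0, 1)))
})

test_that("bootstrap strengths are deterministic given the seed", {
  net <- random_discrete_net(4, seed = 42, strong = TRUE, arc_prob = 0.6)
  d <- sample_net_data(net, 200, seed = 5)
  p <- search_params(bootstrap_reps = 25, seed = 9)
  expect_identical(bootstrap_strength(d, params = p),
                   bootstrap_strength(d, params = p))
})

test_that("averaging applies the inclusion and significance thresholds", {
  st <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                   strength = c(0.94, 0.47, 0.25),
                   direction = c(0.9, 0.8, 0.7))
  class(st) <- c("bn_arc_strength", "data.frame")
  attr(st, "nodes") <- c("a", "b", "c", "d")
  avg <- average_network(st)
  expect_equal(nrow(avg$arcs), 2)
  expect_equal(avg$arcs$significance[avg$arcs$from == "a"], "significant")
  expect_equal(avg$arcs$significance[avg$arcs$from == "b"],
               "non-significant")
  expect_false("d" %in% c(avg$arcs$from, avg$arcs$to))
  # inclusion is >= by default, > when strict
  st$strength <- c(0.3, 0.3, 0.3)
  expect_equal(nrow(average_network(st)$arcs), 3)
  expect_equal(nrow(average_network(st, strict = TRUE)$arcs), 0)
})

test_that("averaging orients by majority direction and repairs cycles", {
  st <- data.frame(from = c("a", "b"), to = c("b", "c"),
                   strength = c(1, 1), direction = c(0.2, 0.9))
  class(st) <- c("bn_arc_strength", "data.frame")
  attr(st, "nodes") <- c("a", "b", "c")
  avg <- average_network(st)
  expect_true(any(avg$arcs$from == "b" & avg$arcs$to == "a"))
  # a thresholded 3-cycle loses its weakest arc
  cyc <- data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"),
                    strength = c(0.9, 0.8, 0.6),
                    direction = c(0.9, 0.9, 0.1))  # a->b, b->c, c->a
  class(cyc) <- c("bn_arc_strength", "data.frame")
  attr(cyc, "nodes") <- c("a", "b", "c")
  avg2 <- average_network(cyc)
  expect_true(is_acyclic(avg2$dag))
  expect_equal(nrow(avg2$arcs), 2)
  expect_false(any(avg2$arcs$strength == 0.6))
  # unanimity keeps everything; empty table gives an empty graph
  expect_equal(nrow(average_network(st)$arcs), 2)
  empty <- st[0, ]
  class(empty) <- c("bn_arc_strength", "data.frame")
  attr(empty, "nodes") <- c("a", "b")
  expect_equal(nrow(average_network(empty)$dag$arcs), 0)
})

test_that("strength tables round-trip through CSV", {
  st <- data.frame(from = "a", to = "b", strength = 0.75, direction = 0.6)
  class(st) <- c("bn_arc_strength", "data.frame")
  f <- tempfile(fileext = ".csv")
  write_strengths_csv(st, f)
  st2 <- read_strengths_csv(f)
  expect_equal(st2$strength, 0.75)
  expect_equal(st2$direction, 0.6)
})

test_that("bootstrap recovers a strong 6-node skeleton", {
  # one seed of the structure-recovery experiment (the 20-seed version
  # is the acceptance criterion)
  net <- random_discrete_net(6, seed = 900, strong = TRUE,
                             arc_prob = 0.25, max_parents = 2)
  d <- sample_net_data(net, 5000, seed = 6)
  st <- bootstrap_strength(d, params = search_params(bootstrap_reps = 50,
                                                     seed = 7))
  true_key <- paste(pmin(net$dag$arcs[, 1], net$dag$arcs[, 2]),
                    pmax(net$dag$arcs[, 1], net$dag$arcs[, 2]))
  got_key <- paste(pmin(st$from, st$to), pmax(st$from, st$to))
  strength_of <- function(k)
    if (any(got_key == k)) st$strength[got_key == k] else 0
  for (k in true_key) expect_gte(strength_of(k), 0.8)
  expect_true(all(st$strength[!(got_key %in% true_key)] <= 0.3))
})
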
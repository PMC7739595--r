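# Hand-built and randomly generated discrete networks used as oracles.

# Build a bn_fit-compatible discrete network directly from CPT matrices.
# cpts: named list, node -> (states x parent-configs) matrix with state
# rownames; parent configurations are ordered with the FIRST parent
# varying fastest, levels as in the parents' own CPT rownames.
manual_discrete_net <- function(g, cpts) {
  nodes <- lapply(g$nodes, function(v) {
    ps <- parents(g, v)
    plev <- lapply(ps, function(p) rownames(cpts[[p]]))
    names(plev) <- ps
    list(type = "discrete", levels = rownames(cpts[[v]]), parents = ps,
         parent_levels = plev, cpt = cpts[[v]])
  })
  names(nodes) <- g$nodes
  structure(list(dag = g, nodes = nodes, n = 0L, hybrid = FALSE),
            class = "bn_fit")
}

# Random binary-node network over letters[1:n_nodes].  strong = TRUE
# gives monotone logistic conditionals with +-2 log-odds per parent,
# centred so no configuration saturates, and caps the in-degree at 3 —
# the operational meaning of "strong, individually detectable effects":
# a family whose log-odds saturate makes its weakest arc statistically
# invisible regardless of sample size.
random_discrete_net <- function(n_nodes = 4, seed = 1, strong = FALSE,
                                arc_prob = 0.4,
                                max_parents = if (strong) 3L else Inf) {
  set.seed(seed)
  nm <- letters[seq_len(n_nodes)]
  ord <- sample(nm)
  arcs <- NULL
  indeg <- stats::setNames(rep(0L, n_nodes), nm)
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq(i + 1, n_nodes)) {
      if (stats::runif(1) < arc_prob && indeg[[ord[j]]] < max_parents) {
        arcs <- rbind(arcs, c(ord[i], ord[j]))
        indeg[[ord[j]]] <- indeg[[ord[j]]] + 1L
      }
    }
  }
  g <- dag(nm, arcs)
  cpts <- list()
  for (v in nm) {
    ps <- parents(g, v)
    k <- length(ps)
    q <- 2L^k
    if (strong && k > 0L) {
      coefs <- sample(c(-2, 2), k, replace = TRUE)
      b0 <- -sum(coefs) / 2 + stats::runif(1, -0.3, 0.3)
      p_high <- vapply(seq_len(q) - 1L, function(cfg) {
        bits <- as.integer(intToBits(cfg))[seq_len(k)]
        stats::plogis(b0 + sum(coefs * bits))
      }, numeric(1))
    } else if (strong) {
      p_high <- sample(c(0.2, 0.8), 1)
    } else {
      p_high <- stats::runif(q, 0.05, 0.95)
    }
    cpts[[v]] <- rbind(l = 1 - p_high, h = p_high)
  }
  manual_discrete_net(g, cpts)
}

# ancestral sample of every node of a discrete net as a data frame of
# factors (levels fixed so downstream fitting sees both states)
sample_net_data <- function(net, n, seed = 1) {
  d <- sample_conditional(net, names(net$nodes), n, seed = seed)
  d[] <- lapply(d, factor, levels = c("l", "h"))
  d
}

.cohort_cache <- new.env(parent = emptyenv())

# one imputed default-world cohort, shared across test files (imputation
# is the slowest prep stage; the cache keeps the suite fast)
cached_imputed_cohort <- function() {
  if (is.null(.cohort_cache$co)) {
    co <- small_cohort(seed = 7)
    .cohort_cache$co <- impute_cohort(co, seed = 3)
  }
  .cohort_cache$co
}

# a small cohort world shared by the slower prep/pipeline tests
small_cohort <- function(seed = 7, effect_scale = 1, n = 351,
                         t1_only = 94, t2_only = 121,
                         miss_stiff = 0.0477, miss_hrv = 0.1077) {
  model <- default_ground_truth(effect_scale)
  spec <- cohort_spec(n_recruited = n, n_t1_only = t1_only,
                      n_t2_only = t2_only,
                      missing_rate_stiffness = miss_stiff,
                      missing_rate_hrv = miss_hrv, seed = seed)
  inject_missingness(sample_cohort(model, spec), spec)
}
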
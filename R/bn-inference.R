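# Inference on fitted networks: exact enumeration (small discrete nets),
# likelihood-weighted conditional probability queries (discrete and
# hybrid), evidence-grid tables over a Markov blanket, and conditional
# ancestral sampling.

#' Exact conditional probability by joint enumeration
#'
#' Computes `P(event | evidence)` on a fully discrete network by summing
#' the joint probability over all configurations.  Intended as an oracle
#' for approximate inference; the joint state space must not exceed 1e6
#' configurations.
#'
#' @param net a discrete `bn_fit`.
#' @param event named list/vector of node = state assignments (conjunction).
#' @param evidence named list/vector of node = state assignments; may be
#'   empty.
#' @return probability in `[0, 1]`.
#' @examples
#' d <- data.frame(a = factor(rep(c("h", "l"), c(30, 70))))
#' net <- fit_parameters(dag("a"), d, smoothing = 0)
#' exact_query(net, c(a = "h"))  # 0.3
#' @export
exact_query <- function(net, event, evidence = NULL) {
  if (net$hybrid) stop("exact enumeration requires a discrete network")
  event <- as.list(event)
  evidence <- as.list(evidence)
  if (length(intersect(names(event), names(evidence))))
    stop("a node appears in both event and evidence")
  lev <- lapply(net$nodes, function(nd) nd$levels)
  if (prod(lengths(lev)) > 1e6) stop("joint state space too large")
  grid <- expand.grid(lev, stringsAsFactors = FALSE)
  joint <- rep(1, nrow(grid))
  for (v in names(net$nodes)) {
    nd <- net$nodes[[v]]
    p <- vapply(seq_len(nrow(grid)), function(i)
      local_prob(nd, grid[i, v], as.list(grid[i, , drop = FALSE])),
      numeric(1))
    joint <- joint * p
  }
  sel <- function(assign) {
    ok <- rep(TRUE, nrow(grid))
    for (v in names(assign)) ok <- ok & grid[[v]] == as.character(assign[[v]])
    ok
  }
  ev <- sel(evidence)
  denom <- sum(joint[ev])
  if (denom <= 0) stop("evidence has probability zero under the network")
  sum(joint[ev & sel(event)]) / denom
}

# draw n ancestral samples of all nodes; evidence nodes clamped.
# Returns list(samples = data.frame, logw = numeric log-weights).
lw_sample <- function(net, n, evidence = NULL) {
  ord <- topological_order(net$dag)
  evidence <- as.list(evidence)
  cols <- vector("list", length(ord))
  names(cols) <- ord
  logw <- rep(0, n)
  for (v in ord) {
    nd <- net$nodes[[v]]
    if (nd$type == "discrete") {
      dpar <- nd$parents
      cfg <- rep(1L, n)
      q <- 1L
      for (p in dpar) {
        code <- match(cols[[p]], nd$parent_levels[[p]])
        cfg <- cfg + (code - 1L) * q
        q <- q * length(nd$parent_levels[[p]])
      }
      if (v %in% names(evidence)) {
        val <- as.character(evidence[[v]])
        i <- match(val, nd$levels)
        if (is.na(i)) stop("unknown state ", val, " for ", v)
        cols[[v]] <- rep(val, n)
        logw <- logw + log(nd$cpt[i, cfg])
      } else {
        u <- stats::runif(n)
        cum <- apply(nd$cpt, 2L, cumsum)  # r x q
        # vectorised categorical draw: compare u against cumulative rows
        cm <- t(cum)[cfg, , drop = FALSE]  # n x r
        pick <- 1L + rowSums(cm < u)
        pick[pick > length(nd$levels)] <- length(nd$levels)
        cols[[v]] <- nd$levels[pick]
      }
    } else {
      cfg <- rep(1L, n)
      q <- 1L
      for (p in nd$dparents) {
        code <- match(cols[[p]], nd$parent_levels[[p]])
        cfg <- cfg + (code - 1L) * q
        q <- q * length(nd$parent_levels[[p]])
      }
      mu <- nd$coef[cfg, 1L]
      for (p in nd$cparents) mu <- mu + nd$coef[cfg, p] * cols[[p]]
      s <- nd$sd[cfg]
      if (v %in% names(evidence)) {
        val <- as.numeric(evidence[[v]])
        cols[[v]] <- rep(val, n)
        logw <- logw + stats::dnorm(val, mu, s, log = TRUE)
      } else {
        cols[[v]] <- stats::rnorm(n, mu, s)
      }
    }
  }
  list(samples = as.data.frame(cols, stringsAsFactors = FALSE), logw = logw)
}

#' Conditional probability query by likelihood weighting
#'
#' Importance sampling in which evidence nodes are clamped to their given
#' values and every sample is weighted by the product of the clamped
#' nodes' conditional probabilities (Gaussian densities for continuous
#' evidence).  The estimate is the weighted fraction of samples matching
#' the event; a Monte-Carlo standard error and effective sample size are
#' reported alongside.
#'
#' @param net a `bn_fit`.
#' @param event named list/vector of node = state (discrete) assignments.
#' @param evidence named list/vector of assignments; discrete states or
#'   continuous values.  May be empty.
#' @param n number of weighted samples (default 1e5).
#' @param seed integer seed.
#' @return list of class `bn_query` with `estimate`, `se`, `ess`, `n`.
#' @export
cpquery_lw <- function(net, event, evidence = NULL, n = 1e5, seed = 1L) {
  stopifnot(n >= 1)
  event <- as.list(event)
  evidence <- as.list(evidence)
  unknown <- setdiff(c(names(event), names(evidence)), names(net$nodes))
  if (length(unknown)) stop("unknown nodes: ", paste(unknown, collapse = ", "))
  if (length(intersect(names(event), names(evidence))))
    stop("a node appears in both event and evidence")
  set.seed(seed)
  draw <- lw_sample(net, as.integer(n), evidence)
  w <- exp(draw$logw - max(draw$logw))
  if (all(w == 0) || !any(is.finite(w)))
    stop("all likelihood weights are zero: evidence impossible under net")
  ind <- rep(TRUE, n)
  for (v in names(event))
    ind <- ind & draw$samples[[v]] == as.character(event[[v]])
  sw <- sum(w)
  est <- sum(w * ind) / sw
  # variance of the ratio estimator
  se <- sqrt(sum((w / sw)^2 * (ind - est)^2))
  ess <- sw^2 / sum(w^2)
  structure(list(estimate = est, se = se, ess = ess, n = as.integer(n)),
            class = "bn_query")
}

#' @export
print.bn_query <- function(x, ...) {
  cat(sprintf("P = %.4f (MC se %.4f, ESS %.0f of %d samples)\n",
              x$estimate, x$se, x$ess, x$n))
  invisible(x)
}

#' Conditional probability table over a Markov-blanket evidence grid
#'
#' Evaluates `P(target = state | blanket assignment)` for every combination
#' in the cross-product of the given variables' levels: both states for
#' discrete variables and, for continuous (standardised) variables, one
#' standard deviation below the mean change, the mean change, and one
#' standard deviation above (values -1, 0, +1).  Rows are sorted by
#' decreasing probability, reproducing the layout of blanket query tables.
#'
#' @param net a `bn_fit`.
#' @param target named length-1 vector, e.g. `c(injured_1 = "injured")`.
#' @param vars character vector of evidence variables (default: the Markov
#'   blanket of the target node).
#' @param n samples per query.
#' @param seed integer seed; each grid row uses a derived child seed.
#' @param continuous_levels values used for continuous variables.
#' @return data frame: `probability` column first, then one column per
#'   evidence variable.
#' @export
blanket_query_table <- function(net, target, vars = NULL, n = 1e4,
                                seed = 1L,
                                continuous_levels = c(`-1 SD` = -1,
                                                      Mean = 0,
                                                      `+1 SD` = 1)) {
  tnode <- names(target)[1L]
  tstate <- as.character(target[[1L]])
  vars <- vars %||% markov_blanket(net$dag, tnode)
  levs <- lapply(vars, function(v) {
    nd <- net$nodes[[v]]
    if (nd$type == "discrete") stats::setNames(nd$levels, nd$levels)
    else continuous_levels
  })
  names(levs) <- vars
  if (length(vars) == 0L) {
    q <- cpquery_lw(net, stats::setNames(list(tstate), tnode), NULL,
                    n = n, seed = seed)
    return(data.frame(probability = q$estimate))
  }
  grid <- expand.grid(lapply(levs, names), stringsAsFactors = FALSE)
  prob <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ev <- lapply(vars, function(v) {
      nd <- net$nodes[[v]]
      if (nd$type == "discrete") grid[i, v] else levs[[v]][[grid[i, v]]]
    })
    names(ev) <- vars
    q <- cpquery_lw(net, stats::setNames(list(tstate), tnode), ev,
                    n = n, seed = derive_seed(seed, i))
    prob[i] <- q$estimate
  }
  out <- cbind(data.frame(probability = prob), grid)
  out <- out[order(-out$probability), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample nodes from their joint conditional distribution
#'
#' Ancestral sampling of the network restricted to the ancestral closure
#' of the requested nodes; returns the requested columns only.
#'
#' @param net a `bn_fit`.
#' @param nodes character vector of node names to sample.
#' @param n number of joint draws.
#' @param seed integer seed.
#' @return data frame of `n` rows.
#' @export
sample_conditional <- function(net, nodes, n, seed = 1L) {
  unknown <- setdiff(nodes, names(net$nodes))
  if (length(unknown)) stop("unknown nodes: ", paste(unknown, collapse = ", "))
  set.seed(seed)
  draw <- lw_sample(net, as.integer(n), NULL)
  draw$samples[nodes]
}

# deterministic child-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %%
               2147483647)
}
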
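# Parameter fitting: conditional probability tables for discrete nodes
# (with optional Laplace smoothing) and linear-Gaussian local models for
# continuous nodes, switched by the configuration of discrete parents.

#' Fit network parameters for a given structure
#'
#' Discrete nodes receive a conditional probability table with entries
#' `(count + smoothing) / (row total + smoothing * states)` per parent
#' configuration.  Continuous nodes receive, per discrete-parent
#' configuration, a least-squares linear-Gaussian model in their continuous
#' parents (intercept, slopes, residual sd).  The result is a
#' `bn_fit` object: a discrete network if every node is discrete, otherwise
#' a conditional-linear-Gaussian hybrid.
#'
#' @param g a `bn_dag`.
#' @param data complete data frame covering the nodes.
#' @param smoothing pseudo-count added to every CPT cell (default 1;
#'   0 gives raw maximum likelihood, in which case an unobserved parent
#'   configuration is an error).
#' @return an object of class `bn_fit` with elements `dag`, `nodes`
#'   (per-node local distributions) and `n`.
#' @examples
#' d <- data.frame(a = factor(c("l", "l", "h", "h")),
#'                 b = factor(c("l", "h", "h", "h")))
#' fit <- fit_parameters(dag(c("a", "b"), rbind(c("a", "b"))), d)
#' fit$nodes$b$cpt
#' @export
fit_parameters <- function(g, data, smoothing = 1) {
  stopifnot(smoothing >= 0)
  data <- data[g$nodes]
  if (anyNA(data)) stop("data must be complete")
  type <- vapply(data, function(x)
    if (is.numeric(x)) "continuous" else "discrete", character(1))
  data[type == "discrete"] <- lapply(data[type == "discrete"], function(x)
    if (is.factor(x)) x else factor(x))
  nodes <- lapply(g$nodes, function(v) {
    ps <- parents(g, v)
    dpar <- ps[type[ps] == "discrete"]
    cpar <- ps[type[ps] == "continuous"]
    if (type[[v]] == "discrete") {
      if (length(cpar)) stop("discrete node ", v, " has continuous parents")
      fit_cpt(data, v, dpar, smoothing)
    } else {
      fit_clg_node(data, v, dpar, cpar)
    }
  })
  names(nodes) <- g$nodes
  hybrid <- any(type == "continuous")
  structure(list(dag = g, nodes = nodes, n = nrow(data), hybrid = hybrid),
            class = "bn_fit")
}

# configuration index (1..q) of each row for a set of discrete parents
config_index <- function(data, dpar) {
  n <- nrow(data)
  cfg <- rep(1L, n)
  q <- 1L
  for (p in dpar) {
    code <- as.integer(data[[p]])
    cfg <- cfg + (code - 1L) * q
    q <- q * nlevels(data[[p]])
  }
  list(cfg = cfg, q = as.integer(q))
}

fit_cpt <- function(data, v, dpar, smoothing) {
  lev <- levels(data[[v]])
  r <- length(lev)
  ci <- config_index(data, dpar)
  cell <- (ci$cfg - 1L) * r + as.integer(data[[v]])
  counts <- matrix(tabulate(cell, nbins = ci$q * r), nrow = r)
  if (smoothing == 0 && any(colSums(counts) == 0L))
    stop("unobserved parent configuration for node ", v,
         " with smoothing 0")
  prob <- sweep(counts + smoothing, 2L,
                colSums(counts) + smoothing * r, "/")
  rownames(prob) <- lev
  plev <- lapply(dpar, function(p) levels(data[[p]]))
  names(plev) <- dpar
  list(type = "discrete", levels = lev, parents = dpar,
       parent_levels = plev, cpt = prob)
}

fit_clg_node <- function(data, v, dpar, cpar) {
  y <- data[[v]]
  ci <- config_index(data, dpar)
  k <- length(cpar)
  X <- matrix(1, nrow(data), 1L)
  if (k) X <- cbind(X, as.matrix(data[cpar]))
  coef <- matrix(NA_real_, ci$q, k + 1L,
                 dimnames = list(NULL, c("(Intercept)", cpar)))
  sd <- rep(NA_real_, ci$q)
  grand <- c(mean(y), rep(0, k))
  for (j in seq_len(ci$q)) {
    rows <- which(ci$cfg == j)
    if (length(rows) > k + 1L) {
      fit <- stats::lm.fit(X[rows, , drop = FALSE], y[rows])
      coef[j, ] <- fit$coefficients
      coef[j, is.na(coef[j, ])] <- 0
      s <- sqrt(sum(fit$residuals^2) / length(rows))
    } else {
      # configuration unobserved or too sparse: fall back to the pooled fit
      coef[j, ] <- grand
      s <- stats::sd(y)
    }
    sd[j] <- max(s, 1e-8)
  }
  plev <- lapply(dpar, function(p) levels(data[[p]]))
  names(plev) <- dpar
  list(type = "continuous", parents = c(dpar, cpar), dparents = dpar,
       cparents = cpar, parent_levels = plev, coef = coef, sd = sd)
}

#' @export
print.bn_fit <- function(x, ...) {
  kind <- if (x$hybrid) "conditional-linear-Gaussian" else "discrete"
  cat("Fitted", kind, "Bayesian network:", length(x$nodes), "nodes,",
      nrow(x$dag$arcs), "arcs, n =", x$n, "\n")
  invisible(x)
}

# configuration index for one assignment (named list of states) given a
# node's discrete parents; states may be character or factor levels
assignment_config <- function(node, assignment) {
  dpar <- if (node$type == "discrete") node$parents else node$dparents
  cfg <- 1L
  q <- 1L
  for (p in dpar) {
    lev <- node$parent_levels[[p]]
    i <- match(as.character(assignment[[p]]), lev)
    if (is.na(i)) stop("unknown state for parent ", p)
    cfg <- cfg + (i - 1L) * q
    q <- q * length(lev)
  }
  cfg
}

# P(value | parents = assignment) for a discrete node, or Gaussian density
# for a continuous node
local_prob <- function(node, value, assignment) {
  cfg <- assignment_config(node, assignment)
  if (node$type == "discrete") {
    i <- match(as.character(value), node$levels)
    if (is.na(i)) stop("unknown state ", value)
    node$cpt[i, cfg]
  } else {
    mu <- node$coef[cfg, 1L]
    if (length(node$cparents))
      mu <- mu + sum(node$coef[cfg, -1L] *
                       vapply(node$cparents,
                              function(p) as.numeric(assignment[[p]]),
                              numeric(1)))
    stats::dnorm(as.numeric(value), mu, node$sd[cfg])
  }
}
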
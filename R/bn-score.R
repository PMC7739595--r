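# BIC scoring for discrete and conditional-linear-Gaussian (CLG) networks.
#
# The network score is decomposable: it is the sum over nodes of a family
# score, log L(node | parents) - (d/2) log N, in natural logs, "higher is
# better".  Family scores are memoised per (child, parent set) so local
# search revisits configurations at hash-lookup cost.

# Preprocess a data frame into a scoring context.  Discrete columns
# (factor/character/logical) are integer-coded; numeric columns kept as-is.
score_context <- function(data) {
  stopifnot(is.data.frame(data), nrow(data) > 0L)
  if (anyNA(data)) stop("scoring data must not contain missing values")
  nodes <- names(data)
  type <- vapply(data, function(x)
    if (is.numeric(x)) "continuous" else "discrete", character(1))
  disc <- lapply(data, function(x) {
    if (is.numeric(x)) return(NULL)
    f <- if (is.factor(x)) x else factor(x)
    list(code = as.integer(f), levels = levels(f))
  })
  ctx <- list(nodes = nodes, type = type, n = nrow(data),
              disc = disc, num = data, cache = new.env(parent = emptyenv()))
  ctx
}

# Family score for `child` given `parents` within a score context.
family_score <- function(ctx, child, parents) {
  key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (ctx$type[[child]] == "discrete") {
    if (any(ctx$type[parents] == "continuous")) {
      -Inf  # CLG: discrete node may not have continuous parents
    } else {
      family_score_discrete(ctx, child, parents)
    }
  } else {
    family_score_gaussian(ctx, child, parents)
  }
  ctx$cache[[key]] <- val
  val
}

family_score_discrete <- function(ctx, child, parents) {
  n <- ctx$n
  cc <- ctx$disc[[child]]
  r <- length(cc$levels)
  if (length(parents) == 0L) {
    counts <- tabulate(cc$code, nbins = r)
    nz <- counts > 0L
    ll <- sum(counts[nz] * log(counts[nz] / n))
    return(ll - (r - 1) / 2 * log(n))
  }
  q <- 1L
  cfg <- rep(1L, n)
  for (p in parents) {
    pc <- ctx$disc[[p]]
    cfg <- cfg + (pc$code - 1L) * q
    q <- q * length(pc$levels)
  }
  cell <- (cfg - 1L) * r + cc$code
  counts <- tabulate(cell, nbins = as.integer(q) * r)
  cm <- matrix(counts, nrow = r)
  nj <- colSums(cm)
  nz <- cm > 0L
  ll <- sum(cm[nz] * log(cm[nz] / rep(nj, each = r)[nz]))
  d <- (r - 1) * q
  ll - d / 2 * log(n)
}

family_score_gaussian <- function(ctx, child, parents) {
  n <- ctx$n
  y <- ctx$num[[child]]
  dpar <- parents[ctx$type[parents] == "discrete"]
  cpar <- parents[ctx$type[parents] == "continuous"]
  q <- 1L
  cfg <- rep(1L, n)
  for (p in dpar) {
    pc <- ctx$disc[[p]]
    cfg <- cfg + (pc$code - 1L) * q
    q <- q * length(pc$levels)
  }
  k <- length(cpar)
  X <- matrix(1, n, 1L)
  if (k) X <- cbind(X, as.matrix(ctx$num[cpar]))
  ll <- 0
  for (j in seq_len(q)) {
    rows <- if (q == 1L) seq_len(n) else which(cfg == j)
    nj <- length(rows)
    if (nj == 0L) next
    if (nj <= k + 1L) {
      # too few rows to estimate: treat the residual as near-degenerate,
      # heavy implicit penalty through the parameter count below
      rss <- 0
    } else {
      fit <- stats::lm.fit(X[rows, , drop = FALSE], y[rows])
      rss <- sum(fit$residuals^2)
    }
    s2 <- max(rss / nj, 1e-10)
    ll <- ll + (-nj / 2 * (log(2 * pi * s2) + 1))
  }
  d <- q * (k + 2)  # per configuration: intercept + slopes + residual sd
  ll - d / 2 * log(n)
}

#' Network BIC score
#'
#' Decomposable penalised log-likelihood score of a DAG against data:
#' the sum over nodes of `logLik(node | parents) - (d/2) log N`, natural
#' logs, higher is better.  Discrete nodes use multinomial maximum
#' likelihood with `d = (states - 1) * prod(parent states)`; continuous
#' nodes use a linear-Gaussian fit per discrete-parent configuration with
#' `d = configs * (continuous parents + 2)`.
#'
#' @param g a `bn_dag` whose nodes are columns of `data`.
#' @param data a complete data frame (factors/characters discrete, numerics
#'   continuous).
#' @return a single numeric score.
#' @examples
#' d <- data.frame(a = factor(rep(c("x", "y"), 50)),
#'                 b = factor(rep(c("x", "y"), each = 50)))
#' bic_score(dag(c("a", "b")), d)
#' @export
bic_score <- function(g, data) {
  missing_cols <- setdiff(g$nodes, names(data))
  if (length(missing_cols)) stop("data lacks columns: ",
                                 paste(missing_cols, collapse = ", "))
  ctx <- score_context(data[g$nodes])
  sum(vapply(g$nodes, function(v) family_score(ctx, v, parents(g, v)),
             numeric(1)))
}

#' Parameter-space size of a discrete network
#'
#' Counts the possible parameter combinations of a fully discretised
#' network under the convention that a network of `n_vars` variables, each
#' with `n_levels` levels, has `n_vars ^ n_levels` combinations (so 10
#' two-level variables give 100 and 10 three-level variables give 1,000).
#'
#' @param n_vars number of variables.
#' @param n_levels number of levels per variable.
#' @return numeric count.
#' @export
parameter_space_size <- function(n_vars, n_levels) {
  stopifnot(n_vars >= 1, n_levels >= 1)
  n_vars ^ n_levels
}
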
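#' Bayesian linear regression with weakly regularising normal priors
#'
#' Fits `y ~ x1 + x2 + x1:x2` (or an arbitrary design) with independent
#' normal(0, `prior_sd`^2) priors on all coefficients and a Jeffreys-style
#' inverse-gamma prior on the residual variance, via a Gibbs sampler on the
#' conjugate conditionals.  Posterior summaries are the mean, standard
#' deviation and central 95% credible interval of the retained draws.
#'
#' @param y numeric response.
#' @param predictors data frame or matrix of numeric predictors (main
#'   effects).
#' @param interaction add the product interaction of the first two
#'   predictors (default TRUE, matching a two-predictor moderation model).
#' @param prior_sd prior standard deviation for every coefficient
#'   (default 5).
#' @param draws posterior draws retained (default 4000).
#' @param burnin discarded warm-up iterations.
#' @param seed integer seed.
#' @return data frame of class `bn_posterior`: one row per coefficient with
#'   `term`, `estimate` (posterior mean), `error` (posterior sd), `lower`,
#'   `upper` (95% credible interval).
#' @examples
#' set.seed(1)
#' x1 <- rnorm(200); x2 <- rnorm(200)
#' y <- 0.4 * x1 - 0.2 * x2 + rnorm(200, sd = 0.5)
#' bayes_linreg(y, data.frame(x1 = x1, x2 = x2), seed = 1)
#' @export
bayes_linreg <- function(y, predictors, interaction = TRUE, prior_sd = 5,
                         draws = 4000, burnin = 500, seed = 1L) {
  if (prior_sd <= 0) stop("prior_sd must be positive")
  X <- as.matrix(predictors)
  if (!is.numeric(X)) stop("predictors must be numeric")
  terms <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  colnames(X) <- terms
  if (interaction && ncol(X) >= 2L) {
    X <- cbind(X, X[, 1L] * X[, 2L])
    colnames(X)[ncol(X)] <- paste0(terms[1L], ":", terms[2L])
  }
  X <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 10L) stop("need at least 10 observations")
  if (qr(X)$rank < p) stop("predictors are rank deficient")
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  prior_prec <- diag(1 / prior_sd^2, p)
  set.seed(seed)
  s2 <- stats::var(y)
  keep <- matrix(NA_real_, draws, p, dimnames = list(NULL, colnames(X)))
  total <- draws + burnin
  for (it in seq_len(total)) {
    post_prec <- XtX / s2 + prior_prec
    ch <- chol(post_prec)
    mu <- backsolve(ch, forwardsolve(t(ch), Xty / s2))
    beta <- mu + backsolve(ch, stats::rnorm(p))
    resid <- y - X %*% beta
    s2 <- 1 / stats::rgamma(1, shape = n / 2, rate = sum(resid^2) / 2)
    if (it > burnin) keep[it - burnin, ] <- beta
  }
  ci <- apply(keep, 2L, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(term = colnames(X),
                    estimate = colMeans(keep),
                    error = apply(keep, 2L, stats::sd),
                    lower = ci[1L, ], upper = ci[2L, ],
                    row.names = NULL)
  attr(out, "draws") <- draws
  attr(out, "prior_sd") <- prior_sd
  class(out) <- c("bn_posterior", "data.frame")
  out
}
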
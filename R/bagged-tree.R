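# A compact CART-style regression tree plus bootstrap aggregation, used
# for imputation of missing continuous measurements.  Greedy binary
# splits by residual sum of squares, found in O(n log n) per node and
# predictor via cumulative sums over the sorted predictor; categorical
# predictors are ordered by mean response (the classical CART device
# that makes the binary-split scan exact for squared error).

# Xlist: named list of predictor vectors (numeric, or factor/character);
# idx: integer rows in play at this node.
grow_tree <- function(Xlist, y, idx = seq_along(y), min_n = 5L,
                      max_depth = 12L, depth = 0L) {
  n <- length(idx)
  yy <- y[idx]
  node <- list(pred = mean(yy))
  if (n < 2L * min_n || depth >= max_depth) return(node)
  tot <- sum(yy)
  tot2 <- sum(yy^2)
  sse0 <- tot2 - tot^2 / n
  if (sse0 < 1e-12) return(node)
  best_sse <- sse0 - 1e-9
  best <- NULL
  for (v in names(Xlist)) {
    x <- Xlist[[v]][idx]
    if (is.numeric(x)) {
      ord <- order(x)
      xs <- x[ord]
      ys <- yy[ord]
      cs <- cumsum(ys)
      cs2 <- cumsum(ys^2)
      i <- seq_len(n - 1L)
      valid <- i >= min_n & (n - i) >= min_n & xs[i] < xs[i + 1L]
      if (!any(valid)) next
      i <- i[valid]
      sse <- (cs2[i] - cs[i]^2 / i) +
        ((tot2 - cs2[i]) - (tot - cs[i])^2 / (n - i))
      k <- which.min(sse)
      if (sse[k] < best_sse) {
        best_sse <- sse[k]
        best <- list(var = v, type = "num",
                     cut = (xs[i[k]] + xs[i[k] + 1L]) / 2)
      }
    } else {
      f <- as.character(x)
      gs <- rowsum(cbind(ys = yy, ys2 = yy^2, one = 1), f)
      if (nrow(gs) < 2L) next
      ord <- order(gs[, "ys"] / gs[, "one"])
      gs <- gs[ord, , drop = FALSE]
      cs <- cumsum(gs[, "ys"])
      cs2 <- cumsum(gs[, "ys2"])
      cn <- cumsum(gs[, "one"])
      i <- seq_len(nrow(gs) - 1L)
      valid <- cn[i] >= min_n & (n - cn[i]) >= min_n
      if (!any(valid)) next
      i <- i[valid]
      sse <- (cs2[i] - cs[i]^2 / cn[i]) +
        ((tot2 - cs2[i]) - (tot - cs[i])^2 / (n - cn[i]))
      k <- which.min(sse)
      if (sse[k] < best_sse) {
        best_sse <- sse[k]
        best <- list(var = v, type = "cat",
                     levels = rownames(gs)[seq_len(i[k])])
      }
    }
  }
  if (is.null(best)) return(node)
  xv <- Xlist[[best$var]][idx]
  left <- if (best$type == "num") xv <= best$cut else
    as.character(xv) %in% best$levels
  node$split <- best
  node$left <- grow_tree(Xlist, y, idx[left], min_n, max_depth, depth + 1L)
  node$right <- grow_tree(Xlist, y, idx[!left], min_n, max_depth,
                          depth + 1L)
  node
}

predict_tree <- function(node, Xlist, idx) {
  out <- numeric(length(idx))
  rec <- function(nd, pos) {
    if (is.null(nd$split)) {
      out[pos] <<- nd$pred
      return(invisible())
    }
    s <- nd$split
    xv <- Xlist[[s$var]][idx[pos]]
    left <- if (s$type == "num") xv <= s$cut else
      as.character(xv) %in% s$levels
    if (any(left)) rec(nd$left, pos[left])
    if (any(!left)) rec(nd$right, pos[!left])
  }
  rec(node, seq_along(idx))
  out
}

bagged_trees <- function(Xlist, y, idx, n_trees = 25L, min_n = 5L) {
  n <- length(idx)
  lapply(seq_len(n_trees), function(b)
    grow_tree(Xlist, y, idx[sample.int(n, n, replace = TRUE)],
              min_n = min_n))
}

predict_bagged <- function(trees, Xlist, idx) {
  preds <- vapply(trees, function(tr) predict_tree(tr, Xlist, idx),
                  numeric(length(idx)))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' Impute missing continuous values with bagged regression trees
#'
#' For each target column containing missing values, a bagged ensemble of
#' regression trees is trained on the rows where the column is observed
#' (using every other column as a predictor) and used to predict the
#' missing entries.  Because several columns can be missing at once, all
#' gaps are first seeded with column medians and the targets are refined
#' over `passes` sweeps.  Non-missing entries are never altered, and the
#' result is deterministic given `seed`.
#'
#' @param table data frame; missingness must be confined to numeric
#'   columns.
#' @param n_trees trees per ensemble (default 25).
#' @param seed integer seed.
#' @param targets columns to impute; defaults to all numeric columns with
#'   any `NA`.
#' @param passes refinement sweeps (default 2).
#' @return the completed data frame.
#' @export
impute_bagged_trees <- function(table, n_trees = 25L, seed = 1L,
                                targets = NULL, passes = 2L) {
  stopifnot(is.data.frame(table))
  targets <- targets %||% names(table)[vapply(table, function(x)
    is.numeric(x) && anyNA(x), logical(1))]
  if (!length(targets)) return(table)
  non_num <- targets[!vapply(table[targets], is.numeric, logical(1))]
  if (length(non_num)) stop("non-numeric imputation targets: ",
                            paste(non_num, collapse = ", "))
  other_na <- setdiff(names(table)[vapply(table, anyNA, logical(1))],
                      targets)
  if (length(other_na)) stop("missing values outside the target columns: ",
                             paste(other_na, collapse = ", "))
  all_missing <- targets[vapply(table[targets], function(x) all(is.na(x)),
                                logical(1))]
  if (length(all_missing)) stop("column entirely missing: ",
                                paste(all_missing, collapse = ", "))
  miss <- lapply(table[targets], is.na)
  names(miss) <- targets
  work <- as.list(table)
  for (v in targets)
    work[[v]][miss[[v]]] <- stats::median(work[[v]], na.rm = TRUE)
  set.seed(derive_seed(seed, 11L))
  for (pass in seq_len(passes)) {
    for (v in targets) {
      if (!any(miss[[v]])) next
      Xlist <- work[setdiff(names(work), v)]
      trees <- bagged_trees(Xlist, work[[v]], which(!miss[[v]]),
                            n_trees = n_trees)
      work[[v]][miss[[v]]] <- predict_bagged(trees, Xlist,
                                             which(miss[[v]]))
    }
  }
  for (v in targets) table[[v]][miss[[v]]] <- work[[v]][miss[[v]]]
  table
}
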
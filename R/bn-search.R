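# Score-based structure search: greedy hill climbing with a Tabu memory of
# recently applied moves.  Local moves are single-arc add / delete /
# reverse; the blacklist/whitelist is honoured throughout and the best
# structure ever visited is returned.

#' Search parameters
#'
#' Bundles the tuning constants for structure search and bootstrap model
#' averaging.  Defaults: Tabu memory of length 10, 100 iterations at most,
#' stop after 15 non-improving iterations, Laplace smoothing pseudo-count 1
#' when fitting parameters, 1,000 bootstrap replicates, arc inclusion
#' threshold 0.3 and significance threshold 0.5.
#'
#' @param tabu_length number of most recent moves kept tabu.
#' @param max_iter hard iteration cap.
#' @param max_noimprove stop after this many iterations without improving
#'   the best score.
#' @param smoothing pseudo-count used by [fit_parameters()].
#' @param bootstrap_reps bootstrap replicate count R for
#'   [bootstrap_strength()].
#' @param inclusion_threshold minimum arc strength for inclusion in the
#'   averaged network.
#' @param significance_threshold strength above which an arc is labelled
#'   significant.
#' @param seed integer seed for stochastic stages.
#' @return a list of class `bn_search_params`.
#' @export
search_params <- function(tabu_length = 10L, max_iter = 100L,
                          max_noimprove = 15L, smoothing = 1,
                          bootstrap_reps = 1000L,
                          inclusion_threshold = 0.3,
                          significance_threshold = 0.5,
                          seed = 1L) {
  stopifnot(bootstrap_reps >= 1,
            inclusion_threshold > 0, inclusion_threshold < 1,
            significance_threshold > 0, significance_threshold < 1,
            inclusion_threshold <= significance_threshold)
  structure(list(tabu_length = as.integer(tabu_length),
                 max_iter = as.integer(max_iter),
                 max_noimprove = as.integer(max_noimprove),
                 smoothing = smoothing,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 inclusion_threshold = inclusion_threshold,
                 significance_threshold = significance_threshold,
                 seed = as.integer(seed)),
            class = "bn_search_params")
}

# Internal search state helpers -------------------------------------------

# is `target` among the ancestors of `start`?  plist maps each node
# (integer index) to its integer parent indices; we walk upwards.
reachable_up <- function(plist, start, target) {
  seen <- rep(FALSE, length(plist))
  frontier <- start
  while (length(frontier)) {
    seen[frontier] <- TRUE
    nxt <- unique(unlist(plist[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    if (target %in% nxt) return(TRUE)
    frontier <- nxt
  }
  FALSE
}

plist_to_arcs <- function(plist) {
  out <- lapply(names(plist), function(v) {
    ps <- plist[[v]]
    if (length(ps)) cbind(from = ps, to = rep(v, length(ps))) else NULL
  })
  do.call(rbind, c(out, list(matrix(character(), 0, 2,
                                    dimnames = list(NULL, c("from", "to"))))))
}

#' Learn a DAG by Tabu search with BIC scoring
#'
#' Greedy local search over single-arc moves (add, delete, reverse) with a
#' short-term memory that forbids undoing recent moves, allowing the search
#' to escape local optima.  The whitelist is seeded into the starting graph
#' and never touched; blacklisted arcs are never added.  The best-scoring
#' structure encountered anywhere during the search is returned.
#'
#' @param data complete data frame; factor/character columns are discrete,
#'   numeric columns continuous (scored as conditional linear Gaussians).
#' @param constraints a [constraints()] object (optional).
#' @param params a [search_params()] object.
#' @param start optional starting `bn_dag`; defaults to the whitelist-only
#'   graph.
#' @return the best `bn_dag` found, with the score in attribute `"score"`.
#' @examples
#' set.seed(1)
#' a <- factor(sample(c("l", "h"), 200, TRUE))
#' b <- factor(ifelse(a == "h", sample(c("l", "h"), 200, TRUE, c(.1, .9)),
#'                    sample(c("l", "h"), 200, TRUE, c(.9, .1))))
#' g <- tabu_search(data.frame(a = a, b = b))
#' g$arcs
#' @export
tabu_search <- function(data, constraints = NULL, params = search_params(),
                        start = NULL) {
  ctx <- score_context(data)
  nodes <- ctx$nodes
  cons <- constraints %||% new_empty_constraints()
  bl <- cons$blacklist
  wl <- cons$whitelist
  if (nrow(wl) && !all(c(wl) %in% nodes))
    stop("whitelist references unknown nodes")
  blkey <- if (nrow(bl)) paste(bl[, 1L], bl[, 2L], sep = "\r") else character()
  wlkey <- if (nrow(wl)) paste(wl[, 1L], wl[, 2L], sep = "\r") else character()
  if (any(wlkey %in% blkey)) stop("constraints unsatisfiable")

  plist <- stats::setNames(vector("list", length(nodes)), nodes)
  if (!is.null(start)) {
    for (i in seq_len(nrow(start$arcs)))
      plist[[start$arcs[i, 2L]]] <- c(plist[[start$arcs[i, 2L]]],
                                      start$arcs[i, 1L])
  }
  for (i in seq_len(nrow(wl))) {
    if (!wl[i, 1L] %in% (plist[[wl[i, 2L]]] %||% character()))
      plist[[wl[i, 2L]]] <- c(plist[[wl[i, 2L]]], wl[i, 1L])
  }
  if (!acyclic_arcs(nodes, plist_to_arcs(plist)))
    stop("whitelist (plus start graph) forms a cycle")

  nn <- length(nodes)
  # integer-indexed state: ip[[t]] = integer parent indices of node t
  ip <- lapply(plist, function(p) match(p, nodes))
  bl_m <- matrix(FALSE, nn, nn)
  if (nrow(bl)) {
    ok <- bl[, 1L] %in% nodes & bl[, 2L] %in% nodes
    bl_m[cbind(match(bl[ok, 1L], nodes), match(bl[ok, 2L], nodes))] <- TRUE
  }
  wl_m <- matrix(FALSE, nn, nn)
  if (nrow(wl))
    wl_m[cbind(match(wl[, 1L], nodes), match(wl[, 2L], nodes))] <- TRUE

  fscore <- function(child, parent_idx)
    family_score_raw(ctx, child, parent_idx)
  fam <- vapply(seq_len(nn), function(v) fscore(v, ip[[v]]), numeric(1))
  cur_score <- sum(fam)
  best_ip <- ip
  best_score <- cur_score
  # lazily-filled candidate family scores, invalidated per child column:
  # sc_plus[f, t] = score of family t with parent f added;
  # sc_minus[f, t] = score of family t with parent f removed
  sc_plus <- matrix(NA_real_, nn, nn)
  sc_minus <- matrix(NA_real_, nn, nn)
  tabu <- integer(0)  # encoded moves whose inverse is forbidden
  enc <- function(op, f, t) (op - 1L) * nn * nn + (f - 1L) * nn + t
  noimprove <- 0L

  for (iter in seq_len(params$max_iter)) {
    best_move <- NULL
    best_delta <- -Inf
    # ancestor closure: anc[x, y] TRUE iff y ~> x in the current graph
    anc <- matrix(FALSE, nn, nn)
    for (v in seq_len(nn)) anc[v, ip[[v]]] <- TRUE
    for (k in seq_len(nn)) {
      via <- anc[, k]
      if (any(via)) anc[via, ] <- anc[via, , drop = FALSE] |
          rep(anc[k, ], each = sum(via))
    }
    for (t in seq_len(nn)) {
      pt <- ip[[t]]
      for (f in seq_len(nn)) {
        if (f == t) next
        if (f %in% pt) {
          if (wl_m[f, t]) next
          # delete f -> t
          if (is.na(sc_minus[f, t]))
            sc_minus[f, t] <- fscore(t, pt[pt != f])
          delta <- sc_minus[f, t] - fam[t]
          if ((!(enc(2L, f, t) %in% tabu) ||
                 cur_score + delta > best_score) && delta > best_delta) {
            best_move <- list(op = 2L, f = f, t = t,
                              new_t = sc_minus[f, t])
            best_delta <- delta
          }
          # reverse f -> t (becomes t -> f); legal unless t -> f is
          # blacklisted or a path f ~> t survives the deletion
          if (!bl_m[t, f]) {
            tmp <- ip
            tmp[[t]] <- pt[pt != f]
            if (!reachable_up(tmp, t, f)) {
              if (is.na(sc_minus[f, t]))
                sc_minus[f, t] <- fscore(t, pt[pt != f])
              if (is.na(sc_plus[t, f]))
                sc_plus[t, f] <- fscore(f, c(ip[[f]], t))
              delta <- (sc_minus[f, t] - fam[t]) +
                (sc_plus[t, f] - fam[f])
              if ((!(enc(3L, f, t) %in% tabu) ||
                     cur_score + delta > best_score) &&
                    delta > best_delta) {
                best_move <- list(op = 3L, f = f, t = t,
                                  new_t = sc_minus[f, t],
                                  new_f = sc_plus[t, f])
                best_delta <- delta
              }
            }
          }
        } else {
          # add f -> t
          if (bl_m[f, t] || t %in% ip[[f]] || anc[f, t]) next
          if (is.na(sc_plus[f, t])) sc_plus[f, t] <- fscore(t, c(pt, f))
          delta <- sc_plus[f, t] - fam[t]
          if ((!(enc(1L, f, t) %in% tabu) ||
                 cur_score + delta > best_score) && delta > best_delta) {
            best_move <- list(op = 1L, f = f, t = t,
                              new_t = sc_plus[f, t])
            best_delta <- delta
          }
        }
      }
    }
    if (is.null(best_move)) break
    m <- best_move
    inverse <- switch(m$op, enc(2L, m$f, m$t), enc(1L, m$f, m$t),
                      enc(3L, m$t, m$f))
    tabu <- c(tabu, inverse)
    if (length(tabu) > params$tabu_length)
      tabu <- tabu[seq.int(length(tabu) - params$tabu_length + 1L,
                           length(tabu))]
    if (m$op == 1L) {
      ip[[m$t]] <- c(ip[[m$t]], m$f)
      fam[m$t] <- m$new_t
      sc_plus[, m$t] <- NA_real_
      sc_minus[, m$t] <- NA_real_
    } else if (m$op == 2L) {
      ip[[m$t]] <- ip[[m$t]][ip[[m$t]] != m$f]
      fam[m$t] <- m$new_t
      sc_plus[, m$t] <- NA_real_
      sc_minus[, m$t] <- NA_real_
    } else {
      ip[[m$t]] <- ip[[m$t]][ip[[m$t]] != m$f]
      ip[[m$f]] <- c(ip[[m$f]], m$t)
      fam[m$t] <- m$new_t
      fam[m$f] <- m$new_f
      sc_plus[, c(m$t, m$f)] <- NA_real_
      sc_minus[, c(m$t, m$f)] <- NA_real_
    }
    cur_score <- sum(fam)
    if (cur_score > best_score + 1e-12) {
      best_score <- cur_score
      best_ip <- ip
      noimprove <- 0L
    } else {
      noimprove <- noimprove + 1L
      if (noimprove >= params$max_noimprove) break
    }
  }
  arcs <- do.call(rbind, lapply(seq_len(nn), function(t) {
    ps <- best_ip[[t]]
    if (length(ps)) cbind(from = nodes[ps], to = rep(nodes[t], length(ps)))
    else NULL
  }))
  g <- dag(nodes, arcs)
  attr(g, "score") <- best_score
  g
}

# family score addressed by integer child / parent indices
family_score_raw <- function(ctx, child, parent_idx) {
  cn <- ctx$nodes[child]
  pn <- ctx$nodes[parent_idx]
  if (ctx$type[child] == "discrete") {
    if (any(ctx$type[parent_idx] == "continuous")) return(-Inf)
    family_score_discrete(ctx, cn, pn)
  } else {
    family_score_gaussian(ctx, cn, pn)
  }
}

#' Plain greedy hill climbing (no Tabu memory)
#'
#' Same move set and constraints as [tabu_search()] but stops at the first
#' iteration with no strictly improving move.  Used as a baseline.
#'
#' @inheritParams tabu_search
#' @return a `bn_dag` with attribute `"score"`.
#' @export
hill_climb <- function(data, constraints = NULL, params = search_params()) {
  p <- params
  p$tabu_length <- 0L
  p$max_noimprove <- 1L
  tabu_search(data, constraints, p)
}

#' Exhaustive structure search (test oracle)
#'
#' Enumerates every DAG over at most 4 nodes (subject to constraints) and
#' returns the BIC-optimal one.  Exponential: intended only for validating
#' heuristic search on tiny problems.
#'
#' @inheritParams tabu_search
#' @return list with `dag` and `score`.
#' @export
exhaustive_search <- function(data, constraints = NULL) {
  nodes <- names(data)
  n <- length(nodes)
  if (n > 4L) stop("exhaustive search supports at most 4 nodes")
  cons <- constraints %||% new_empty_constraints()
  blkey <- paste(cons$blacklist[, 1L], cons$blacklist[, 2L], sep = "\r")
  wl <- cons$whitelist
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  ctx <- score_context(data)
  best <- NULL
  best_score <- -Inf
  # each unordered pair is absent / forward / backward: 3^m structures
  states <- rep(0L, m)
  repeat {
    arcs <- NULL
    for (k in seq_len(m)) {
      if (states[k] == 1L)
        arcs <- rbind(arcs, c(nodes[pairs[k, 1L]], nodes[pairs[k, 2L]]))
      if (states[k] == 2L)
        arcs <- rbind(arcs, c(nodes[pairs[k, 2L]], nodes[pairs[k, 1L]]))
    }
    ok <- acyclic_arcs(nodes, as_arc_matrix(arcs))
    if (ok && length(blkey) && NROW(arcs)) {
      ok <- !any(paste(arcs[, 1L], arcs[, 2L], sep = "\r") %in% blkey)
    }
    if (ok && nrow(wl)) {
      ok <- all(apply(wl, 1L, function(a)
        NROW(arcs) && any(arcs[, 1L] == a[1L] & arcs[, 2L] == a[2L])))
    }
    if (ok) {
      g <- dag(nodes, arcs)
      s <- sum(vapply(nodes, function(v) family_score(ctx, v, parents(g, v)),
                      numeric(1)))
      if (s > best_score) {
        best_score <- s
        best <- g
      }
    }
    k <- 1L
    while (k <= m && states[k] == 2L) {
      states[k] <- 0L
      k <- k + 1L
    }
    if (k > m) break
    states[k] <- states[k] + 1L
  }
  list(dag = best, score = best_score)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
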
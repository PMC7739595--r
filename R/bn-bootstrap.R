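# Bootstrap model averaging: learn a structure on each nonparametric
# resample of the rows, record how often each (undirected) arc appears and
# in which orientation, and threshold the frequencies into an averaged
# network.

#' Bootstrap arc strengths
#'
#' Draws `params$bootstrap_reps` nonparametric bootstrap resamples of the
#' rows of `data`, runs [tabu_search()] on each, and tabulates per
#' unordered node pair the fraction of learned models containing the arc in
#' either direction (`strength`) and, among those, the fraction oriented in
#' the canonical direction `from -> to` (`direction`).  Whitelisted arcs
#' appear in every model, so their strength is exactly 1.
#'
#' @inheritParams tabu_search
#' @param unit resampling unit: `"row"` (default) resamples table rows;
#'   `"participant"` resamples participant ids given in `id`.
#' @param id optional vector of participant ids (length `nrow(data)`),
#'   required for `unit = "participant"`.
#' @return a data frame of class `bn_arc_strength` with columns `from`,
#'   `to`, `strength`, `direction`, plus attribute `"reps"`.
#' @export
bootstrap_strength <- function(data, constraints = NULL,
                               params = search_params(), unit = c("row",
                               "participant"), id = NULL) {
  unit <- match.arg(unit)
  R <- params$bootstrap_reps
  n <- nrow(data)
  nodes <- names(data)
  counts <- new.env(parent = emptyenv())  # pairkey -> c(either, forward)
  set.seed(params$seed)
  for (r in seq_len(R)) {
    rows <- if (unit == "row") {
      sample.int(n, n, replace = TRUE)
    } else {
      if (is.null(id)) stop("participant-level resampling needs `id`")
      ids <- unique(id)
      keep <- sample(ids, length(ids), replace = TRUE)
      unlist(lapply(keep, function(i) which(id == i)), use.names = FALSE)
    }
    g <- tabu_search(data[rows, , drop = FALSE], constraints, params)
    if (nrow(g$arcs) == 0L) next
    a <- g$arcs
    canon_fwd <- a[, 1L] < a[, 2L]
    key <- ifelse(canon_fwd, paste(a[, 1L], a[, 2L], sep = "\r"),
                  paste(a[, 2L], a[, 1L], sep = "\r"))
    for (i in seq_along(key)) {
      cur <- counts[[key[i]]] %||% c(0L, 0L)
      counts[[key[i]]] <- cur + c(1L, as.integer(canon_fwd[i]))
    }
  }
  keys <- ls(counts)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    either <- vapply(keys, function(k) counts[[k]][1L], integer(1))
    fwd <- vapply(keys, function(k) counts[[k]][2L], integer(1))
    out <- data.frame(from = parts[, 1L], to = parts[, 2L],
                      strength = either / R,
                      direction = ifelse(either > 0, fwd / either, 0.5),
                      row.names = NULL)
    out <- out[order(-out$strength, out$from, out$to), ]
    rownames(out) <- NULL
  } else {
    out <- data.frame(from = character(), to = character(),
                      strength = numeric(), direction = numeric())
  }
  class(out) <- c("bn_arc_strength", "data.frame")
  attr(out, "reps") <- R
  attr(out, "nodes") <- nodes
  out
}

#' Average a bootstrap arc-strength table into a single network
#'
#' Arcs with strength at or above `inclusion` are retained, oriented by the
#' majority bootstrap direction, and labelled `"significant"` when strength
#' exceeds `significance`, otherwise `"non-significant"`.  If the retained
#' arcs contain a directed cycle, the weakest arc on each cycle is dropped
#' until the graph is acyclic.  Orientation ties (direction exactly 0.5)
#' are broken toward the orientation that keeps the graph acyclic, else
#' lexicographically.
#'
#' @param strengths a `bn_arc_strength` table from [bootstrap_strength()].
#' @param inclusion minimum strength for inclusion (default 0.3, applied
#'   as `>=`; set `strict = TRUE` for `>`).
#' @param significance strength above which an arc is significant (0.5).
#' @param strict apply the inclusion threshold strictly (`>`).
#' @param nodes optional node universe for the returned DAG; defaults to
#'   the nodes recorded on `strengths`.
#' @return list with `dag` (a `bn_dag`), and `arcs`: a data frame of kept
#'   arcs with `from`, `to`, `strength`, `significance` labels.
#' @export
average_network <- function(strengths, inclusion = 0.3, significance = 0.5,
                            strict = FALSE, nodes = NULL) {
  stopifnot(inclusion > 0, inclusion < 1, significance > 0, significance < 1,
            inclusion <= significance)
  nodes <- nodes %||% attr(strengths, "nodes") %||%
    unique(c(strengths$from, strengths$to))
  keep <- if (strict) strengths$strength > inclusion else
    strengths$strength >= inclusion
  s <- strengths[keep, , drop = FALSE]
  if (nrow(s) == 0L) {
    return(list(dag = dag(nodes),
                arcs = data.frame(from = character(), to = character(),
                                  strength = numeric(),
                                  significance = character())))
  }
  # orient by majority direction; ties resolved below
  fwd <- s$direction > 0.5
  tie <- abs(s$direction - 0.5) < 1e-12
  from <- ifelse(fwd | tie, s$from, s$to)
  to <- ifelse(fwd | tie, s$to, s$from)
  ord <- order(-s$strength)
  arcs <- cbind(from = from[ord], to = to[ord])
  strength <- s$strength[ord]
  tie <- tie[ord]
  # tie-broken orientation: try the lexicographic one, flip if it closes a
  # cycle with the stronger arcs already placed
  placed <- NULL
  for (i in seq_len(nrow(arcs))) {
    cand <- rbind(placed, arcs[i, ])
    if (!acyclic_arcs(nodes, cand) && tie[i]) {
      arcs[i, ] <- arcs[i, 2:1]
      cand <- rbind(placed, arcs[i, ])
    }
    placed <- cand
  }
  # repair residual cycles: repeatedly drop the weakest arc that lies on a
  # directed cycle (an arc f -> t is on a cycle iff f is reachable from t
  # through the remaining arcs)
  keep_row <- rep(TRUE, nrow(arcs))
  while (!acyclic_arcs(nodes, arcs[keep_row, , drop = FALSE])) {
    idx <- which(keep_row)
    cyc <- idx[vapply(idx, function(i)
      arc_on_cycle(arcs[keep_row, , drop = FALSE],
                   arcs[i, 1L], arcs[i, 2L]), logical(1))]
    keep_row[max(cyc)] <- FALSE  # arcs are sorted by decreasing strength
  }
  arcs <- arcs[keep_row, , drop = FALSE]
  strength <- strength[keep_row]
  g <- dag(nodes, arcs)
  lab <- ifelse(strength > significance, "significant", "non-significant")
  list(dag = g,
       arcs = data.frame(from = arcs[, 1L], to = arcs[, 2L],
                         strength = strength, significance = lab,
                         row.names = NULL))
}

# is there a directed path to -> ... -> from within `arcs`?
arc_on_cycle <- function(arcs, from, to) {
  frontier <- to
  seen <- character(0)
  while (length(frontier)) {
    nxt <- unique(arcs[arcs[, 1L] %in% frontier, 2L])
    nxt <- setdiff(nxt, seen)
    if (from %in% nxt) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- nxt
  }
  FALSE
}

#' Write / read an arc-strength table as CSV
#' @param strengths a `bn_arc_strength` data frame.
#' @param file path.
#' @export
write_strengths_csv <- function(strengths, file) {
  utils::write.csv(as.data.frame(strengths), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_strengths_csv
#' @export
read_strengths_csv <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  class(out) <- c("bn_arc_strength", "data.frame")
  out
}
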
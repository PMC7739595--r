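#' Structural constraints for network learning
#'
#' A constraint set pairs a blacklist (directed arcs that may never appear)
#' with a whitelist (directed arcs that must always appear).  Temporal
#' ordering and theory-driven structure are encoded this way before search.
#'
#' @param blacklist,whitelist two-column matrices / data frames of directed
#'   arcs (`from`, `to`); either may be `NULL`.
#' @return An object of class `bn_constraints`.
#' @export
constraints <- function(blacklist = NULL, whitelist = NULL) {
  bl <- as_arc_matrix(blacklist)
  wl <- as_arc_matrix(whitelist)
  bl <- unique(bl)
  wl <- unique(wl)
  if (nrow(wl)) {
    wkey <- paste(wl[, 1L], wl[, 2L], sep = "\r")
    bkey <- paste(bl[, 1L], bl[, 2L], sep = "\r")
    rkey <- paste(bl[, 2L], bl[, 1L], sep = "\r")
    if (any(wkey %in% bkey)) stop("an arc is both whitelisted and blacklisted")
    nodes <- unique(c(wl))
    if (!acyclic_arcs(nodes, wl)) stop("whitelist arcs form a cycle")
    # a blacklist entry for the reverse of a whitelisted arc is redundant but
    # legal; both directions blacklisted while one is whitelisted is not
    both <- wkey %in% rkey & paste(wl[, 2L], wl[, 1L], sep = "\r") %in% wkey
    if (any(both)) stop("whitelist contains both directions of an arc")
  }
  structure(list(blacklist = bl, whitelist = wl), class = "bn_constraints")
}

new_empty_constraints <- function() constraints(NULL, NULL)

#' @export
print.bn_constraints <- function(x, ...) {
  cat("Constraint set:", nrow(x$blacklist), "blacklisted,",
      nrow(x$whitelist), "whitelisted arcs\n")
  invisible(x)
}

arc_in <- function(arcs, from, to) {
  any(arcs[, 1L] == from & arcs[, 2L] == to)
}

#' Build the study-style blacklist for a two-time-slice table
#'
#' Generates the rule families used for longitudinal cohort networks:
#' temporal order (no arcs from later-slice `_2` variables into `_1`
#' variables), no arcs from time-varying independent variables into fixed
#' explanatory variables, no same-variable persistence arcs `x_1 -> x_2`,
#' and a set of named explanatory-pair restrictions (by default: competitive
#' level into gender, baseline negative life events into gender and into
#' sport type, which would not make substantive sense reversed).
#'
#' @param explanatory character vector of fixed explanatory variable names.
#' @param independent character vector of base names of time-varying
#'   variables; their slice columns are `<name>_1` and `<name>_2`.
#' @param extra_pairs optional two-column matrix of additional forbidden
#'   directed arcs among explanatory variables.
#' @param same_variable forbid `x_1 -> x_2` persistence arcs (default TRUE).
#' @return two-column character matrix of blacklisted arcs.
#' @export
make_blacklist_2tbn <- function(explanatory, independent,
                                extra_pairs = NULL, same_variable = TRUE) {
  s1 <- paste0(independent, "_1")
  s2 <- paste0(independent, "_2")
  bl <- list()
  # temporal: second slice never points at first slice
  bl$temporal <- cbind(from = rep(s2, each = length(s1)),
                       to = rep(s1, times = length(s2)))
  # independent (either slice) never points at explanatory
  ind <- c(s1, s2)
  bl$expl <- cbind(from = rep(ind, each = length(explanatory)),
                   to = rep(explanatory, times = length(ind)))
  if (same_variable) bl$same <- cbind(from = s1, to = s2)
  if (!is.null(extra_pairs)) bl$extra <- as_arc_matrix(extra_pairs)
  unique(do.call(rbind, bl))
}

#' Default forbidden explanatory-pair arcs
#'
#' @param gender,comp_level,sport_type,baseline_nle column names used in the
#'   prepared table.
#' @return two-column arc matrix.
#' @export
default_explanatory_blacklist <- function(gender = "gender",
                                          comp_level = "comp_level",
                                          sport_type = "sport_type",
                                          baseline_nle = "baseline_nle") {
  rbind(c(comp_level, gender),
        c(baseline_nle, gender),
        c(baseline_nle, sport_type))
}

#' Blacklist for a conditional-linear-Gaussian table
#'
#' In a CLG network a discrete node may not have continuous parents, so
#' every continuous-to-discrete arc is forbidden.  Arcs from time-varying
#' variables into the fixed explanatory variables are forbidden as well.
#'
#' @param discrete,continuous column names by type.
#' @param explanatory subset of `discrete` treated as fixed explanatory
#'   variables (no incoming arcs from non-explanatory variables).
#' @return two-column arc matrix.
#' @export
make_blacklist_clg <- function(discrete, continuous, explanatory = discrete) {
  bl <- cbind(from = rep(continuous, each = length(discrete)),
              to = rep(discrete, times = length(continuous)))
  nonexp <- setdiff(c(discrete, continuous), explanatory)
  if (length(nonexp) && length(explanatory)) {
    bl <- rbind(bl, cbind(from = rep(nonexp, each = length(explanatory)),
                          to = rep(explanatory, times = length(nonexp))))
  }
  unique(bl)
}

#' Read / write arc lists as CSV
#' @param file path to a CSV with columns `from`, `to`.
#' @return two-column character matrix.
#' @export
read_arcs_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  as_arc_matrix(d[, c("from", "to")])
}

#' @rdname read_arcs_csv
#' @param arcs two-column arc matrix.
#' @export
write_arcs_csv <- function(arcs, file) {
  utils::write.csv(as.data.frame(as_arc_matrix(arcs)), file,
                   row.names = FALSE)
  invisible(file)
}
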
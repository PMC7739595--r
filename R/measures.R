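# Scoring of the raw study instruments into analysis variables: life-event
# survey totals, personality subscale sums, RMSSD heart rate variability
# from inter-beat intervals, total lower-limb muscle stiffness, and balance
# error scores.

#' Score a 69-item life-event survey response
#'
#' Each of the 69 items is rated on an 8-point scale from -4 (extremely
#' negative) to +4 (extremely positive), or marked not experienced
#' (`NA`), which contributes 0.  The negative life event score (NLE) is
#' the magnitude of the sum of negative ratings, the positive score (PLE)
#' the sum of positive ratings, and the total (TLE) the sum of absolute
#' values of all ratings, so that `TLE = NLE + PLE`.
#'
#' @param ratings numeric vector of exactly 69 item ratings in -4..4
#'   (0 excluded by the instrument but tolerated), with `NA` for items not
#'   experienced.
#' @return named numeric vector `c(nle, ple, tle)`.
#' @examples
#' r <- rep(NA_real_, 69); r[1:3] <- c(-3, 2, -1)
#' score_lesca(r)  # nle 4, ple 2, tle 6
#' @export
score_lesca <- function(ratings) {
  if (length(ratings) != 69L) stop("a response must have exactly 69 items")
  ok <- is.na(ratings) | (ratings >= -4 & ratings <= 4 &
                            ratings == round(ratings))
  if (!all(ok)) stop("ratings must be integers in -4..4 or NA")
  r <- ratings[!is.na(ratings)]
  nle <- abs(sum(r[r < 0]))
  ple <- sum(r[r > 0])
  c(nle = nle, ple = ple, tle = nle + ple)
}

#' Default subscale map for the 51-item personality questionnaire
#'
#' Maps items 1..51 to the six subscales: Fight-Flight-Freeze System
#' (FFFS, 8 items), Behavioural Inhibition System (BIS, 17 items), Reward
#' Interest (RI, 4 items), Goal Drive Persistence (GDP, 7 items), Reward
#' Reactivity (RR, 8 items) and Impulsivity (I, 7 items).  The BIS count
#' is pinned by the observed score span 17-68 (17 items at ratings 1..4),
#' FFFS by the span 8-30 and RI by 4-16.
#'
#' @return character vector of length 51 naming the subscale of each item.
#' @export
rstpq_default_map <- function() {
  rep(c("FFFS", "BIS", "RI", "GDP", "RR", "I"),
      times = c(8L, 17L, 4L, 7L, 8L, 7L))
}

#' Score personality questionnaire subscales
#'
#' Sums the 1..4 item responses within each subscale of the reinforcement
#' sensitivity theory personality questionnaire.
#'
#' @param responses integer vector of 51 item responses, each in 1..4.
#' @param subscale_map character vector (same length) mapping each item to
#'   its subscale; defaults to [rstpq_default_map()].
#' @return named numeric vector of per-subscale sums.
#' @export
score_rstpq <- function(responses, subscale_map = rstpq_default_map()) {
  if (length(responses) != length(subscale_map))
    stop("responses and subscale map differ in length")
  if (anyNA(responses) || any(responses < 1 | responses > 4 |
                              responses != round(responses)))
    stop("responses must be integers in 1..4")
  if (anyNA(subscale_map)) stop("every item must be mapped to a subscale")
  scales <- unique(subscale_map)
  vapply(stats::setNames(scales, scales),
         function(s) sum(responses[subscale_map == s]), numeric(1))
}

#' Adaptive artifact filter for inter-beat interval series
#'
#' Removes intervals deviating from a centered running median by more than
#' a relative tolerance; a documented stand-in for the adaptive threshold
#' filters of dedicated HRV packages.  Output is always a subsequence of
#' the input, and the filter is idempotent at a fixed tolerance.
#'
#' @param ibi numeric vector of inter-beat intervals in ms.
#' @param rel_tolerance relative deviation above which a beat is an
#'   artifact (default 0.2).
#' @param window running-median window width in beats (odd; default 11).
#' @return the filtered interval vector.
#' @export
filter_ibi <- function(ibi, rel_tolerance = 0.2, window = 11L) {
  stopifnot(length(ibi) >= 2L, all(ibi > 0),
            rel_tolerance > 0, rel_tolerance < 1)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(ibi)
  half <- window %/% 2L
  med <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    stats::median(ibi[lo:hi])
  }, numeric(1))
  keep <- abs(ibi - med) <= rel_tolerance * med
  if (!any(keep)) stop("all beats rejected: unusable recording")
  ibi[keep]
}

#' RMSSD of a trimmed inter-beat interval recording
#'
#' Discards the first `trim_head` seconds and last `trim_tail` seconds of
#' the recording (default 3 min and 2 min, leaving the central 5-min
#' window of a 10-min recording) and computes the root mean square of
#' successive differences of the remaining RR intervals, together with its
#' natural logarithm.
#'
#' @param ibi numeric vector of inter-beat intervals in ms, in order.
#' @param trim_head,trim_tail seconds discarded at the start / end.
#' @return named numeric vector `c(rmssd, ln_rmssd)` in ms; `ln_rmssd` is
#'   `-Inf` for a constant window.
#' @examples
#' compute_rmssd(rep(c(800, 850), 400))["rmssd"]  # 50
#' @export
compute_rmssd <- function(ibi, trim_head = 180, trim_tail = 120) {
  stopifnot(length(ibi) >= 2L, all(ibi > 0))
  t_end <- cumsum(ibi) / 1000  # s, time at the end of each interval
  total <- t_end[length(t_end)]
  keep <- t_end > trim_head & t_end <= total - trim_tail
  rr <- ibi[keep]
  if (length(rr) < 2L) stop("trimmed window contains fewer than 2 intervals")
  d <- diff(rr)
  rmssd <- sqrt(mean(d^2))
  c(rmssd = rmssd, ln_rmssd = log(rmssd))
}

#' Mean RR interval (as printed alongside the RMSSD definition)
#'
#' The source protocol prints the mean-RR formula `(1/N) sum RR_i` under
#' its RMSSD heading; this helper exposes that arithmetic for
#' completeness.  [compute_rmssd()] implements the canonical RMSSD.
#'
#' @param ibi numeric vector of RR intervals (ms).
#' @return mean RR in ms.
#' @export
mean_rr <- function(ibi) mean(ibi)

#' Total lower-limb stiffness from eight measurement sites
#'
#' Each site (rectus femoris, biceps femoris, medial and lateral
#' gastrocnemius, both limbs) is probed with five consecutive impulses;
#' the site value is the median of the five, a set with coefficient of
#' variation at or above `cv_limit` percent is flagged for re-measurement,
#' and the total score is the sum of the eight site medians.
#'
#' @param impulses a list of 8 numeric vectors (5 impulse stiffness values
#'   each, N/m), named by site, or an 5 x 8 matrix with site columns.
#' @param cv_limit acceptance threshold for the within-site coefficient of
#'   variation, in percent (default 3).
#' @return list with `total` (N/m), `site_values` (named medians), `cv`
#'   (named CVs, %) and `flagged` (sites with CV >= limit).
#' @export
total_stiffness <- function(impulses, cv_limit = 3) {
  if (is.matrix(impulses))
    impulses <- lapply(seq_len(ncol(impulses)), function(j) impulses[, j])
  if (length(impulses) != 8L) stop("exactly 8 sites are required")
  if (any(lengths(impulses) != 5L)) stop("each site needs 5 impulses")
  med <- vapply(impulses, stats::median, numeric(1))
  cv <- vapply(impulses, function(x) 100 * stats::sd(x) / mean(x), numeric(1))
  if (is.null(names(med)) || any(!nzchar(names(med)))) {
    names(med) <- names(cv) <- paste0("site", 1:8)
  }
  list(total = sum(med), site_values = med, cv = cv,
       flagged = names(med)[cv >= cv_limit])
}

#' Score a balance error trial
#'
#' Sums the error counts of the six 20-second stances (dominant leg,
#' non-dominant leg, tandem; each on firm and foam surfaces), each capped
#' at 10 errors, and reports the percentage asymmetry between limbs,
#' `100 * |dominant - non-dominant| / mean(dominant, non-dominant)`
#' computed on the single-leg stances.
#'
#' @param errors named numeric vector of six stance error counts with
#'   names `dl_firm`, `ndl_firm`, `ts_firm`, `dl_foam`, `ndl_foam`,
#'   `ts_foam` (order free).  A stance abandoned for more than 5 s is
#'   entered as 10 by the caller.
#' @return named numeric vector `c(total, asymmetry)`; total in 0..60,
#'   asymmetry in percent (0 when both limb totals are 0).
#' @export
score_bess <- function(errors) {
  need <- c("dl_firm", "ndl_firm", "ts_firm", "dl_foam", "ndl_foam",
            "ts_foam")
  if (!all(need %in% names(errors))) stop("stance counts missing: ",
    paste(setdiff(need, names(errors)), collapse = ", "))
  e <- errors[need]
  if (any(e < 0 | e > 10)) stop("stance counts must be in 0..10")
  dom <- e[["dl_firm"]] + e[["dl_foam"]]
  ndom <- e[["ndl_firm"]] + e[["ndl_foam"]]
  asym <- if (dom + ndom == 0) 0 else 100 * abs(dom - ndom) / mean(c(dom, ndom))
  c(total = sum(e), asymmetry = asym)
}

#' Read / write inter-beat interval files
#'
#' Space-delimited text, one interval in milliseconds per line, tolerant
#' of a single non-numeric header line (the dialect of Polar watch
#' exports).
#'
#' @param file path.
#' @return numeric vector of intervals (ms).
#' @export
read_ibi <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (length(vals) && is.na(vals[1L])) {
    lines <- lines[-1L]
    vals <- suppressWarnings(as.numeric(lines))
  }
  if (anyNA(vals)) stop("non-numeric interval values in ", file)
  vals
}

#' @rdname read_ibi
#' @param ibi numeric vector of intervals (ms).
#' @export
write_ibi <- function(ibi, file) {
  writeLines(format(ibi, trim = TRUE, scientific = FALSE), file)
  invisible(file)
}
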
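# Preparation of scored cohort data into the two analysis tables: the
# discretised two-time-slice table (first network) and the standardised
# change-score table (second network).

#' Cumulative life-event scores
#'
#' Running total of per-time-point life-event scores, accounting for the
#' continuing effect of earlier events: `cum(Tk) = sum_{j <= k} score(Tj)`.
#'
#' @param scores numeric vector of per-time-point scores, time-ordered.
#' @return numeric vector of cumulative scores (monotone non-decreasing).
#' @export
cumulative_life_events <- function(scores) {
  if (any(scores < 0, na.rm = TRUE)) stop("life-event scores are nonnegative")
  cumsum(scores)
}

#' Log scaling of life-event counts
#'
#' `log(x + 1)` in natural logs, so zero counts map to zero; used to make
#' the right-skewed life-event distributions approximately normal before
#' a median split (a raw count of 13 maps to 2.64 and 93 to 4.54,
#' reproducing the published Low/High boundary correspondence).
#'
#' @param score nonnegative numeric vector.
#' @return `log1p(score)`.
#' @export
log_scale <- function(score) {
  if (any(score < 0, na.rm = TRUE)) stop("scores must be nonnegative")
  log1p(score)
}

#' Median-split discretisation into Low / High
#'
#' Values at or below the median become `"Low"`, values above it
#' `"High"`; ties at the boundary go to the lower state, matching the
#' inclusive-lower notation "0-13 (Low) / >13-93 (High)".
#'
#' @param values numeric vector (at least two non-missing values).
#' @param variable optional variable name recorded in the map.
#' @param digits rounding used in the rendered span.
#' @return list with `labels` (factor Low/High, `NA` preserved) and `map`
#'   (class `disc_map`: variable, boundary, min, max and a rendered
#'   span string).
#' @examples
#' median_split(c(1, 2, 3, 4))$labels
#' @export
median_split <- function(values, variable = NULL, digits = 2) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2L) stop("need at least two non-missing values")
  if (max(obs) - min(obs) < 1e-12)
    stop("degenerate split: all values identical")
  m <- stats::median(obs)
  labels <- factor(ifelse(values <= m, "Low", "High"),
                   levels = c("Low", "High"))
  fmt <- function(x) format(round(x, digits), big.mark = ",",
                            trim = TRUE, scientific = FALSE)
  map <- structure(list(variable = variable, boundary = m,
                        min = min(obs), max = max(obs),
                        render = paste0(fmt(min(obs)), "-", fmt(m),
                                        " (Low)  >", fmt(m), "-",
                                        fmt(max(obs)), " (High)")),
                   class = "disc_map")
  list(labels = labels, map = map)
}

#' @export
print.disc_map <- function(x, ...) {
  cat(x$variable %||% "variable", ": ", x$render, "\n", sep = "")
  invisible(x)
}

#' Serialise discretisation maps as JSON
#' @param maps a list of `disc_map` objects.
#' @param file path.
#' @export
write_disc_maps_json <- function(maps, file) {
  jsonlite::write_json(lapply(maps, unclass), file, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(file)
}

# variables measured at every time point (first-network independents)
tbn_independent_vars <- function() {
  c("nle", "bis", "fffs", "ri", "stiffness", "hrv", "balance")
}

tbn_explanatory_vars <- function() {
  c("gender", "sport_type", "comp_level", "prev_injury", "training_hours",
    "baseline_nle")
}

# measurement rows of retained participants, time-ordered
measure_rows <- function(cohort) {
  keep <- cohort$time %in% c("T1", "T2", "T3") &
    cohort$participant %in% retained_ids(cohort)
  out <- cohort[keep, , drop = FALSE]
  out[order(out$participant, out$time), , drop = FALSE]
}

#' Impute a cohort's missing physiological measurements
#'
#' Applies [impute_bagged_trees()] to the measurement rows (T1-T3 of
#' retained participants) of a cohort, imputing stiffness and heart rate
#' variability from the demographics and the other measures.
#'
#' @param cohort a cohort table with missingness flags.
#' @param n_trees,seed passed to [impute_bagged_trees()].
#' @return the cohort with gaps filled (flags retained).
#' @export
impute_cohort <- function(cohort, n_trees = 25L, seed = 1L) {
  rows <- which(cohort$time %in% c("T1", "T2", "T3") &
                  cohort$participant %in% retained_ids(cohort))
  pred_cols <- c("time", "gender", "sport_type", "comp_level",
                 "prev_injury", "training_hours", "nle", "tle", "bis",
                 "fffs", "ri", "stiffness", "hrv", "balance")
  sub <- cohort[rows, pred_cols]
  done <- impute_bagged_trees(sub, n_trees = n_trees, seed = seed,
                              targets = c("stiffness", "hrv"))
  cohort$stiffness[rows] <- done$stiffness
  cohort$hrv[rows] <- done$hrv
  cohort
}

#' Discretise a cohort for the first (two-time-slice) network
#'
#' Computes cumulative, log-scaled negative life events per time point,
#' keeps the untransformed baseline NLE as an explanatory variable, and
#' median-splits every analysis variable into Low/High: per time point
#' for the time-varying variables (their medians drift over the study)
#' and pooled for the time-stable explanatory ones.
#'
#' @param cohort an imputed cohort table.
#' @return list with `data` (long discretised measurement table) and
#'   `maps` (named list of `disc_map`).
#' @export
discretise_cohort <- function(cohort) {
  m <- measure_rows(cohort)
  if (anyNA(m$stiffness) || anyNA(m$hrv)) stop("impute the cohort first")
  # cumulative log NLE per participant
  m <- m[order(m$participant, m$time), ]
  m$cum_nle <- stats::ave(m$nle, m$participant, FUN = cumsum)
  m$log_cum_nle <- log_scale(m$cum_nle)
  base <- m[m$time == "T1", c("participant", "nle")]
  names(base)[2L] <- "baseline_nle_raw"
  m <- merge(m, base, by = "participant", sort = FALSE)
  m <- m[order(m$participant, m$time), ]
  maps <- list()
  disc <- data.frame(participant = m$participant, time = m$time,
                     stringsAsFactors = FALSE)
  for (v in c("gender", "sport_type", "comp_level", "prev_injury"))
    disc[[v]] <- factor(m[[v]])
  for (v in c("training_hours", "baseline_nle_raw")) {
    out_name <- if (v == "baseline_nle_raw") "baseline_nle" else v
    sp <- median_split(m[[v]], out_name)
    disc[[out_name]] <- sp$labels
    maps[[out_name]] <- sp$map
  }
  per_tp <- function(values, name) {
    lab <- factor(rep(NA_character_, length(values)),
                  levels = c("Low", "High"))
    for (tp in unique(m$time)) {
      i <- m$time == tp
      sp <- median_split(values[i], paste0(name, "_", sub("T", "", tp)))
      lab[i] <- sp$labels
      maps[[paste0(name, "_", sub("T", "", tp))]] <<- sp$map
    }
    lab
  }
  disc$nle <- per_tp(m$log_cum_nle, "nle")
  for (v in c("bis", "fffs", "ri", "stiffness", "hrv", "balance"))
    disc[[v]] <- per_tp(m[[v]], v)
  disc$injured <- factor(m$injured, levels = c("healthy", "injured"))
  list(data = disc, maps = maps)
}

#' Assemble the two-time-slice (2TBN) analysis table
#'
#' One row per participant per consecutive pair of completed time points
#' (T1+T2 and T2+T3).  Time-varying variables appear twice, suffixed `_1`
#' for time T and `_2` for time T+1; explanatory variables are repeated.
#' `injured_1` is the injury reported at the end of the first interval of
#' the pair and `injured_2` the report for the following interval (the
#' remote final report standing in when no in-person follow-up exists).
#'
#' @param cohort an imputed cohort table (with injury reports).
#' @param disc optional result of [discretise_cohort()]; computed when
#'   omitted.
#' @return list with `data` (the 2TBN data frame of factors) and `maps`.
#' @export
build_2tbn_table <- function(cohort, disc = NULL) {
  disc <- disc %||% discretise_cohort(cohort)
  d <- disc$data
  inj <- cohort[!is.na(cohort$injured),
                c("participant", "time", "injured")]
  report <- function(pid, tp) {
    hit <- inj$injured[inj$participant == pid & inj$time == tp]
    if (length(hit)) hit[1L] else NA_character_
  }
  ind <- tbn_independent_vars()
  expl <- tbn_explanatory_vars()
  rows <- list()
  for (pid in unique(d$participant)) {
    sub <- d[d$participant == pid, ]
    tps <- sub$time
    for (k in seq_len(nrow(sub) - 1L)) {
      t1 <- tps[k]
      t2 <- tps[k + 1L]
      if (match(t2, c("T1", "T2", "T3")) -
            match(t1, c("T1", "T2", "T3")) != 1L) next
      r1 <- sub[k, ]
      r2 <- sub[k + 1L, ]
      inj1 <- report(pid, t2)
      next_tp <- c(T1 = "T2", T2 = "T3", T3 = "T4")[[t2]]
      inj2 <- report(pid, next_tp)
      if (is.na(inj2)) inj2 <- report(pid, "T4")
      row <- c(list(participant = pid, pair = paste0(t1, "_", t2)),
               lapply(expl, function(v) as.character(r1[[v]])),
               lapply(ind, function(v) as.character(r1[[v]])),
               list(as.character(inj1)),
               lapply(ind, function(v) as.character(r2[[v]])),
               list(as.character(inj2)))
      names(row) <- c("participant", "pair", expl,
                      paste0(c(ind, "injured"), "_1"),
                      paste0(c(ind, "injured"), "_2"))
      rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  keep <- stats::complete.cases(out)
  out <- out[keep, , drop = FALSE]
  var_cols <- setdiff(names(out), c("participant", "pair"))
  lev <- function(v) {
    if (grepl("^injured", v)) c("healthy", "injured")
    else if (v %in% c("gender", "sport_type", "comp_level", "prev_injury"))
      sort(unique(out[[v]]))
    else c("Low", "High")
  }
  for (v in var_cols) out[[v]] <- factor(out[[v]], levels = lev(v))
  rownames(out) <- NULL
  list(data = out, maps = disc$maps)
}

#' Assemble the standardised change-score table (second network)
#'
#' Per participant and consecutive completed interval (T1 to T2, T2 to
#' T3), the change `value(T+1) - value(T)` of each continuous measure is
#' computed, pooled across intervals, and standardised to mean 0 and
#' standard deviation 1.  Discrete explanatory variables are carried
#' over (training hours median-split); the outcome is collapsed to
#' whether the participant was injured at any point during the study.
#' Baseline NLE is deliberately excluded so the change in negative life
#' events is the only life-event variable.
#'
#' @param cohort an imputed cohort table.
#' @return list with `data` (data frame: factors + standardised numeric
#'   change columns prefixed `d_`) and `scale` (per-variable mean/sd of
#'   the raw changes).
#' @export
build_change_table <- function(cohort) {
  m <- measure_rows(cohort)
  if (anyNA(m$stiffness) || anyNA(m$hrv)) stop("impute the cohort first")
  vars <- c("nle", "bis", "fffs", "ri", "stiffness", "hrv", "balance")
  any_inj <- tapply(cohort$injured == "injured", cohort$participant,
                    function(x) any(x, na.rm = TRUE))
  rows <- list()
  for (pid in unique(m$participant)) {
    sub <- m[m$participant == pid, ]
    for (k in seq_len(nrow(sub) - 1L)) {
      if (match(sub$time[k + 1L], c("T1", "T2", "T3")) -
            match(sub$time[k], c("T1", "T2", "T3")) != 1L) next
      delta <- lapply(vars, function(v) sub[[v]][k + 1L] - sub[[v]][k])
      names(delta) <- paste0("d_", vars)
      rows[[length(rows) + 1L]] <- as.data.frame(c(
        list(participant = pid,
             interval = paste0(sub$time[k], "_", sub$time[k + 1L]),
             gender = sub$gender[1L], sport_type = sub$sport_type[1L],
             comp_level = sub$comp_level[1L],
             prev_injury = sub$prev_injury[1L],
             training_hours_raw = sub$training_hours[1L]),
        delta), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("no participant contributes a complete interval")
  sp <- median_split(out$training_hours_raw, "training_hours")
  out$training_hours <- sp$labels
  out$training_hours_raw <- NULL
  scale_tab <- list()
  for (v in paste0("d_", vars)) {
    mu <- mean(out[[v]])
    s <- stats::sd(out[[v]])
    if (s < 1e-12) stop("degenerate change column: ", v)
    out[[v]] <- (out[[v]] - mu) / s
    scale_tab[[v]] <- c(mean = mu, sd = s)
  }
  out$injured <- factor(ifelse(any_inj[as.character(out$participant)],
                               "injured", "healthy"),
                        levels = c("healthy", "injured"))
  for (v in c("gender", "sport_type", "comp_level", "prev_injury"))
    out[[v]] <- factor(out[[v]])
  rownames(out) <- NULL
  list(data = out, scale = scale_tab,
       maps = list(training_hours = sp$map))
}
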
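# End-to-end orchestration of the two analyses: the discretised
# two-time-slice network and the standardised change-score network,
# with derived per-stage seeds and an inspectable artifact bundle.

#' Pipeline configuration
#'
#' @param cohort a cohort data frame (or `NULL` to simulate one from
#'   `sim_spec` and `sim_model`).
#' @param sim_model,sim_spec ground-truth model and cohort spec used when
#'   `cohort` is `NULL`.
#' @param params a [search_params()]; its `seed` is re-derived per stage
#'   from `seed`.
#' @param query_samples likelihood-weighting samples per query.
#' @param out_dir optional directory for CSV/JSON/DOT artifacts.
#' @param seed master seed; every stochastic stage receives a derived
#'   child seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, sim_model = NULL,
                            sim_spec = NULL, params = search_params(),
                            query_samples = 1e4, out_dir = NULL,
                            seed = 17L) {
  structure(list(cohort = cohort, sim_model = sim_model,
                 sim_spec = sim_spec, params = params,
                 query_samples = query_samples, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_cohort <- function(config) {
  if (!is.null(config$cohort)) return(config$cohort)
  model <- config$sim_model %||% default_ground_truth()
  spec <- config$sim_spec %||% cohort_spec(seed = derive_seed(config$seed,
                                                              101L))
  inject_missingness(sample_cohort(model, spec), spec)
}

write_artifact <- function(out_dir, name, writer) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writer(file.path(out_dir, name))
}

#' Run the first-network (two-time-slice) analysis
#'
#' Imputes the cohort, builds the discretised 2TBN table, assembles the
#' temporal / explanatory / same-variable blacklist and the life-event
#' whitelist (negative life events into the concurrent injury node),
#' learns bootstrap arc strengths, averages them into a final network,
#' fits its parameters, and queries the Markov blankets of the two injury
#' nodes: single-variable conditional probabilities and the full
#' cross-product evidence grid.
#'
#' @param config a [pipeline_config()].
#' @return list (artifact bundle): `table`, `maps`, `constraints`,
#'   `strengths`, `network` (averaged arcs + dag), `fit`, `blankets`,
#'   `single_cpq`, `grid_cpq`, `log`.
#' @export
run_first_network <- function(config) {
  cohort <- resolve_cohort(config)
  cohort <- impute_cohort(cohort, seed = derive_seed(config$seed, 201L))
  tbn <- build_2tbn_table(cohort)
  data <- tbn$data[setdiff(names(tbn$data), c("participant", "pair"))]
  ind <- c(tbn_independent_vars(), "injured")
  bl <- make_blacklist_2tbn(tbn_explanatory_vars(), ind,
                            extra_pairs = default_explanatory_blacklist())
  wl <- rbind(c("nle_1", "injured_1"), c("nle_2", "injured_2"))
  cons <- constraints(bl, wl)
  params <- config$params
  params$seed <- derive_seed(config$seed, 202L)
  strengths <- bootstrap_strength(data, cons, params)
  avg <- average_network(strengths, params$inclusion_threshold,
                         params$significance_threshold,
                         nodes = names(data))
  fit <- fit_parameters(avg$dag, data, smoothing = params$smoothing)
  blankets <- list(injured_1 = markov_blanket(avg$dag, "injured_1"),
                   injured_2 = markov_blanket(avg$dag, "injured_2"))
  single <- list()
  grid <- list()
  qn <- config$query_samples
  for (tgt in c("injured_1", "injured_2")) {
    mb <- setdiff(blankets[[tgt]], c("injured_1", "injured_2"))
    if (length(mb)) {
      rows <- lapply(mb, function(v) {
        lev <- fit$nodes[[v]]$levels
        ps <- vapply(seq_along(lev), function(i) {
          cpquery_lw(fit, stats::setNames("injured", tgt),
                     stats::setNames(lev[i], v), n = qn,
                     seed = derive_seed(config$seed, 300L + i))$estimate
        }, numeric(1))
        data.frame(variable = v, state = lev, probability = ps,
                   row.names = NULL)
      })
      single[[tgt]] <- do.call(rbind, rows)
      grid[[tgt]] <- blanket_query_table(
        fit, stats::setNames("injured", tgt), mb, n = qn,
        seed = derive_seed(config$seed, 400L))
    }
  }
  log <- list(seed = config$seed,
              bootstrap_reps = params$bootstrap_reps,
              inclusion_threshold = params$inclusion_threshold,
              significance_threshold = params$significance_threshold,
              n_rows = nrow(data),
              blacklist_rules = nrow(cons$blacklist),
              whitelist = wl,
              boundaries = lapply(tbn$maps, function(m) m$render))
  od <- config$out_dir
  write_artifact(od, "first_strengths.csv",
                 function(f) write_strengths_csv(strengths, f))
  write_artifact(od, "first_network.json",
                 function(f) write_dag_json(avg$dag, f))
  write_artifact(od, "first_network.dot",
                 function(f) write_dot(avg$dag, f))
  write_artifact(od, "first_run_log.json", function(f)
    jsonlite::write_json(log, f, auto_unbox = TRUE, pretty = TRUE))
  for (tgt in names(grid)) {
    local({
      t0 <- tgt
      write_artifact(od, paste0("first_grid_", t0, ".csv"), function(f)
        utils::write.csv(grid[[t0]], f, row.names = FALSE))
    })
  }
  list(table = tbn$data, maps = tbn$maps, constraints = cons,
       strengths = strengths, network = avg, fit = fit,
       blankets = blankets, single_cpq = single, grid_cpq = grid,
       log = log)
}

#' Run the second-network (change-score) analysis
#'
#' Imputes the cohort, builds the standardised change table with the
#' any-injury outcome, forbids continuous-to-discrete and
#' independent-to-explanatory arcs, learns and averages the conditional
#' linear Gaussian network, queries the injury node's Markov blanket on
#' the -1 SD / mean / +1 SD evidence grid, and regresses network-drawn
#' samples of the fight-flight-freeze change on the behavioural
#' inhibition and heart-rate-variability changes with a product
#' interaction under normal(0, 5^2) priors.
#'
#' @param config a [pipeline_config()].
#' @return list bundle: `table`, `scale`, `constraints`, `strengths`,
#'   `network`, `fit`, `blanket`, `grid_cpq`, `regression`, `log`.
#' @export
run_second_network <- function(config) {
  cohort <- resolve_cohort(config)
  cohort <- impute_cohort(cohort, seed = derive_seed(config$seed, 201L))
  chg <- build_change_table(cohort)
  data <- chg$data[setdiff(names(chg$data), c("participant", "interval"))]
  disc_vars <- names(data)[!vapply(data, is.numeric, logical(1))]
  cont_vars <- setdiff(names(data), disc_vars)
  expl <- c("gender", "sport_type", "comp_level", "prev_injury",
            "training_hours")
  cons <- constraints(make_blacklist_clg(disc_vars, cont_vars, expl))
  params <- config$params
  params$seed <- derive_seed(config$seed, 502L)
  strengths <- bootstrap_strength(data, cons, params)
  avg <- average_network(strengths, params$inclusion_threshold,
                         params$significance_threshold,
                         nodes = names(data))
  fit <- fit_parameters(avg$dag, data, smoothing = params$smoothing)
  mb <- markov_blanket(avg$dag, "injured")
  grid <- blanket_query_table(fit, c(injured = "injured"), mb,
                              n = config$query_samples,
                              seed = derive_seed(config$seed, 600L))
  # regression stage: FFFS change on BIS and HRV changes + interaction,
  # using network-drawn joint samples
  sm <- sample_conditional(fit, c("d_bis", "d_hrv", "d_fffs"),
                           n = 4000, seed = derive_seed(config$seed, 601L))
  reg <- bayes_linreg(sm$d_fffs,
                      data.frame(BIS = sm$d_bis, HRV = sm$d_hrv),
                      prior_sd = 5, seed = derive_seed(config$seed, 602L))
  log <- list(seed = config$seed,
              bootstrap_reps = params$bootstrap_reps,
              inclusion_threshold = params$inclusion_threshold,
              significance_threshold = params$significance_threshold,
              n_rows = nrow(data), blanket = mb)
  od <- config$out_dir
  write_artifact(od, "second_strengths.csv",
                 function(f) write_strengths_csv(strengths, f))
  write_artifact(od, "second_network.json",
                 function(f) write_dag_json(avg$dag, f))
  write_artifact(od, "second_network.dot",
                 function(f) write_dot(avg$dag, f))
  write_artifact(od, "second_grid.csv", function(f)
    utils::write.csv(grid, f, row.names = FALSE))
  write_artifact(od, "second_regression.csv", function(f)
    utils::write.csv(as.data.frame(reg), f, row.names = FALSE))
  write_artifact(od, "second_run_log.json", function(f)
    jsonlite::write_json(log, f, auto_unbox = TRUE, pretty = TRUE))
  list(table = chg$data, scale = chg$scale, constraints = cons,
       strengths = strengths, network = avg, fit = fit, blanket = mb,
       grid_cpq = grid, regression = reg, log = log)
}

#' Plain-text report of an analysis bundle
#'
#' Renders arc strengths, Markov blankets and query tables of a bundle
#' returned by [run_first_network()] or [run_second_network()] as
#' markdown-flavoured text.
#'
#' @param bundle an artifact bundle.
#' @param file optional path; when `NULL` the text is returned.
#' @export
render_report <- function(bundle, file = NULL) {
  fmt_tab <- function(d) paste(utils::capture.output(print(d)),
                               collapse = "\n")
  parts <- c("# Network analysis report", "",
             "## Averaged network arcs", fmt_tab(bundle$network$arcs), "")
  if (!is.null(bundle$blankets)) {
    for (t in names(bundle$blankets))
      parts <- c(parts, paste0("Markov blanket of ", t, ": ",
                               paste(bundle$blankets[[t]],
                                     collapse = ", ")))
  }
  if (!is.null(bundle$blanket))
    parts <- c(parts, paste0("Markov blanket of injured: ",
                             paste(bundle$blanket, collapse = ", ")))
  grids <- bundle$grid_cpq
  if (is.data.frame(grids)) grids <- list(injured = grids)
  for (t in names(grids))
    parts <- c(parts, "", paste0("## Evidence grid: ", t),
               fmt_tab(grids[[t]]))
  if (!is.null(bundle$regression))
    parts <- c(parts, "", "## Posterior summary (regression stage)",
               fmt_tab(as.data.frame(bundle$regression)))
  txt <- paste(parts, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
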
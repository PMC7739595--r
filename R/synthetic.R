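# Synthetic athlete cohort generator.  A fixed, documented ground-truth
# hybrid network over the study variables (discrete demographics,
# continuous psychosocial and physiological measures per time point, a
# binary injury outcome per reporting interval) is sampled ancestrally so
# that every downstream stage of the pipeline can be validated against a
# known dependency structure.

#' Ground-truth generative model for synthetic cohorts
#'
#' Returns a fixed hybrid network over the study variables.  Discrete
#' demographic roots (gender, sport type, competitive level, previous
#' injury) feed continuous measures (training hours, life-event counts,
#' personality subscales, stiffness, heart rate variability, balance) that
#' persist across the three measurement time points with first-order
#' autocorrelation.  The binary injury outcome for each reporting interval
#' follows a logistic model whose linear predictor combines the
#' standardised change in total stiffness, the standardised change in
#' negative life events, and the standardised stiffness level, each
#' multiplied by `effect_scale`; `effect_scale = 0` renders injury
#' independent of every parent.
#'
#' @param effect_scale nonnegative multiplier on all injury effect sizes.
#' @param base_rate per-interval injury probability when all effects are
#'   at their centred values.  The default 0.216 makes the expected
#'   share of retained participants reporting at least one injury equal
#'   0.46 (117 of 257) under the default retention pattern, in which
#'   participants contribute two or three reporting intervals.
#' @return an object of class `cohort_model`.
#' @export
default_ground_truth <- function(effect_scale = 1, base_rate = 0.216) {
  if (effect_scale < 0) stop("effect_scale must be nonnegative")
  stopifnot(base_rate > 0, base_rate < 1)
  model <- list(
    discrete = list(
      gender = c(female = 120 / 351, male = 231 / 351),
      sport_type = c(individual = 0.35, team = 0.65),
      comp_level = c(club_university_county = 0.80,
                     national_international = 0.20),
      prev_injury = c(no_injury = 0.54, injury = 0.46)
    ),
    continuous = list(
      # mu_fun gives the stationary mean from the participant's discrete
      # profile; rho is time-point-to-time-point autocorrelation
      training_hours = list(mean = 9, sd = 4, rho = 1,
                            effects = list(sport_type = c(individual = 2.5,
                                                          team = 0))),
      bis = list(mean = 38, sd = 8, rho = 0.7, effects = list()),
      ri = list(mean = 9.5, sd = 2.2, rho = 0.7,
                effects = list()),
      gdp = list(mean = 19, sd = 4, rho = 0.7, effects = list()),
      rr = list(mean = 22, sd = 4.5, rho = 0.7, effects = list()),
      imp = list(mean = 16, sd = 4, rho = 0.7, effects = list()),
      stiffness = list(mean = 2150, sd = 380, rho = 0.75,
                       effects = list(gender = c(female = 0, male = 250),
                                      prev_injury = c(no_injury = 0,
                                                      injury = 150))),
      hrv = list(mean = 4.0, sd = 0.55, rho = 0.6, effects = list()),
      balance = list(mean = 16, sd = 6, rho = 0.6,
                     effects = list(comp_level =
                                      c(club_university_county = 1,
                                        national_international = -2)))
    ),
    # child of bis within a time point (moderately strong, recoverable)
    fffs = list(intercept = 4, slope = 0.33, sd = 2.5),
    # negative / positive life events: over-dispersed counts; baseline
    # (12-month window) larger than the later 4-month windows, and
    # individual-sport athletes report more events at baseline
    life_events = list(
      baseline = list(mu = 16, size = 0.8, sport_mult = c(individual = 1.5,
                                                          team = 1)),
      period = list(mu = 8, size = 0.5)
    ),
    injury = list(
      intercept = stats::qlogis(base_rate),
      beta_dstiff = 0.8 * effect_scale,
      beta_dnle = 0.6 * effect_scale,
      beta_stiff = 0.35 * effect_scale,
      # fixed standardisation constants for the linear predictor
      scale_dstiff = 380 * sqrt(2 * (1 - 0.75)),
      scale_dnle = 9,
      scale_stiff = 380
    ),
    effect_scale = effect_scale
  )
  class(model) <- "cohort_model"
  validate_ground_truth(model)
  model
}

validate_ground_truth <- function(model) {
  for (v in names(model$discrete)) {
    p <- model$discrete[[v]]
    if (abs(sum(p) - 1) > 1e-9) stop("probabilities of ", v,
                                     " do not sum to 1")
    if (any(p < 0)) stop("negative probability in ", v)
  }
  for (v in names(model$continuous)) {
    if (model$continuous[[v]]$sd <= 0) stop("nonpositive sd for ", v)
  }
  if (model$fffs$sd <= 0) stop("nonpositive residual sd for fffs")
  invisible(model)
}

#' Per-interval injury probability under the ground truth
#'
#' Exact logistic injury probability for given standardised inputs;
#' used both by the sampler and as an enumeration oracle in tests.
#'
#' @param model a `cohort_model`.
#' @param dstiff,dnle raw changes in stiffness (N/m) and negative life
#'   events between consecutive time points.
#' @param stiff_dev deviation of the stiffness level from the
#'   participant's profile mean (N/m).
#' @return probability in (0, 1).
#' @export
injury_probability <- function(model, dstiff, dnle, stiff_dev = 0) {
  inj <- model$injury
  eta <- inj$intercept +
    inj$beta_dstiff * dstiff / inj$scale_dstiff +
    inj$beta_dnle * dnle / inj$scale_dnle +
    inj$beta_stiff * stiff_dev / inj$scale_stiff
  stats::plogis(eta)
}

#' Cohort sampling specification
#'
#' @param n_recruited participants recruited (default 351).
#' @param n_t1_only participants who complete only the first time point
#'   and contribute no injury reports (default 94).
#' @param n_t2_only retained participants who complete only T1 and T2
#'   (default 121; with the defaults the retained participants contribute
#'   121 x 2 + 136 x 3 = 650 measurement sessions).
#' @param missing_rate_stiffness,missing_rate_hrv independent
#'   missing-completely-at-random rates applied by
#'   [inject_missingness()] (defaults 0.0477 and 0.1077).
#' @param seed integer master seed; stage seeds are derived from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_recruited = 351L, n_t1_only = 94L,
                        n_t2_only = 121L,
                        missing_rate_stiffness = 0.0477,
                        missing_rate_hrv = 0.1077, seed = 17L) {
  stopifnot(n_recruited >= 0, n_t1_only >= 0,
            n_t1_only + n_t2_only <= n_recruited,
            missing_rate_stiffness >= 0, missing_rate_stiffness <= 1,
            missing_rate_hrv >= 0, missing_rate_hrv <= 1)
  structure(list(n_recruited = as.integer(n_recruited),
                 n_t1_only = as.integer(n_t1_only),
                 n_t2_only = as.integer(n_t2_only),
                 missing_rate_stiffness = missing_rate_stiffness,
                 missing_rate_hrv = missing_rate_hrv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

cohort_columns <- function() {
  c("participant", "time", "gender", "sport_type", "comp_level",
    "prev_injury", "training_hours", "nle", "ple", "tle", "bis", "fffs",
    "ri", "gdp", "rr", "imp", "stiffness", "hrv", "balance",
    "balance_asym", "injured", "miss_stiffness", "miss_hrv")
}

empty_cohort <- function() {
  cols <- cohort_columns()
  out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                       cols))
  out$participant <- integer(0)
  out$time <- character(0)
  for (v in c("gender", "sport_type", "comp_level", "prev_injury",
              "injured")) out[[v]] <- character(0)
  for (v in c("training_hours", "nle", "ple", "tle", "bis", "fffs", "ri",
              "gdp", "rr", "imp", "stiffness", "hrv", "balance",
              "balance_asym")) out[[v]] <- numeric(0)
  out$miss_stiffness <- logical(0)
  out$miss_hrv <- logical(0)
  out
}

#' Sample a longitudinal cohort from a ground-truth model
#'
#' Ancestral sampling of the generative network: discrete demographics
#' first, then continuous measures at T1 with per-participant profile
#' means, then T2/T3 by first-order autoregression toward the profile
#' mean, then one injury report per interval (T2, T3, and the remote T4
#' report) from the logistic injury model.  One row per participant per
#' time point; T4 rows carry only the injury report.  Dropout is
#' completely at random: `n_t1_only` participants contribute a single T1
#' row and no injury reports, `n_t2_only` stop after T2.
#'
#' @param model a `cohort_model`.
#' @param spec a `cohort_spec`.
#' @return a cohort data frame (see `cohort_columns()`), deterministic
#'   given `spec$seed`.
#' @export
sample_cohort <- function(model, spec = cohort_spec()) {
  stopifnot(inherits(model, "cohort_model"), inherits(spec, "cohort_spec"))
  n <- spec$n_recruited
  if (n == 0L) return(empty_cohort())
  set.seed(derive_seed(spec$seed, 1L))
  disc <- lapply(model$discrete, function(p)
    names(p)[1L + (stats::runif(n) > p[1L])])
  # completion pattern, completely at random
  perm <- sample.int(n)
  last_tp <- rep(3L, n)
  last_tp[perm[seq_len(spec$n_t1_only)]] <- 1L
  if (spec$n_t2_only > 0L)
    last_tp[perm[spec$n_t1_only + seq_len(spec$n_t2_only)]] <- 2L

  profile_mean <- function(v) {
    cfg <- model$continuous[[v]]
    mu <- rep(cfg$mean, n)
    for (d in names(cfg$effects)) mu <- mu + cfg$effects[[d]][disc[[d]]]
    mu
  }
  cont_names <- names(model$continuous)
  mu <- lapply(stats::setNames(cont_names, cont_names), profile_mean)
  vals <- list()
  for (v in cont_names) {
    cfg <- model$continuous[[v]]
    x <- matrix(NA_real_, n, 3L)
    x[, 1L] <- stats::rnorm(n, mu[[v]], cfg$sd)
    for (t in 2:3) {
      if (cfg$rho >= 1) {
        x[, t] <- x[, t - 1L]  # fixed explanatory quantity
      } else {
        innov_sd <- cfg$sd * sqrt(1 - cfg$rho^2)
        x[, t] <- mu[[v]] + cfg$rho * (x[, t - 1L] - mu[[v]]) +
          stats::rnorm(n, 0, innov_sd)
      }
    }
    vals[[v]] <- x
  }
  vals$training_hours <- pmax(vals$training_hours, 1)
  vals$stiffness <- pmax(vals$stiffness, 800)
  vals$balance <- pmin(pmax(vals$balance, 0), 60)
  vals$hrv <- pmin(pmax(vals$hrv, 1.5), 6.5)
  # fffs is a within-time-point child of bis
  ff <- model$fffs
  vals$fffs <- ff$intercept + ff$slope * vals$bis +
    matrix(stats::rnorm(3L * n, 0, ff$sd), n, 3L)
  # life events: over-dispersed counts, baseline window wider than later
  le <- model$life_events
  nle <- matrix(NA_real_, n, 3L)
  ple <- matrix(NA_real_, n, 3L)
  mu_base <- le$baseline$mu * le$baseline$sport_mult[disc$sport_type]
  nle[, 1L] <- stats::rnbinom(n, size = le$baseline$size, mu = mu_base)
  ple[, 1L] <- stats::rnbinom(n, size = 0.8, mu = 10)
  for (t in 2:3) {
    nle[, t] <- stats::rnbinom(n, size = le$period$size, mu = le$period$mu)
    ple[, t] <- stats::rnbinom(n, size = 0.8, mu = 6)
  }
  nle <- pmin(nle, 93)
  tle <- nle + ple
  # injuries per reporting interval: the T2 / T3 in-person reports use the
  # change into the interval; the remote T4 report (collected from every
  # retained participant by email) reuses the last observed change
  set.seed(derive_seed(spec$seed, 2L))
  p_of <- function(from, to) injury_probability(
    model, vals$stiffness[, to] - vals$stiffness[, from],
    nle[, to] - nle[, from], vals$stiffness[, to] - mu$stiffness)
  p12 <- p_of(1L, 2L)
  p23 <- p_of(2L, 3L)
  p_t4 <- ifelse(last_tp >= 3L, p23, p12)
  u <- matrix(stats::runif(3L * n), n, 3L)
  inj <- cbind(u[, 1L] < p12, u[, 2L] < p23, u[, 3L] < p_t4)

  rows <- list()
  tp_names <- c("T1", "T2", "T3")
  for (t in 1:3) {
    in_t <- last_tp >= t
    idx <- which(in_t)
    if (!length(idx)) next
    rows[[t]] <- data.frame(
      participant = idx, time = tp_names[t],
      gender = disc$gender[idx], sport_type = disc$sport_type[idx],
      comp_level = disc$comp_level[idx], prev_injury = disc$prev_injury[idx],
      training_hours = round(vals$training_hours[idx, 1L], 1),
      nle = nle[idx, t], ple = ple[idx, t], tle = tle[idx, t],
      bis = round(vals$bis[idx, t], 1), fffs = round(vals$fffs[idx, t], 1),
      ri = round(vals$ri[idx, t], 1), gdp = round(vals$gdp[idx, t], 1),
      rr = round(vals$rr[idx, t], 1), imp = round(vals$imp[idx, t], 1),
      stiffness = round(vals$stiffness[idx, t]),
      hrv = round(vals$hrv[idx, t], 2),
      balance = round(vals$balance[idx, t]),
      balance_asym = round(abs(stats::rnorm(length(idx), 20, 12)), 1),
      injured = if (t == 1L) NA_character_ else
        ifelse(inj[idx, t - 1L], "injured", "healthy"),
      miss_stiffness = FALSE, miss_hrv = FALSE,
      stringsAsFactors = FALSE)
  }
  # injury reports only exist for intervals the participant stayed for:
  # a T2 row reports interval T1->T2, etc.; the remote T4 report is
  # collected from every retained participant
  idx4 <- which(last_tp >= 2L)
  t4 <- data.frame(
    participant = idx4, time = "T4",
    gender = disc$gender[idx4], sport_type = disc$sport_type[idx4],
    comp_level = disc$comp_level[idx4], prev_injury = disc$prev_injury[idx4],
    training_hours = NA_real_, nle = NA_real_, ple = NA_real_,
    tle = NA_real_, bis = NA_real_, fffs = NA_real_, ri = NA_real_,
    gdp = NA_real_, rr = NA_real_, imp = NA_real_, stiffness = NA_real_,
    hrv = NA_real_, balance = NA_real_, balance_asym = NA_real_,
    injured = ifelse(inj[idx4, 3L], "injured", "healthy"),
    miss_stiffness = FALSE, miss_hrv = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, c(rows, list(t4)))
  out <- out[order(out$participant, out$time), cohort_columns()]
  rownames(out) <- NULL
  out
}

#' Inject missing-completely-at-random gaps into a cohort
#'
#' Independently masks each stiffness measurement with probability
#' `spec$missing_rate_stiffness` and each heart-rate-variability
#' measurement with `spec$missing_rate_hrv` on the measurement rows
#' (T1-T3) of retained participants, recording missingness flags.  All
#' other fields are untouched.
#'
#' @param cohort a complete cohort table.
#' @param spec a `cohort_spec` (rates and seed are used).
#' @return the cohort with `NA` gaps and updated flags.
#' @export
inject_missingness <- function(cohort, spec = cohort_spec()) {
  if (any(cohort$miss_stiffness | cohort$miss_hrv))
    stop("cohort already contains injected missingness")
  set.seed(derive_seed(spec$seed, 3L))
  measure <- cohort$time %in% c("T1", "T2", "T3") &
    cohort$participant %in% retained_ids(cohort)
  ms <- measure & stats::runif(nrow(cohort)) < spec$missing_rate_stiffness
  mh <- measure & stats::runif(nrow(cohort)) < spec$missing_rate_hrv
  cohort$stiffness[ms] <- NA_real_
  cohort$hrv[mh] <- NA_real_
  cohort$miss_stiffness <- ms
  cohort$miss_hrv <- mh
  cohort
}

# participants with at least one post-T1 observation
retained_ids <- function(cohort) {
  has_later <- tapply(cohort$time != "T1", cohort$participant, any)
  as.integer(names(has_later)[has_later])
}

#' Deterministic descriptive counts of a cohort table
#'
#' Reproduces the study-level bookkeeping: recruited and retained
#' participant counts, number of retained participants reporting at least
#' one injury, total measurement sessions (T1-T3 rows of retained
#' participants), and missing stiffness / heart-rate-variability counts.
#'
#' @param cohort a cohort table.
#' @return named list of counts.
#' @export
cohort_descriptives <- function(cohort) {
  retained <- retained_ids(cohort)
  meas <- cohort$time %in% c("T1", "T2", "T3") &
    cohort$participant %in% retained
  inj <- tapply(cohort$injured == "injured", cohort$participant,
                function(x) any(x, na.rm = TRUE))
  list(n_recruited = length(unique(cohort$participant)),
       n_retained = length(retained),
       n_t1_only = length(unique(cohort$participant)) - length(retained),
       n_injured = sum(inj[as.character(retained)]),
       n_measurements = sum(meas),
       n_missing_stiffness = sum(is.na(cohort$stiffness[meas])),
       n_missing_hrv = sum(is.na(cohort$hrv[meas])))
}

#' Generate a synthetic inter-beat-interval recording
#'
#' Builds a recording with a prescribed mean interval and target RMSSD by
#' alternating intervals `mean_ibi + d` and `mean_ibi - d` with
#' `d = target_rmssd / 2`, so every successive difference is `2 d` and the
#' RMSSD of any window equals `target_rmssd` exactly.  Optional ectopic
#' artifacts (interval doubling) can be injected for filter testing.
#'
#' @param mean_ibi mean interval in ms (> 0).
#' @param target_rmssd desired RMSSD in ms (>= 0).
#' @param duration recording length in seconds (>= 600 to leave a 5-min
#'   analysis window after the 3-min head / 2-min tail trim).
#' @param seed integer seed (placement of artifacts).
#' @param artifact_rate fraction of beats replaced by a doubled interval.
#' @return numeric vector of intervals (ms).
#' @export
generate_ibi_series <- function(mean_ibi, target_rmssd, duration = 600,
                                seed = 1L, artifact_rate = 0) {
  stopifnot(mean_ibi > 0, target_rmssd >= 0,
            artifact_rate >= 0, artifact_rate < 1)
  if (duration < 600) stop("duration must leave a 5-min analysis window")
  n <- ceiling(duration * 1000 / mean_ibi) + 1L
  d <- target_rmssd / 2
  ibi <- rep(c(mean_ibi + d, mean_ibi - d), length.out = n)
  if (artifact_rate > 0) {
    set.seed(derive_seed(seed, 5L))
    hit <- stats::runif(n) < artifact_rate
    ibi[hit] <- ibi[hit] * 2
  }
  ibi
}

#' Write a cohort table to CSV
#' @param cohort a cohort table.
#' @param file path.
#' @export
write_cohort_csv <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE, na.strings = "")
  out$miss_stiffness <- as.logical(out$miss_stiffness)
  out$miss_hrv <- as.logical(out$miss_hrv)
  out
}
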
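# Seeded synthetic cohort generator. Emulates a large dual-app cohort:
# logistic-normal macronutrient energy compositions, moment-matched sleep
# outcomes (normal TST; gamma latency and %WASO, which cannot go negative),
# demographic covariates, and minor dietary exposures with sodium derived
# from a lognormal Na/K ratio so the mean ratio is controlled directly.
# Linear effects of pivot-balance coordinates on sleep outcomes can be
# planted and calibrated so that a chosen reallocation of the mean
# composition shifts the model-implied outcome by an exact target amount.

#' Construct a planted balance effect
#'
#' Declares that the model generating a sleep outcome should respond to the
#' focal pivot balance of a reallocation spec such that applying the
#' reallocation at the mean composition changes the outcome by exactly
#' `target`.
#'
#' @param spec A [realloc_spec()] naming the focal nutrient and displacement.
#' @param outcome One of `"tst_h"`, `"sl_min"`, `"waso_pct"`.
#' @param target Target model-implied difference, in outcome units.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(spec, outcome, target) {
  stopifnot(inherits(spec, "realloc_spec"))
  outcome <- match.arg(outcome, c("tst_h", "sl_min", "waso_pct"))
  structure(list(spec = spec, outcome = outcome, target = as.numeric(target)),
            class = "planted_effect")
}

#' Generator configuration
#'
#' Assembles (and validates) all parameters of the synthetic cohort. Defaults
#' reproduce the study conditions: n = 4825, mean energy composition
#' (0.182, 0.538, 0.097, 0.118, 0.065), balance-coordinate SDs of 0.12,
#' sleep marginals TST 6.7 (1.1) h, latency 21.5 (12.1) min, %WASO 9.9 (7.2),
#' age 36.7 (10.4) y truncated to 18-80, BMI 24.8 (4.8) truncated to 14-60,
#' 81.6% female, energy 1662.6 (330.3) kcal, fiber 11.7 (3.5) g/d,
#' potassium 2295.3 (602.1) mg/d, Na/K ratio 1.6 (0.4) (sodium derived as
#' ratio x potassium), and three planted balance effects calibrated to
#' add-6% reallocation differences of +0.27 h TST (protein), +4.64 min SL
#' (monounsaturated fat) and -4.72 min SL (polyunsaturated fat).
#'
#' @param n_participants Number of analysis-ready rows to generate.
#' @param seed Integer RNG seed.
#' @param mean_composition 5-part simplex centre of the logistic-normal.
#' @param ilr_sd SDs of the 4 balance coordinates (default basis).
#' @param outcome_params Per-outcome list of `mean`, `sd`, `family`
#'   (`"normal"` or `"gamma"`).
#' @param covariate_params Age/BMI moments, truncation bounds, `p_female`.
#' @param covariate_effects Per-outcome coefficients on (female, age, bmi),
#'   applied centred so marginal outcome means are preserved.
#' @param minor_exposures Moments for energy, fiber, potassium and the
#'   sodium-to-potassium ratio.
#' @param days_params Moments and floor for per-stream recording-day counts.
#' @param planted_effects List of [planted_effect()] objects.
#' @param exclusion_counts Named counts `missing_sleep`, `tst_outlier`,
#'   `short_usage` of extra flagged rows to append (all zero by default).
#' @param days_per_participant,p_complete_day,daily_cv Day-level log
#'   parameters: days per participant, probability a day has all three meals
#'   recorded, and the coefficient of variation of daily values around the
#'   participant mean.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(
    n_participants = 4825,
    seed = 20240131,
    mean_composition = c(protein = 0.182, carbohydrate = 0.538,
                         saturated = 0.097, monounsaturated = 0.118,
                         polyunsaturated = 0.065),
    ilr_sd = rep(0.12, 4),
    outcome_params = list(
      tst_h    = list(mean = 6.7,  sd = 1.1,  family = "normal"),
      sl_min   = list(mean = 21.5, sd = 12.1, family = "gamma"),
      waso_pct = list(mean = 9.9,  sd = 7.2,  family = "gamma")),
    covariate_params = list(age_mean = 36.7, age_sd = 10.4,
                            age_range = c(18, 80),
                            bmi_mean = 24.8, bmi_sd = 4.8,
                            bmi_range = c(14, 60),
                            p_female = 0.816),
    covariate_effects = list(
      tst_h    = c(female = 0.2,  age = -0.005, bmi = -0.01),
      sl_min   = c(female = -2.4, age = 0.05,   bmi = 0.1),
      waso_pct = c(female = -3.9, age = 0.05,   bmi = 0.1)),
    minor_exposures = list(energy_mean = 1662.6, energy_sd = 330.3,
                           fiber_mean = 11.7, fiber_sd = 3.5,
                           potassium_mean = 2295.3, potassium_sd = 602.1,
                           na_k_mean = 1.6, na_k_sd = 0.4),
    days_params = list(sleep_mean = 134.0, sleep_sd = 54.5,
                       diet_mean = 85.8, diet_sd = 63.6, min_days = 7),
    planted_effects = list(
      planted_effect(realloc_spec("protein", 0.06, "add"), "tst_h", 0.27),
      planted_effect(realloc_spec("monounsaturated", 0.06, "add"), "sl_min", 4.64),
      planted_effect(realloc_spec("polyunsaturated", 0.06, "add"), "sl_min", -4.72)),
    exclusion_counts = c(missing_sleep = 0, tst_outlier = 0, short_usage = 0),
    days_per_participant = 28,
    p_complete_day = 0.8,
    daily_cv = 0.15) {
  mean_composition <- as.numeric(mean_composition)
  if (length(mean_composition) != 5 || any(mean_composition <= 0) ||
      abs(sum(mean_composition) - 1) > 1e-12) {
    stop("mean_composition must be 5 strictly positive parts summing to 1")
  }
  names(mean_composition) <- macro_parts()
  if (!is.numeric(n_participants) || length(n_participants) != 1 ||
      n_participants < 0 || n_participants != round(n_participants)) {
    stop("n_participants must be a non-negative integer")
  }
  if (any(ilr_sd < 0) || length(ilr_sd) != 4) stop("ilr_sd must be 4 non-negative SDs")
  pf <- covariate_params$p_female
  if (is.null(pf) || pf < 0 || pf > 1) stop("p_female must lie in [0, 1]")
  for (op in outcome_params) {
    if (op$sd < 0) stop("outcome SDs must be non-negative")
  }
  if (days_per_participant < 0 || days_per_participant != round(days_per_participant)) {
    stop("days_per_participant must be a non-negative integer")
  }
  if (p_complete_day < 0 || p_complete_day > 1) stop("p_complete_day must lie in [0, 1]")
  ec <- c(missing_sleep = 0, tst_outlier = 0, short_usage = 0)
  ec[names(exclusion_counts)] <- exclusion_counts
  if (any(ec < 0)) stop("exclusion counts must be non-negative")
  structure(
    list(n_participants = as.integer(n_participants), seed = as.integer(seed),
         mean_composition = mean_composition, ilr_sd = as.numeric(ilr_sd),
         outcome_params = outcome_params, covariate_params = covariate_params,
         covariate_effects = covariate_effects,
         minor_exposures = minor_exposures, days_params = days_params,
         planted_effects = planted_effects, exclusion_counts = ec,
         days_per_participant = as.integer(days_per_participant),
         p_complete_day = p_complete_day, daily_cv = daily_cv),
    class = "generator_config")
}

#' Calibrate a single balance coefficient to a target reallocation difference
#'
#' Returns `b = target / (z1(reallocate(x, spec)) - z1(x))` where `z1` is the
#' first (focal pivot) balance of `basis`. Planting `b` on that balance, with
#' all other balance coefficients zero, makes the model-implied difference of
#' the reallocation exactly `target`.
#'
#' @param target_difference Desired difference in outcome units.
#' @param realloc A [realloc_spec()], feasible at `mean_comp`.
#' @param mean_comp Composition at which the reallocation is evaluated.
#' @param basis Pivot basis whose first row isolates the focal nutrient
#'   (default: the pivot basis of `realloc$focal`).
#' @return Coefficient in outcome units per balance unit.
#' @export
calibrate_balance_effect <- function(target_difference, realloc, mean_comp,
                                     basis = make_basis(length(mean_comp), realloc$focal)) {
  mean_comp <- check_composition(mean_comp)
  z1 <- function(x) sum(basis[1, ] * log(x))
  dz <- z1(reallocate(mean_comp, realloc)) - z1(mean_comp)
  if (abs(dz) < 1e-12) stop("degenerate reallocation: zero balance displacement")
  as.numeric(target_difference) / dz
}

# Jointly calibrate all planted effects. Each effect l contributes
# b_l * z1_l(x) to its outcome, z1_l being the focal pivot balance of its
# spec. Effects sharing an outcome interact (one nutrient's reallocation
# moves every pivot balance), so per outcome we solve the square linear
# system A b = target with A[k, l] = change in balance l under reallocation k
# at the mean composition. For a single effect this reduces to
# calibrate_balance_effect().
calibrate_planted_effects <- function(effects, mean_comp) {
  if (length(effects) == 0) return(list())
  rows <- lapply(effects, function(e) make_basis(length(mean_comp), e$spec$focal)[1, ])
  out_names <- vapply(effects, function(e) e$outcome, character(1))
  coefs <- numeric(length(effects))
  for (oc in unique(out_names)) {
    idx <- which(out_names == oc)
    A <- matrix(0, length(idx), length(idx))
    tgt <- vapply(effects[idx], function(e) e$target, numeric(1))
    for (k in seq_along(idx)) {
      xk <- reallocate(mean_comp, effects[[idx[k]]]$spec)
      dlog <- log(xk) - log(mean_comp)
      for (l in seq_along(idx)) A[k, l] <- sum(rows[[idx[l]]] * dlog)
    }
    coefs[idx] <- solve(A, tgt)
  }
  Map(function(e, b, v) { e$coef <- b; e$balance_row <- v; e },
      effects, coefs, rows)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

rlnorm_moments <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Canonical participant-table column layout
#'
#' Column names of an analysis-ready participant table, in order.
#'
#' @return Character vector of column names.
#' @export
participant_columns <- function() {
  c("participant_id", "age_years", "sex", "bmi",
    "protein_g", "carb_g", "satfat_g", "monofat_g", "polyfat_g",
    "energy_kcal", "sodium_mg", "potassium_mg", "fiber_g",
    "tst_h", "sl_min", "waso_pct", "days_sleep", "days_diet")
}

empty_participants <- function() {
  df <- data.frame(participant_id = character(0), age_years = numeric(0),
                   sex = character(0), bmi = numeric(0),
                   protein_g = numeric(0), carb_g = numeric(0),
                   satfat_g = numeric(0), monofat_g = numeric(0),
                   polyfat_g = numeric(0), energy_kcal = numeric(0),
                   sodium_mg = numeric(0), potassium_mg = numeric(0),
                   fiber_g = numeric(0), tst_h = numeric(0),
                   sl_min = numeric(0), waso_pct = numeric(0),
                   days_sleep = integer(0), days_diet = integer(0),
                   stringsAsFactors = FALSE)
  df
}

# core sampler for n analysis-like rows (no exclusion flags)
sample_participants <- function(n, config, id_offset = 0L) {
  if (n == 0) return(empty_participants())
  cp <- config$covariate_params
  me <- config$minor_exposures
  dp <- config$days_params

  sex <- ifelse(stats::runif(n) < cp$p_female, "female", "male")
  age <- rnorm_trunc(n, cp$age_mean, cp$age_sd, cp$age_range[1], cp$age_range[2])
  bmi <- rnorm_trunc(n, cp$bmi_mean, cp$bmi_sd, cp$bmi_range[1], cp$bmi_range[2])

  B <- make_basis(5, "default")
  mu <- as.numeric(B %*% log(config$mean_composition))
  Z <- sapply(1:4, function(j) stats::rnorm(n, mu[j], config$ilr_sd[j]))
  Z <- matrix(Z, nrow = n)
  comp <- t(apply(Z, 1, function(z) ilr_inv(z, B)))
  colnames(comp) <- macro_parts()

  energy <- rnorm_trunc(n, me$energy_mean, me$energy_sd, lower = 200)
  fiber <- rnorm_trunc(n, me$fiber_mean, me$fiber_sd, lower = 0.5)
  potassium <- rlnorm_moments(n, me$potassium_mean, me$potassium_sd)
  nak <- rlnorm_moments(n, me$na_k_mean, me$na_k_sd)
  sodium <- nak * potassium

  grams <- sweep(sweep(comp, 2, kcal_factors(), "/"), 1, energy, "*")

  # planted balance effects + centred covariate effects per outcome
  eff <- calibrate_planted_effects(config$planted_effects, config$mean_composition)
  logc <- log(comp)
  female <- as.numeric(sex == "female")
  shift <- list(tst_h = numeric(n), sl_min = numeric(n), waso_pct = numeric(n))
  for (e in eff) {
    z1 <- as.numeric(logc %*% e$balance_row)
    shift[[e$outcome]] <- shift[[e$outcome]] + e$coef * (z1 - mean(z1))
  }
  for (oc in names(shift)) {
    ce <- config$covariate_effects[[oc]]
    if (!is.null(ce)) {
      shift[[oc]] <- shift[[oc]] +
        ce[["female"]] * (female - mean(female)) +
        ce[["age"]] * (age - mean(age)) +
        ce[["bmi"]] * (bmi - mean(bmi))
    }
  }

  draw_outcome <- function(oc) {
    op <- config$outcome_params[[oc]]
    v_noise <- max(op$sd^2 - stats::var(shift[[oc]]) * (n > 1), 0.25 * op$sd^2)
    if (identical(op$family, "gamma")) {
      shape <- op$mean^2 / v_noise
      base <- stats::rgamma(n, shape = shape, scale = v_noise / op$mean)
    } else {
      base <- stats::rnorm(n, op$mean, sqrt(v_noise))
    }
    base + shift[[oc]]
  }
  tst <- draw_outcome("tst_h")
  # plausibility bounds: redraw noise for rows outside (0, 14]
  bad <- which(tst <= 0 | tst > 14)
  while (length(bad) > 0) {
    op <- config$outcome_params$tst_h
    v_noise <- max(op$sd^2 - stats::var(shift$tst_h) * (n > 1), 0.25 * op$sd^2)
    tst[bad] <- stats::rnorm(length(bad), op$mean, sqrt(v_noise)) + shift$tst_h[bad]
    bad <- bad[tst[bad] <= 0 | tst[bad] > 14]
  }
  sl <- pmax(draw_outcome("sl_min"), 0)
  waso <- pmin(pmax(draw_outcome("waso_pct"), 0), 100)

  days_sleep <- as.integer(round(rnorm_trunc(n, dp$sleep_mean, dp$sleep_sd,
                                             lower = dp$min_days)))
  days_diet <- as.integer(round(rnorm_trunc(n, dp$diet_mean, dp$diet_sd,
                                            lower = dp$min_days)))

  data.frame(
    participant_id = sprintf("P%05d", id_offset + seq_len(n)),
    age_years = age, sex = sex, bmi = bmi,
    protein_g = grams[, 1], carb_g = grams[, 2], satfat_g = grams[, 3],
    monofat_g = grams[, 4], polyfat_g = grams[, 5],
    energy_kcal = energy, sodium_mg = sodium, potassium_mg = potassium,
    fiber_g = fiber, tst_h = tst, sl_min = sl, waso_pct = waso,
    days_sleep = days_sleep, days_diet = days_diet,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic participant-level cohort
#'
#' Draws `n_participants` analysis-ready rows: compositions are
#' logistic-normal (4 default-basis balance coordinates, normal around the
#' ilr of the mean composition, back-transformed), sleep outcomes are
#' moment-matched noise plus calibrated planted balance effects and centred
#' covariate terms, and sodium is derived as ratio x potassium so the mean
#' Na/K ratio is controlled directly. When `exclusion_counts` are nonzero,
#' additional flagged rows are appended (missing sleep summaries, extreme
#' total-sleep-time outliers at six marginal SDs, or usage below the day
#' floor) and the table is row-shuffled, producing a consented-roster fixture
#' for the exclusion cascade.
#'
#' @param config A [generator_config()].
#' @return data.frame with columns [participant_columns()]; identical
#'   configs (including seed) give identical tables.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_participants
  clean <- sample_participants(n, config)
  ec <- config$exclusion_counts
  if (sum(ec) == 0) return(clean)

  dp <- config$days_params
  op <- config$outcome_params$tst_h
  extras <- list()
  if (ec[["missing_sleep"]] > 0) {
    m <- sample_participants(ec[["missing_sleep"]], config, id_offset = n)
    m$tst_h <- NA_real_; m$sl_min <- NA_real_; m$waso_pct <- NA_real_
    extras <- c(extras, list(m))
  }
  if (ec[["tst_outlier"]] > 0) {
    k <- ec[["tst_outlier"]]
    m <- sample_participants(k, config, id_offset = n + ec[["missing_sleep"]])
    # plant at +/- 6 marginal SDs, balanced, so the rows fall outside the
    # mean +/- 3 SD band of the post-missing cohort even after the planted
    # rows themselves inflate that SD
    side <- rep(c(1, -1), length.out = k)
    m$tst_h <- op$mean + side * 6 * op$sd
    extras <- c(extras, list(m))
  }
  if (ec[["short_usage"]] > 0) {
    k <- ec[["short_usage"]]
    m <- sample_participants(k, config,
                             id_offset = n + ec[["missing_sleep"]] + ec[["tst_outlier"]])
    which_stream <- sample(1:3, k, replace = TRUE)  # sleep, diet, or both short
    short <- function(k) as.integer(sample(seq_len(dp$min_days - 1), k, replace = TRUE))
    m$days_sleep[which_stream != 2] <- short(sum(which_stream != 2))
    m$days_diet[which_stream != 1] <- short(sum(which_stream != 1))
    extras <- c(extras, list(m))
  }
  out <- rbind(clean, do.call(rbind, extras))
  out <- out[sample(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate synthetic day-level app logs
#'
#' For each participant of the (clean) cohort implied by `config`, emits
#' `days_per_participant` daily rows whose diet and sleep values fluctuate
#' around the participant-level values with coefficient of variation
#' `daily_cv`, so that per-participant averages over complete-meal days
#' reproduce the participant-level values in expectation. A day records all
#' three meals with probability `p_complete_day`; otherwise one or two meal
#' flags are dropped at random.
#'
#' @param config A [generator_config()].
#' @param cohort Optional pre-generated participant table; default generates
#'   one from `config`.
#' @return data.frame of daily logs: `participant_id`, `day`,
#'   `breakfast`/`lunch`/`dinner` logicals, daily gram intakes and kcal,
#'   nightly `tst_h`, `sl_min`, `waso_pct`, and `diet_recorded`/
#'   `sleep_recorded` flags.
#' @export
generate_daily_logs <- function(config = generator_config(),
                                cohort = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config)
  set.seed(config$seed + 1L)
  d <- config$days_per_participant
  n <- nrow(cohort)
  cols <- c("protein_g", "carb_g", "satfat_g", "monofat_g", "polyfat_g",
            "energy_kcal", "sodium_mg", "potassium_mg", "fiber_g")
  if (n == 0 || d == 0) {
    out <- data.frame(participant_id = character(0), day = integer(0),
                      breakfast = logical(0), lunch = logical(0),
                      dinner = logical(0))
    for (cl in cols) out[[cl]] <- numeric(0)
    out$tst_h <- numeric(0); out$sl_min <- numeric(0); out$waso_pct <- numeric(0)
    out$diet_recorded <- logical(0); out$sleep_recorded <- logical(0)
    return(out)
  }
  idx <- rep(seq_len(n), each = d)
  N <- n * d
  complete <- stats::runif(N) < config$p_complete_day
  meals <- matrix(TRUE, N, 3)
  miss <- which(!complete)
  if (length(miss) > 0) {
    n_missing <- 1 + (stats::runif(length(miss)) < 0.3)  # drop 1 or 2 meals
    for (k in seq_along(miss)) {
      meals[miss[k], sample(3, n_missing[k])] <- FALSE
    }
  }
  noisy <- function(v) {
    x <- v[idx] * (1 + stats::rnorm(N, 0, config$daily_cv))
    pmax(x, 0.05 * v[idx])
  }
  out <- data.frame(participant_id = cohort$participant_id[idx],
                    day = rep(seq_len(d), times = n),
                    breakfast = meals[, 1], lunch = meals[, 2],
                    dinner = meals[, 3], stringsAsFactors = FALSE)
  for (cl in cols) out[[cl]] <- noisy(cohort[[cl]])
  tstp <- cohort$tst_h[idx]
  out$tst_h <- pmin(pmax(tstp + stats::rnorm(N, 0, 0.5), 0.1), 14)
  out$sl_min <- pmax(cohort$sl_min[idx] * (1 + stats::rnorm(N, 0, config$daily_cv)), 0)
  out$waso_pct <- pmin(pmax(cohort$waso_pct[idx] * (1 + stats::rnorm(N, 0, config$daily_cv)), 0), 100)
  out$diet_recorded <- TRUE
  out$sleep_recorded <- TRUE
  out
}
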
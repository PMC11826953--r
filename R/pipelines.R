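# End-to-end analysis stages: derived exposures, quartile dummy regression,
# compositional +/-6% reallocation tables, and isotemporal substitution
# tables. All models adjust for age, sex and BMI and all intervals come from
# the explicit model-matrix algebra in fit_ols()/predict_difference_ci().

macro_gram_cols <- function() {
  c(protein = "protein_g", carbohydrate = "carb_g", saturated = "satfat_g",
    monounsaturated = "monofat_g", polyunsaturated = "polyfat_g")
}

#' Derive analysis exposures from a participant table
#'
#' Adds energy-adjusted macronutrient columns (percent of total energy:
#' gram intake x kcal factor / total kcal x 100, plus total fat), the
#' sodium-to-potassium ratio, and the closed 5-part macronutrient energy
#' composition (`comp_*` columns). Zero gram intakes are replaced by 0.1 g
#' (multiplicative replacement) with a warning before closure, since
#' compositions must be strictly positive.
#'
#' @param cohort Participant-level data.frame with gram intake, energy,
#'   sodium and potassium columns.
#' @return `cohort` with added `pct_*`, `na_k_ratio` and `comp_*` columns.
#' @export
derive_exposures <- function(cohort) {
  if (any(cohort$energy_kcal <= 0)) stop("total energy must be positive")
  if (any(cohort$potassium_mg <= 0)) stop("potassium must be positive")
  gc <- macro_gram_cols()
  grams <- as.matrix(cohort[, gc])
  if (any(grams <= 0)) {
    warning("zero/negative gram intakes replaced by 0.1 g before closure")
    grams[grams <= 0] <- 0.1
  }
  kcal <- sweep(grams, 2, kcal_factors(), "*")
  for (i in seq_along(gc)) {
    cohort[[paste0("pct_", names(gc)[i])]] <- 100 * kcal[, i] / cohort$energy_kcal
  }
  cohort$pct_total_fat <- 100 * rowSums(kcal[, 3:5]) / cohort$energy_kcal
  cohort$na_k_ratio <- cohort$sodium_mg / cohort$potassium_mg
  comp <- kcal / rowSums(kcal)
  colnames(comp) <- paste0("comp_", names(gc))
  cbind(cohort, as.data.frame(comp))
}

#' Assign sample quartiles
#'
#' Cutpoints are the 25th/50th/75th percentiles under the
#' linear-interpolation convention (`stats::quantile` type 7); intervals are
#' closed on the right. Labels are invariant to strictly monotone transforms
#' of the values.
#'
#' @param values Numeric vector with at least 4 distinct values.
#' @return List with `labels` (factor Q1-Q4) and `cutpoints` (3 values).
#' @export
quartile_assign <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("quartile_assign() does not accept missing values")
  if (length(unique(values)) < 4) {
    stop("quartile assignment needs at least 4 distinct values")
  }
  cuts <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  labels <- cut(values, breaks = c(-Inf, cuts, Inf),
                labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  list(labels = labels, cutpoints = cuts)
}

covariate_matrix <- function(cohort) {
  cbind(age = cohort$age_years,
        female = as.numeric(cohort$sex == "female"),
        bmi = cohort$bmi)
}

default_outcomes <- function() c("tst_h", "sl_min", "waso_pct")

#' Quartile dummy-variable regression
#'
#' For each (exposure, outcome) pair, fits one forced-entry OLS of the
#' outcome on Q2-Q4 dummies (first quartile as reference) plus age, sex and
#' BMI, and reports each quartile coefficient with its t-based confidence
#' interval. The reference quartile is never emitted.
#'
#' @param cohort Participant table, already passed through
#'   [derive_exposures()] (or carrying the exposure columns directly).
#' @param exposures Character vector of exposure column names (default: the
#'   energy-adjusted macronutrients, total energy, sodium, potassium, fiber
#'   and the Na/K ratio).
#' @param outcomes Outcome column names (default [default_outcomes()]).
#' @param level Confidence level (default 0.95).
#' @return data.frame with one row per (exposure, outcome, quartile Q2-Q4):
#'   cutpoints, estimate, lower, upper.
#' @export
quartile_regression <- function(cohort,
                                exposures = c("energy_kcal",
                                              paste0("pct_", names(macro_gram_cols())),
                                              "pct_total_fat", "sodium_mg",
                                              "potassium_mg", "fiber_g",
                                              "na_k_ratio"),
                                outcomes = default_outcomes(),
                                level = 0.95) {
  exposures <- intersect(exposures, names(cohort))
  covs <- covariate_matrix(cohort)
  out <- list()
  for (ex in exposures) {
    qa <- quartile_assign(cohort[[ex]])
    dummies <- sapply(c("Q2", "Q3", "Q4"), function(q) as.numeric(qa$labels == q))
    X <- cbind(intercept = 1, dummies, covs)
    for (oc in outcomes) {
      fit <- fit_ols(X, cohort[[oc]])
      for (q in c("Q2", "Q3", "Q4")) {
        d1 <- d0 <- rep(0, ncol(X)); names(d1) <- names(d0) <- colnames(X)
        d1[q] <- 1
        ci <- predict_difference_ci(fit, d1, d0, level)
        out[[length(out) + 1]] <- data.frame(
          exposure = ex, outcome = oc, quartile = q,
          cut_q25 = qa$cutpoints[1], cut_q50 = qa$cutpoints[2],
          cut_q75 = qa$cutpoints[3],
          estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Extract the macronutrient composition matrix of a cohort
#'
#' Returns the closed 5-part energy compositions (`comp_*` columns, derived
#' on the fly when absent) as a plain matrix with [macro_parts()] columns.
#'
#' @param cohort Participant-level data.frame.
#' @return Numeric matrix, one composition per row.
#' @export
composition_matrix <- function(cohort) {
  cc <- paste0("comp_", macro_parts())
  if (!all(cc %in% names(cohort))) cohort <- derive_exposures(cohort)
  m <- as.matrix(cohort[, paste0("comp_", macro_parts())])
  colnames(m) <- macro_parts()
  m
}

# One OLS per outcome on the default-basis ilr coordinates + covariates.
# Predictions (hence reallocation contrasts) are invariant to the basis, so
# a single fit serves every focal nutrient.
fit_compda_models <- function(cohort, outcomes) {
  comp <- composition_matrix(cohort)
  B <- make_basis(5, "default")
  Z <- ilr(comp, B)
  colnames(Z) <- paste0("z", 1:4)
  X <- cbind(intercept = 1, Z, covariate_matrix(cohort))
  fits <- lapply(stats::setNames(nm = outcomes), function(oc) fit_ols(X, cohort[[oc]]))
  list(fits = fits, basis = B, X = X, xbar = compositional_mean(comp))
}

contrast_ci <- function(model, fit, x_new, x_ref, level) {
  p <- length(fit$coefficients)
  d1 <- d0 <- rep(0, p)
  d1[2:5] <- ilr(x_new, model$basis)
  d0[2:5] <- ilr(x_ref, model$basis)
  # identical entries elsewhere (intercept/covariates) cancel exactly
  predict_difference_ci(fit, d1, d0, level)
}

#' Compositional reallocation table (take/add a fixed energy share)
#'
#' Fits, per outcome, an OLS of the outcome on the 4 ilr balance coordinates
#' plus age, sex and BMI; computes the compositional mean of the sample; and
#' for every nutrient and both proportional modes (take `delta` from the
#' nutrient and redistribute; add `delta` to it from the others) reports the
#' confidence interval of the difference between the mean prediction at the
#' reallocated and the original mean composition. With 5 nutrients, 2 modes
#' and 3 outcomes the table has 30 rows.
#'
#' @param cohort Participant table (compositions derived on the fly if
#'   absent).
#' @param delta Displaced energy fraction (default 0.06, the 6% cap implied
#'   by the smallest mean share).
#' @param outcomes Outcome columns (default [default_outcomes()]).
#' @param level Confidence level.
#' @return data.frame: nutrient, mode (`take_6`/`add_6` style), outcome,
#'   estimate, lower, upper, significant (CI excludes 0 at `level`).
#' @export
compda_reallocation_table <- function(cohort, delta = 0.06,
                                      outcomes = default_outcomes(),
                                      level = 0.95) {
  model <- fit_compda_models(cohort, outcomes)
  tag <- paste0(c("take_", "add_"), round(100 * delta))
  out <- list()
  for (nut in macro_parts()) {
    for (mode in c("take", "add")) {
      x_new <- tryCatch(reallocate(model$xbar, realloc_spec(nut, delta, mode)),
                        error = function(e) { warning(conditionMessage(e)); NULL })
      for (oc in outcomes) {
        if (is.null(x_new)) {
          ci <- data.frame(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
        } else {
          ci <- contrast_ci(model, model$fits[[oc]], x_new, model$xbar, level)
        }
        out[[length(out) + 1]] <- data.frame(
          nutrient = nut, mode = tag[1 + (mode == "add")], outcome = oc,
          estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
          significant = !is.na(ci$lower) && (ci$lower > 0 || ci$upper < 0),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Isotemporal substitution table (one-to-one swaps)
#'
#' Uses the same per-outcome compositional fits as
#' [compda_reallocation_table()] but contrasts the mean composition against
#' one-to-one substitutions: for every ordered (from, to) pair of distinct
#' nutrients, `delta` of total energy is moved from the donor to the
#' recipient with the other parts held constant. With 5 nutrients and 3
#' outcomes the table has 5 x 4 x 3 = 60 rows; same-nutrient pairs are
#' skipped by convention.
#'
#' @inheritParams compda_reallocation_table
#' @return data.frame: from, to, outcome, estimate, lower, upper,
#'   significant.
#' @export
isotemporal_table <- function(cohort, delta = 0.06,
                              outcomes = default_outcomes(),
                              level = 0.95) {
  model <- fit_compda_models(cohort, outcomes)
  out <- list()
  for (from in macro_parts()) {
    for (to in setdiff(macro_parts(), from)) {
      x_new <- tryCatch(substitute_pairwise(model$xbar, from, to, delta),
                        error = function(e) { warning(conditionMessage(e)); NULL })
      for (oc in outcomes) {
        if (is.null(x_new)) {
          ci <- data.frame(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
        } else {
          ci <- contrast_ci(model, model$fits[[oc]], x_new, model$xbar, level)
        }
        out[[length(out) + 1]] <- data.frame(
          from = from, to = to, outcome = oc,
          estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
          significant = !is.na(ci$lower) && (ci$lower > 0 || ci$upper < 0),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
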
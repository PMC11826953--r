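test_that("derived exposures follow the energy-adjustment arithmetic", {
  co <- tiny_cohort(6)
  co$protein_g <- 80; co$energy_kcal <- 1600
  co$sodium_mg <- 3200; co$potassium_mg <- 2000
  ex <- derive_exposures(co)
  expect_equal(ex$pct_protein, rep(20, 6))
  expect_equal(ex$na_k_ratio, rep(1.6, 6))
  comp <- composition_matrix(ex)
  expect_equal(rowSums(comp), rep(1, 6), tolerance = 1e-12)

  # %E columns are scale invariant to doubling all grams and energy together
  dbl <- co
  for (cl in c("protein_g", "carb_g", "satfat_g", "monofat_g", "polyfat_g")) {
    dbl[[cl]] <- 2 * dbl[[cl]]
  }
  dbl$energy_kcal <- 2 * dbl$energy_kcal
  expect_equal(derive_exposures(dbl)$pct_carbohydrate, ex$pct_carbohydrate,
               tolerance = 1e-12)

  bad <- co; bad$energy_kcal[1] <- 0
  expect_error(derive_exposures(bad), "energy")
  badk <- co; badk$potassium_mg[1] <- 0
  expect_error(derive_exposures(badk), "potassium")
  zg <- co; zg$polyfat_g[1] <- 0
  expect_warning(derive_exposures(zg), "0.1 g")
})

test_that("quartile assignment uses interpolated cutpoints and is rank invariant", {
  qa <- quartile_assign(1:8)
  expect_equal(qa$cutpoints, c(2.75, 4.5, 6.25))
  expect_equal(as.vector(table(qa$labels)), c(2, 2, 2, 2))
  v <- rexp(40)
  expect_identical(quartile_assign(v)$labels, quartile_assign(exp(v))$labels)
  expect_error(quartile_assign(rep(c(1, 2, 3), 10)), "4 distinct")
})

test_that("quartile regression reports Q2-Q4 against the reference only", {
  co <- derive_exposures(generate_cohort(generator_config(n_participants = 250, seed = 51)))
  qr <- quartile_regression(co, exposures = c("pct_protein", "fiber_g"),
                            outcomes = c("tst_h", "sl_min"))
  expect_equal(nrow(qr), 2 * 2 * 3)
  expect_false("Q1" %in% qr$quartile)
  expect_true(all(qr$lower <= qr$estimate & qr$estimate <= qr$upper))
})

test_that("quartile regression recovers null and monotone planted exposure effects", {
  ests_null <- c(); ests_q2 <- c(); ests_q4 <- c()
  for (s in 1:10) {
    set.seed(900 + s)
    co <- tiny_cohort(250, seed = 900 + s)
    co$tst_h <- rnorm(250, 6.7, 1)                        # no exposure effect
    qr0 <- quartile_regression(co, exposures = "fiber_g", outcomes = "tst_h")
    ests_null <- c(ests_null, qr0$estimate)
    co$tst_h <- co$tst_h + 0.08 * co$fiber_g              # monotone effect
    qr1 <- quartile_regression(co, exposures = "fiber_g", outcomes = "tst_h")
    ests_q2 <- c(ests_q2, qr1$estimate[qr1$quartile == "Q2"])
    ests_q4 <- c(ests_q4, qr1$estimate[qr1$quartile == "Q4"])
  }
  expect_lt(abs(mean(ests_null)), 0.1)
  expect_gt(mean(ests_q4), mean(ests_q2))
})

test_that("reallocation and substitution tables have the full factorial shape", {
  co <- derive_exposures(generate_cohort(generator_config(n_participants = 300, seed = 61)))
  rt <- compda_reallocation_table(co)
  expect_equal(nrow(rt), 30)
  expect_equal(sort(unique(rt$mode)), c("add_6", "take_6"))
  expect_setequal(unique(rt$nutrient), macro_parts())
  expect_true(all(rt$lower <= rt$estimate & rt$estimate <= rt$upper))

  it <- isotemporal_table(co)
  expect_equal(nrow(it), 60)
  expect_true(all(it$from != it$to))  # same-nutrient pairs skipped
})

test_that("reallocation contrasts are invariant to the fitting basis and covariate levels", {
  co <- derive_exposures(generate_cohort(generator_config(n_participants = 200, seed = 71)))
  comp <- composition_matrix(co)
  xbar <- compositional_mean(comp)
  x_new <- reallocate(xbar, realloc_spec("monounsaturated", 0.06, "add"))
  covs <- covariate_matrix <- cbind(age = co$age_years,
                                    female = as.numeric(co$sex == "female"),
                                    bmi = co$bmi)
  res <- list()
  for (focal in c("default", "protein", "polyunsaturated")) {
    B <- make_basis(5, focal)
    X <- cbind(1, ilr(comp, B), covs)
    fit <- fit_ols(X, co$tst_h)
    for (at in list(colMeans(covs), c(0, 0, 0))) {
      d1 <- c(1, ilr(x_new, B), at)
      d0 <- c(1, ilr(xbar, B), at)
      res[[length(res) + 1]] <- predict_difference_ci(fit, d1, d0)
    }
  }
  for (r in res[-1]) expect_equal(r, res[[1]], tolerance = 1e-9)
})

test_that("pairwise estimates match the analytic value of a planted single-balance model", {
  cfg <- generator_config(
    n_participants = 2000, seed = 81, ilr_sd = rep(0.12, 4),
    planted_effects = list(
      planted_effect(realloc_spec("protein", 0.06, "add"), "tst_h", 0.3)),
    covariate_effects = list(tst_h = c(female = 0, age = 0, bmi = 0),
                             sl_min = c(female = 0, age = 0, bmi = 0),
                             waso_pct = c(female = 0, age = 0, bmi = 0)),
    outcome_params = list(
      tst_h = list(mean = 6.7, sd = 0.05, family = "normal"),
      sl_min = list(mean = 21.5, sd = 12.1, family = "gamma"),
      waso_pct = list(mean = 9.9, sd = 7.2, family = "gamma")))
  co <- derive_exposures(generate_cohort(cfg))
  comp <- composition_matrix(co)
  xbar <- compositional_mean(comp)
  b <- calibrate_balance_effect(0.3, realloc_spec("protein", 0.06, "add"),
                                cfg$mean_composition)
  v <- make_basis(5, "protein")[1, ]
  it <- isotemporal_table(co, outcomes = "tst_h")
  for (k in which(it$from == "carbohydrate" & it$to == "protein")) {
    x_new <- substitute_pairwise(xbar, it$from[k], it$to[k], 0.06)
    analytic <- b * sum(v * (log(x_new) - log(xbar)))
    expect_equal(it$estimate[k], analytic, tolerance = 0.02)
  }
})

test_that("small substitutions flip sign to first order when reversed", {
  co <- derive_exposures(generate_cohort(generator_config(n_participants = 400, seed = 91)))
  fwd <- isotemporal_table(co, delta = 0.001, outcomes = "tst_h")
  get <- function(f, t) fwd$estimate[fwd$from == f & fwd$to == t]
  for (pair in list(c("protein", "carbohydrate"),
                    c("monounsaturated", "polyunsaturated"))) {
    a <- get(pair[1], pair[2]); b <- get(pair[2], pair[1])
    # reversal cancels the first-order term; only log-ratio curvature remains
    expect_lt(abs(a + b), 0.05 * abs(a - b) / 2 + 5e-4)
    if (max(abs(a), abs(b)) > 1e-3) expect_true(sign(a) != sign(b))
  }
})
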
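# shared fixtures, built in code

# random strictly positive compositions on the D-simplex
random_compositions <- function(n, D = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(exp(rnorm(n * D, sd = 0.5)), nrow = n)
  m / rowSums(m)
}

# small participant table with hand-controlled fields
tiny_cohort <- function(n = 40, seed = 42) {
  set.seed(seed)
  grams <- cbind(protein_g = runif(n, 50, 110), carb_g = runif(n, 150, 300),
                 satfat_g = runif(n, 10, 30), monofat_g = runif(n, 12, 35),
                 polyfat_g = runif(n, 6, 20))
  energy <- as.numeric(grams %*% c(4, 4, 9, 9, 9))
  data.frame(participant_id = sprintf("T%03d", 1:n),
             age_years = runif(n, 20, 60),
             sex = sample(c("female", "male"), n, replace = TRUE),
             bmi = runif(n, 18, 32), grams,
             energy_kcal = energy,
             sodium_mg = runif(n, 2000, 5000),
             potassium_mg = runif(n, 1500, 3200),
             fiber_g = runif(n, 5, 20),
             tst_h = rnorm(n, 6.7, 1), sl_min = rgamma(n, 4, 0.2),
             waso_pct = rgamma(n, 2, 0.25),
             days_sleep = sample(7:60, n, replace = TRUE),
             days_diet = sample(7:60, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
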
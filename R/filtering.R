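# Inclusion/exclusion cascade and day-level meal filtering: complete-meal-day
# restriction, overlap-window averaging of the two app streams, the staged
# exclusion ledger (missing sleep -> +/-3 SD total-sleep-time outliers ->
# <7-day usage), and Table-1-style cohort summaries.

#' Keep only days with all three meals recorded
#'
#' A day-level diet record is retained only when breakfast, lunch and dinner
#' are all flagged as recorded, since a missing flag cannot be distinguished
#' from a skipped meal. Row order is preserved.
#'
#' @param logs Daily-log data.frame with logical `breakfast`, `lunch`,
#'   `dinner` columns.
#' @return The subset of `logs` with all three meal flags TRUE.
#' @export
filter_complete_meal_days <- function(logs) {
  need <- c("breakfast", "lunch", "dinner")
  if (!all(need %in% names(logs))) {
    stop("daily logs must carry breakfast/lunch/dinner flags")
  }
  keep <- logs$breakfast & logs$lunch & logs$dinner
  keep[is.na(keep)] <- FALSE
  logs[keep, , drop = FALSE]
}

#' Average daily logs within the overlapping usage window
#'
#' For each participant, the analysis window is the overlap of the diet and
#' sleep recording periods: days in `[max(start days), min(end days)]` of the
#' two streams. Diet fields are averaged over retained complete-meal days in
#' the window and sleep fields over retained sleep nights; `days_diet` and
#' `days_sleep` record the retained counts. A participant whose streams do
#' not overlap is emitted with zero day counts (and NA averages); the
#' downstream usage filter removes such rows.
#'
#' @param logs Daily-log data.frame as produced by [generate_daily_logs()]
#'   (needs `participant_id`, `day`, meal flags, `diet_recorded`,
#'   `sleep_recorded`, intake and sleep columns).
#' @param demographics Optional data.frame with `participant_id`,
#'   `age_years`, `sex`, `bmi` to merge into the output.
#' @return Participant-level data.frame with the [participant_columns()]
#'   layout (demographic columns NA unless supplied).
#' @export
restrict_overlap_and_average <- function(logs, demographics = NULL) {
  diet_cols <- c("protein_g", "carb_g", "satfat_g", "monofat_g", "polyfat_g",
                 "energy_kcal", "sodium_mg", "potassium_mg", "fiber_g")
  sleep_cols <- c("tst_h", "sl_min", "waso_pct")
  ids <- unique(logs$participant_id)
  rows <- lapply(ids, function(id) {
    li <- logs[logs$participant_id == id, , drop = FALSE]
    diet <- li[li$diet_recorded, , drop = FALSE]
    sleep <- li[li$sleep_recorded, , drop = FALSE]
    if (nrow(diet) == 0 || nrow(sleep) == 0) {
      lo <- 1; hi <- 0
    } else {
      lo <- max(min(diet$day), min(sleep$day))
      hi <- min(max(diet$day), max(sleep$day))
    }
    diet <- filter_complete_meal_days(diet[diet$day >= lo & diet$day <= hi, , drop = FALSE])
    sleep <- sleep[sleep$day >= lo & sleep$day <= hi, , drop = FALSE]
    out <- data.frame(participant_id = id, age_years = NA_real_,
                      sex = NA_character_, bmi = NA_real_,
                      stringsAsFactors = FALSE)
    for (cl in diet_cols) {
      out[[cl]] <- if (nrow(diet) > 0) mean(diet[[cl]]) else NA_real_
    }
    for (cl in sleep_cols) {
      out[[cl]] <- if (nrow(sleep) > 0) mean(sleep[[cl]]) else NA_real_
    }
    out$days_sleep <- nrow(sleep)
    out$days_diet <- nrow(diet)
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(demographics)) {
    m <- match(out$participant_id, demographics$participant_id)
    for (cl in intersect(c("age_years", "sex", "bmi"), names(demographics))) {
      out[[cl]] <- demographics[[cl]][m]
    }
  }
  out[, participant_columns(), drop = FALSE]
}

#' Apply the staged exclusion cascade
#'
#' Removes, in order: (1) rows with a missing sleep summary; (2) rows whose
#' total sleep time falls outside mean +/- `z_cut` sample SDs, with the mean
#' and SD computed once on the post-stage-1 cohort; (3) rows with fewer than
#' `min_days` retained days in either app stream. A ledger records the count
#' removed at each stage; `analyzed + missing_sleep + tst_outliers +
#' short_usage = consented` always holds.
#'
#' @param cohort Participant-level data.frame ([participant_columns()]).
#' @param min_days Minimum retained days required in each stream (default 7).
#' @param z_cut SD multiple for the total-sleep-time outlier band (default 3).
#' @return List with `cohort` (the retained rows) and `ledger` (named counts
#'   `consented`, `missing_sleep`, `tst_outliers`, `short_usage`, `analyzed`).
#' @export
apply_exclusions <- function(cohort, min_days = 7, z_cut = 3) {
  if (min_days < 0 || z_cut < 0) stop("min_days and z_cut must be non-negative")
  consented <- nrow(cohort)

  miss <- is.na(cohort$tst_h) | is.na(cohort$sl_min) | is.na(cohort$waso_pct)
  s1 <- cohort[!miss, , drop = FALSE]

  if (nrow(s1) > 1) {
    m <- mean(s1$tst_h); s <- stats::sd(s1$tst_h)
    outl <- abs(s1$tst_h - m) > z_cut * s
  } else {
    outl <- rep(FALSE, nrow(s1))
  }
  s2 <- s1[!outl, , drop = FALSE]

  short <- s2$days_sleep < min_days | s2$days_diet < min_days
  s3 <- s2[!short, , drop = FALSE]
  rownames(s3) <- NULL

  list(cohort = s3,
       ledger = c(consented = consented,
                  missing_sleep = sum(miss),
                  tst_outliers = sum(outl),
                  short_usage = sum(short),
                  analyzed = nrow(s3)))
}

#' Table-1-style cohort summary
#'
#' Per-variable mean and sample SD (n-1 denominator) overall and by sex, plus
#' sex counts with percentages rounded to one decimal. For a single
#' observation the SD is reported as 0 by convention.
#'
#' @param cohort Non-empty participant-level data.frame.
#' @param variables Numeric columns to summarise (default: all numeric
#'   analysis columns present).
#' @return List with `continuous` (data.frame: variable, group, n, mean, sd)
#'   and `sex` (data.frame: sex, n, pct).
#' @export
cohort_summary <- function(cohort,
                           variables = intersect(setdiff(participant_columns(),
                                                         c("participant_id", "sex")),
                                                 names(cohort))) {
  if (nrow(cohort) == 0) stop("cohort_summary() requires a non-empty cohort")
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  groups <- c(list(all = rep(TRUE, nrow(cohort))),
              lapply(stats::setNames(nm = unique(cohort$sex)),
                     function(s) cohort$sex == s))
  cont <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(names(groups), function(g) {
      x <- cohort[[v]][groups[[g]]]
      x <- x[!is.na(x)]
      data.frame(variable = v, group = g, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x)) sd0(x) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  tab <- table(cohort$sex)
  sex <- data.frame(sex = names(tab), n = as.integer(tab),
                    pct = round(100 * as.integer(tab) / nrow(cohort), 1),
                    stringsAsFactors = FALSE)
  list(continuous = cont, sex = sex)
}
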
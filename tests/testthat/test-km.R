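test_that("km_fit reproduces hand product-limit arithmetic", {
  # no censoring: empirical survival
  f <- km_fit(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(tidy(f)$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(f$median, 2)

  # censoring at 2: S(1) = 2/3, S(3) = (2/3) * (1 - 1/1) = 0, median 3
  f2 <- km_fit(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(tidy(f2)$survival, c(2 / 3, 0))
  expect_equal(f2$median, 3)

  # all censored: survival identically 1, median undefined (not an error)
  f3 <- km_fit(c(4, 5, 6), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(tidy(f3)), 0)
  expect_true(is.na(f3$median))

  expect_error(km_fit(c(-1, 2), c(TRUE, TRUE)), class = "npccdb_validation_error")
  expect_error(km_fit(numeric(0), logical(0)), class = "npccdb_validation_error")
})

test_that("no-censoring limit equals 1 - ECDF at every event time", {
  withr::local_seed(11)
  for (i in 1:20) {
    x <- round(stats::rexp(15, 0.3), 2)
    f <- tidy(km_fit(x, rep(TRUE, 15)))
    ecdf_x <- stats::ecdf(x)
    expect_equal(f$survival, 1 - ecdf_x(f$time), tolerance = 1e-12)
  }
})

test_that("late censored observations perturb risk sets but not event times", {
  x <- c(1, 2, 2, 4, 7)
  obs <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  base <- tidy(km_fit(x, obs))
  ext <- tidy(km_fit(c(x, 99), c(obs, FALSE)))
  # no new event times; curve still a proper survival function
  expect_equal(ext$time, base$time)
  expect_true(all(diff(ext$survival) <= 1e-12))
  expect_equal(ext$n_risk, base$n_risk + 1)
  # moving an already-beyond-all-events censoring time changes nothing
  ext2 <- tidy(km_fit(c(x, 500), c(obs, FALSE)))
  expect_equal(ext2$survival, ext$survival, tolerance = 1e-12)
})

test_that("km_fit agrees with survival::survfit on random censored data", {
  withr::local_seed(13)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    dur <- round(stats::rexp(n, 0.2), 1)
    obs <- stats::runif(n) < 0.7
    if (!any(obs)) obs[1] <- TRUE
    mine <- km_fit(dur, obs)
    sf <- survival::survfit(survival::Surv(dur, obs) ~ 1,
                            conf.type = "log-log")
    sm <- summary(sf, censored = FALSE)
    keep <- sm$n.event > 0
    expect_equal(tidy(mine)$survival, sm$surv[keep], tolerance = 1e-10)
    # survfit reports NaN Greenwood SE once the curve hits zero
    pos <- tidy(mine)$survival > 0
    expect_equal(tidy(mine)$std_err[pos], sm$std.err[keep][pos],
                 tolerance = 1e-8)
    # median per the smallest-t-with-S<=0.5 definition, recomputed from the
    # survfit curve (survfit's table averages times at exact 0.5 crossings)
    hit <- sm$surv[keep] <= 0.5 + 1e-12
    exp_med <- if (any(hit)) min(sm$time[keep][hit]) else NA_real_
    expect_equal(mine$median, exp_med)
    if (!any(abs(c(sm$surv, sm$lower, sm$upper) - 0.5) < 1e-9, na.rm = TRUE)) {
      tab <- summary(sf)$table
      expect_equal(unname(mine$median_ci[1]), unname(tab["0.95LCL"]),
                   tolerance = 1e-10)
      expect_equal(unname(mine$median_ci[2]), unname(tab["0.95UCL"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("median CI contains the median whenever both are defined", {
  withr::local_seed(14)
  for (i in 1:50) {
    n <- sample(8:60, 1)
    dur <- round(stats::rweibull(n, 1.3, 8), 1)
    obs <- stats::runif(n) < 0.75
    f <- km_fit(dur, obs)
    if (!is.na(f$median)) {
      if (!is.na(f$median_ci[1])) expect_lte(f$median_ci[1], f$median)
      if (!is.na(f$median_ci[2])) expect_gte(f$median_ci[2], f$median)
    }
  }
})

test_that("symptom_onset_curve censors non-manifesting patients at last visit", {
  co <- small_generated_cohort(n = 50, seed = 31)
  f <- symptom_onset_curve(co, "cognitive_impairment")
  n_neuro <- sum(!is.na(co$patients$age_at_neuro_onset))
  expect_equal(f$n, n_neuro)
  expect_error(symptom_onset_curve(co, "not_a_symptom"),
               class = "npccdb_validation_error")

  # zero-prevalence symptom: all censored
  co0 <- generate_cohort(generator_config(30, seed = 32, catalog = {
    cat_tbl <- tibble::as_tibble(default_symptom_catalog())
    cat_tbl$prevalence[cat_tbl$symptom_id == "mutism"] <- 0
    symptom_catalog(cat_tbl)
  }))
  f0 <- symptom_onset_curve(co0, "mutism")
  expect_equal(f0$n_events, 0)
  expect_true(is.na(f0$median))
})

test_that("single manifesting patient yields a one-step curve at its duration", {
  co <- cohort(
    patients = tibble::tibble(patient_id = "S", age_at_assessment = 9,
                              age_at_neuro_onset = 2, age_at_diagnosis = 3,
                              age_at_last_visit = 9),
    events = tibble::tibble(patient_id = "S", symptom_id = "ataxia",
                            onset_age = 6),
    catalog = tiny_catalog()
  )
  f <- symptom_onset_curve(co, "ataxia")
  expect_equal(f$median, 4)  # 6 - 2
})

test_that("pre-onset manifestations are clamped to zero with a warning", {
  co <- cohort(
    patients = tibble::tibble(patient_id = c("S", "W"), age_at_assessment = 9,
                              age_at_neuro_onset = c(5, 5),
                              age_at_diagnosis = 6, age_at_last_visit = 9),
    events = tibble::tibble(patient_id = c("S", "W"),
                            symptom_id = "clumsiness",
                            onset_age = c(3, 7)),
    catalog = tiny_catalog()
  )
  expect_warning(f <- symptom_onset_curve(co, "clumsiness"), "clamped")
  expect_equal(tidy(f)$time, c(0, 2))
})

test_that("rank_symptoms orders early cognition/coordination before VSGP/ataxia", {
  co <- generate_cohort(generator_config(400, seed = 33))
  rk <- rank_symptoms(co, min_frequency = 0.4)
  pos <- function(s) which(rk$symptom_id == s)
  expect_true(pos("cognitive_impairment") < pos("vsgp"))
  expect_true(pos("cognitive_impairment") < pos("ataxia"))
  expect_true(pos("clumsiness") < pos("vsgp"))
  # frequencies all strictly above the threshold
  expect_true(all(rk$frequency > 0.4))
  expect_error(rank_symptoms(co, symptom_ids = character()),
               class = "npccdb_validation_error")
})

test_that("rank_symptoms tie-breaks deterministically and honors min_frequency = 1", {
  co <- cohort(
    patients = tibble::tibble(patient_id = c("a", "b"), age_at_assessment = 10,
                              age_at_neuro_onset = 1, age_at_diagnosis = 2,
                              age_at_last_visit = 10),
    events = tibble::tibble(
      patient_id = c("a", "a", "b", "b"),
      symptom_id = c("clumsiness", "ataxia", "clumsiness", "ataxia"),
      onset_age = c(4, 4, 6, 6)
    ),
    catalog = tiny_catalog()
  )
  rk <- rank_symptoms(co, min_frequency = 0)
  # identical medians and frequencies -> alphabetical by id
  expect_equal(rk$symptom_id, c("ataxia", "clumsiness"))
  # a strictly-greater threshold of 1 excludes everything (frequency == 1)
  expect_equal(nrow(rank_symptoms(co, min_frequency = 1)), 0)
})

test_that("onset_relative_to_diagnosis uses the printed sign convention", {
  co <- cohort(
    patients = tibble::tibble(patient_id = c("x", "y"), age_at_assessment = 12,
                              age_at_neuro_onset = 1,
                              age_at_diagnosis = c(6, 5),
                              age_at_last_visit = 12),
    events = tibble::tibble(patient_id = c("x", "y"), symptom_id = "clumsiness",
                            onset_age = c(2, 4)),
    catalog = tiny_catalog()
  )
  d <- onset_relative_to_diagnosis(co, "clumsiness")
  expect_equal(sort(d$deltas[[1]]$delta), c(-4, -1))
  expect_equal(d$mean, -2.5)

  # simultaneity gives a zero delta
  co2 <- tiny_cohort()
  d2 <- onset_relative_to_diagnosis(co2, "ataxia")
  expect_equal(d2$deltas[[1]]$delta, 0)  # onset 5, diagnosis 5
  expect_error(onset_relative_to_diagnosis(co2, "not_a_symptom"),
               class = "npccdb_validation_error")
})
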
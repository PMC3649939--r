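test_that("fisher_exact matches hand-enumerated probabilities", {
  # degenerate margin: single admissible table
  expect_equal(fisher_exact(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)), 1)
  # support probs (1, 16, 36, 16, 1)/70; observed a = 3 -> (16+16+1+1)/70
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 34 / 70,
               tolerance = 1e-12)
  # perfect diagonal: two extreme tables each 1/252
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)), 2 / 252,
               tolerance = 1e-12)
  # C(12, 6) = 924; two extreme tables
  expect_equal(fisher_exact(matrix(c(0, 6, 6, 0), 2, byrow = TRUE)), 2 / 924,
               tolerance = 1e-12)
  expect_error(fisher_exact(matrix(0, 2, 2)), class = "npccdb_validation_error")
  expect_error(fisher_exact(c(1, 2, 3)), class = "npccdb_validation_error")
  expect_error(fisher_exact(c(1, -1, 2, 3)), class = "npccdb_validation_error")
})

test_that("fisher_exact agrees with dhyper enumeration and stats::fisher.test", {
  # exhaustive against the dhyper oracle up to total 16
  for (n_tot in 2:16) {
    for (a in 0:n_tot) for (b in 0:(n_tot - a)) for (c_ in 0:(n_tot - a - b)) {
      d <- n_tot - a - b - c_
      expect_equal(fisher_exact(c(a, b, c_, d)), fisher_oracle(a, b, c_, d),
                   tolerance = 1e-10)
    }
  }
  # spot-check the independent base-R implementation on random tables
  withr::local_seed(51)
  for (i in 1:60) {
    tab <- matrix(stats::rpois(4, 6), 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("seizure association flags engineered acceleration", {
  cfg <- generator_config(
    200, seed = 52,
    progression_mix = c(steady = 0.65, fulminant = 0, accelerated = 0.35),
    seizure_link_prob = 1
  )
  co <- generate_cohort(cfg)
  sa <- seizure_association(co, match_seed = 1)
  expect_lt(sa$p_value, 0.01)
  expect_equal(dim(sa$table), c(2, 2))
  expect_equal(sum(sa$table), nrow(sa$details))
  # seeded matching is reproducible
  sa2 <- seizure_association(co, match_seed = 1)
  expect_identical(sa$table, sa2$table)
  expect_identical(sa$p_value, sa2$p_value)
})

test_that("seizure association requires eligible patients", {
  co <- generate_cohort(generator_config(40, seed = 53, seizure_prevalence = 0))
  expect_error(seizure_association(co), class = "npccdb_validation_error")
})

test_that("screening-index sensitivity splits by disease duration", {
  rub <- risk_index_rubric(c(marker = 80))
  mk <- function(durations, likely) {
    n <- length(durations)
    ids <- sprintf("q%02d", seq_len(n))
    cohort(
      patients = tibble::tibble(
        patient_id = ids, age_at_assessment = 30, age_at_neuro_onset = 10,
        age_at_diagnosis = 10 + durations, age_at_last_visit = 30
      ),
      events = tibble::tibble(patient_id = character(),
                              symptom_id = character(), onset_age = double()),
      catalog = tiny_catalog(),
      risk_answers = tibble::tibble(patient_id = ids, item_id = "marker",
                                    answer = likely)
    )
  }
  # 6 long-duration all likely, 6 short-duration none likely
  co <- mk(c(rep(10, 6), rep(1, 6)), c(rep(TRUE, 6), rep(FALSE, 6)))
  res <- si_sensitivity_vs_duration(co, rub)
  expect_equal(unname(res$table),
               matrix(c(0, 6, 6, 0), 2, byrow = TRUE))
  expect_equal(res$p_value, 2 / 924, tolerance = 1e-12)

  # likely everywhere: no association
  co2 <- mk(c(rep(10, 5), rep(1, 5)), rep(TRUE, 10))
  expect_equal(si_sensitivity_vs_duration(co2, rub)$p_value, 1)

  # single stratum is a precondition failure
  co3 <- mk(rep(10, 6), rep(TRUE, 6))
  expect_error(si_sensitivity_vs_duration(co3, rub),
               class = "npccdb_validation_error")
})

test_that("oxysterol correlation recovers a linear score relationship", {
  n <- 12
  ids <- sprintf("o%02d", seq_len(n))
  score_events <- tibble::tibble(
    patient_id = rep(ids, each = 1),
    symptom_id = "ataxia",
    onset_age = seq(2, 13, length.out = n)
  )
  withr::local_seed(54)
  patients <- tibble::tibble(
    patient_id = ids, age_at_assessment = 20, age_at_neuro_onset = 1,
    age_at_diagnosis = 2, age_at_last_visit = 20
  )
  # raw score at age 15 is 3 for patients whose ataxia onset <= 15 (all)
  # vary scores by stacking clumsiness for half the patients
  extra <- tibble::tibble(patient_id = ids[seq(1, n, 2)],
                          symptom_id = "clumsiness", onset_age = 3)
  events <- rbind(score_events, extra)
  co <- cohort(patients, events, tiny_catalog(),
               oxysterols = NULL)
  sc <- vapply(ids, function(p) score_at_age(co, p, 15), numeric(1))
  oxy <- tibble::tibble(
    patient_id = ids, age = 15,
    triol = 2 * sc + stats::rnorm(n, 0, 0.2),
    seven_kc = 100
  )
  co <- cohort(patients, events, tiny_catalog(), oxysterols = oxy)
  res <- oxysterol_correlation(co)
  tri <- res$fits[res$fits$analyte == "triol", ]
  expect_true(tri$slope_lower <= 2 && 2 <= tri$slope_upper)
  # constant analyte: zero slope, zero R^2
  kc <- res$fits[res$fits$analyte == "seven_kc", ]
  expect_equal(kc$slope, 0, tolerance = 1e-9)
  expect_equal(kc$r_squared, 0)
  # cut-off flags: a triol of 29 (bottom of the healthy-exclusion range)
  # lies above the 24.5 screening cut-off
  oxy29 <- oxy
  oxy29$triol[1] <- 29
  co29 <- cohort(patients, events, tiny_catalog(), oxysterols = oxy29)
  s29 <- oxysterol_correlation(co29)$samples
  expect_true(s29$above_cutoff_triol[s29$triol == 29])
  expect_equal(s29$above_cutoff_triol, s29$triol > 24.5)
})

test_that("oxysterol correlation needs at least three eligible patients", {
  co <- tiny_cohort()
  expect_error(oxysterol_correlation(co), class = "npccdb_validation_error")
})
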
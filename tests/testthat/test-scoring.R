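test_that("scores are hand-checkable sums of manifested severity weights", {
  co <- tiny_cohort()
  expect_equal(compute_score(co, "A", t = 1), 1)
  expect_equal(compute_score(co, "A", t = 3), 4)
  # cleaned variant drops the (contrived) seizure-domain ataxia entry
  co_s <- tiny_cohort(ataxia_seizure = TRUE)
  expect_equal(compute_score(co_s, "A", t = 3, variant = "cleaned"), 1)
  expect_equal(compute_score(co_s, "A", t = 3, variant = "raw"), 4)
})

test_that("a patient without events scores zero at any time", {
  co <- cohort(
    patients = tibble::tibble(patient_id = "E", age_at_assessment = 9,
                              age_at_neuro_onset = 2, age_at_diagnosis = 4,
                              age_at_last_visit = 9),
    events = tibble::tibble(patient_id = character(), symptom_id = character(),
                            onset_age = double()),
    catalog = tiny_catalog()
  )
  expect_equal(compute_score(co, "E", t = 0), 0)
  expect_equal(compute_score(co, "E", t = 7), 0)
})

test_that("scoring refuses undefined anchors and extrapolation", {
  co <- tiny_cohort()
  p <- co$patients
  p$age_at_neuro_onset <- NA_real_
  co_nn <- cohort(p, co$events[0, ], co$catalog)
  expect_error(compute_score(co_nn, "A", t = 1),
               class = "npccdb_validation_error")
  expect_error(compute_score(co, "A", t = 100),
               class = "npccdb_validation_error")
  expect_error(compute_score(co, "A", t = -10),
               class = "npccdb_validation_error")
  expect_error(compute_score(co, "nobody", t = 1),
               class = "npccdb_validation_error")
})

test_that("trajectories sample the score on the annual grid", {
  co <- cohort(
    patients = tibble::tibble(patient_id = "T", age_at_assessment = 8,
                              age_at_neuro_onset = 3, age_at_diagnosis = 4,
                              age_at_last_visit = 8),
    events = tibble::tibble(patient_id = c("T", "T"),
                            symptom_id = c("clumsiness", "ataxia"),
                            onset_age = c(3, 5)),
    catalog = tiny_catalog()
  )
  tr <- score_trajectories(co, grid_step = 1)
  expect_equal(nrow(tr), 6)  # followed 5 years -> t = 0..5
  expect_equal(tr$score, c(1, 1, 4, 4, 4, 4))
  expect_error(score_trajectories(co, grid_step = 0),
               class = "npccdb_validation_error")
})

test_that("score invariants hold across generated patients", {
  co <- small_generated_cohort(n = 60, seed = 21)
  raw <- score_trajectories(co, variant = "raw")
  cleaned <- score_trajectories(co, variant = "cleaned")
  # monotone in t within each patient
  for (d in list(raw, cleaned)) {
    diffs <- d |>
      dplyr::group_by(patient_id) |>
      dplyr::summarise(ok = all(diff(score) >= -1e-12), .groups = "drop")
    expect_true(all(diffs$ok))
  }
  # cleaned dominated by raw, equal iff no seizure-domain symptom manifested
  merged <- dplyr::left_join(raw, cleaned, by = c("patient_id", "t"),
                             suffix = c("_raw", "_cln"))
  expect_true(all(merged$score_cln <= merged$score_raw + 1e-12))
  seiz <- co$patients$patient_id[!is.na(co$patients$first_seizure_age)]
  no_seiz <- merged[!merged$patient_id %in% seiz, ]
  expect_equal(no_seiz$score_cln, no_seiz$score_raw)
  # additivity over a catalog partition
  cat_tbl <- tibble::as_tibble(co$catalog)
  half <- seq_len(nrow(cat_tbl)) %% 2 == 0
  co_a <- co
  co_a$catalog <- symptom_catalog(cat_tbl[half, ])
  co_a$events <- co$events[co$events$symptom_id %in% cat_tbl$symptom_id[half], ]
  co_b <- co
  co_b$catalog <- symptom_catalog(cat_tbl[!half, ])
  co_b$events <- co$events[co$events$symptom_id %in% cat_tbl$symptom_id[!half], ]
  pid <- co$patients$patient_id[!is.na(co$patients$age_at_neuro_onset)][1]
  for (t in c(0, 2, 5)) {
    expect_equal(compute_score(co, pid, t),
                 compute_score(co_a, pid, t) + compute_score(co_b, pid, t))
  }
})

test_that("risk index totals and categories follow the rubric thresholds", {
  rub <- risk_index_rubric(c(a = 40, b = 35))
  mk <- function(answers) {
    cohort(
      patients = tibble::tibble(patient_id = "R", age_at_assessment = 5,
                                age_at_diagnosis = 3, age_at_last_visit = 5),
      events = tibble::tibble(patient_id = character(),
                              symptom_id = character(), onset_age = double()),
      catalog = tiny_catalog(),
      risk_answers = answers
    )
  }
  none <- evaluate_risk_index(mk(NULL), rub)
  expect_equal(none$total, 0)
  expect_equal(none$category, "unlikely")

  both <- evaluate_risk_index(
    mk(tibble::tibble(patient_id = "R", item_id = c("a", "b"), answer = TRUE)),
    rub
  )
  expect_equal(both$total, 75)
  expect_equal(both$category, "likely")

  # 40 falls in the inclusive follow-up band
  only_a <- evaluate_risk_index(
    mk(tibble::tibble(patient_id = "R", item_id = "a", answer = TRUE)),
    risk_index_rubric(c(a = 40))
  )
  expect_equal(only_a$total, 40)
  expect_equal(only_a$category, "followup")

  # category is a step function with breaks exactly at the thresholds
  totals <- c(0, 39.99, 40, 69.99, 70, 200)
  cats <- npccdb:::risk_category(totals, rub)
  expect_equal(cats, c("unlikely", "unlikely", "followup", "followup",
                       "likely", "likely"))
})
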
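#' NPC-cdb composite score of one patient at a time point
#'
#' The NPC-cdb score at disease time `t` (years after neurological onset) is
#' the sum of the severity weights of all catalog symptoms that have
#' manifested by absolute age `age_at_neuro_onset + t`: each past or current
#' symptom contributes its weight once, as a summand, and persists. The
#' `cleaned` variant excludes seizure-domain symptoms, removing
#' seizure-associated score points.
#'
#' @param cohort An `npc_cohort`.
#' @param patient_id Patient to score.
#' @param t Time in years relative to neurological onset. Must satisfy
#'   `t >= -age_at_neuro_onset` (absolute age >= 0) and not extend beyond the
#'   last visit (no extrapolation).
#' @param variant `"raw"` or `"cleaned"`.
#' @return A single non-negative score.
#' @export
compute_score <- function(cohort, patient_id, t, variant = c("raw", "cleaned")) {
  variant <- arg_match(variant)
  p <- cohort$patients[cohort$patients$patient_id == patient_id, ]
  if (nrow(p) == 0) {
    abort_npc(paste0("unknown patient_id: ", patient_id), "npccdb_validation_error")
  }
  if (is.na(p$age_at_neuro_onset)) {
    abort_npc(paste0("patient ", patient_id, " has no neurological onset; ",
                     "onset-relative scoring is undefined (score at absolute ",
                     "ages via score_at_age())"),
              "npccdb_validation_error")
  }
  stopifnot_scalar_number(t, "t")
  if (t < -p$age_at_neuro_onset - 1e-9) {
    abort_npc("t implies a negative absolute age", "npccdb_validation_error")
  }
  age <- p$age_at_neuro_onset + t
  if (age > p$age_at_last_visit + 1e-9) {
    abort_npc("t lies beyond the last visit; scores are not extrapolated",
              "npccdb_validation_error")
  }
  score_at_age(cohort, patient_id, age, variant)
}

#' NPC-cdb score at an absolute age
#'
#' Absolute-age companion to [compute_score()]; usable also for patients
#' without a neurological onset anchor.
#'
#' @inheritParams compute_score
#' @param age Absolute age in years (0 to the patient's last visit).
#' @return A single non-negative score.
#' @export
score_at_age <- function(cohort, patient_id, age, variant = c("raw", "cleaned")) {
  variant <- arg_match(variant)
  stopifnot_scalar_number(age, "age", min = 0)
  ev <- cohort$events[cohort$events$patient_id == patient_id, ]
  if (nrow(ev) == 0) return(0)
  w <- scoring_weights(cohort$catalog, variant)
  sum(w[ev$symptom_id[ev$onset_age <= age + 1e-9]], na.rm = TRUE)
}

scoring_weights <- function(catalog, variant) {
  w <- setNames(catalog$severity_weight, catalog$symptom_id)
  if (variant == "cleaned") w[catalog$seizure_domain] <- 0
  w
}

#' Annual (or finer) NPC-cdb score trajectories
#'
#' Samples each eligible patient's score on a regular grid of disease time
#' `t = 0, grid_step, ...` up to `age_at_last_visit - age_at_neuro_onset`,
#' normalized so `t = 0` is the neurological onset. Patients without a
#' neurological onset are skipped (they have no `t = 0` anchor).
#'
#' @inheritParams compute_score
#' @param grid_step Grid spacing in years (default 1: annual scores).
#' @param patients Optional character vector restricting the patients scored.
#' @return A tibble `patient_id`, `t`, `score`, `variant`; scores are
#'   non-decreasing in `t` within a patient.
#' @export
score_trajectories <- function(cohort, grid_step = 1, variant = c("raw", "cleaned"),
                               patients = NULL) {
  variant <- arg_match(variant)
  if (!is.numeric(grid_step) || length(grid_step) != 1 || grid_step <= 0) {
    abort_npc("grid_step must be > 0", "npccdb_validation_error")
  }
  pts <- neuro_patients(cohort)
  if (!is.null(patients)) pts <- pts[pts$patient_id %in% patients, ]
  if (nrow(pts) == 0) {
    abort_npc("no patients with a neurological onset to build trajectories for",
              "npccdb_validation_error")
  }
  w <- scoring_weights(cohort$catalog, variant)
  ev <- cohort$events
  purrr::map(seq_len(nrow(pts)), function(i) {
    pid <- pts$patient_id[i]
    onset <- pts$age_at_neuro_onset[i]
    horizon <- pts$age_at_last_visit[i] - onset
    grid <- seq(0, horizon, by = grid_step)
    e <- ev[ev$patient_id == pid, ]
    rel <- e$onset_age - onset
    wts <- unname(w[e$symptom_id])
    score <- map_dbl(grid, function(t) sum(wts[rel <= t + 1e-9]))
    tibble(patient_id = pid, t = grid, score = score, variant = variant)
  }) |> list_rbind()
}

#' Evaluate a risk-index rubric over a cohort
#'
#' Sums each patient's points over rubric items answered `TRUE` (a missing
#' answer counts as `FALSE`) and assigns the screening category:
#' `unlikely` (total below the follow-up threshold), `followup` (from the
#' follow-up threshold up to, but excluding, the likely threshold), or
#' `likely`. With the default thresholds this is the published <40 / 40--69 /
#' >=70 categorization.
#'
#' @param cohort An `npc_cohort` with `risk_answers`.
#' @param rubric An [risk_index_rubric()].
#' @return A tibble `patient_id`, `total`, `category`.
#' @export
evaluate_risk_index <- function(cohort, rubric = default_risk_rubric()) {
  if (!inherits(rubric, "npc_rubric")) {
    abort_npc("rubric must come from risk_index_rubric()", "npccdb_validation_error")
  }
  ans <- cohort$risk_answers |> filter(.data$item_id %in% names(rubric$items))
  totals <- ans |>
    filter(.data$answer) |>
    mutate(points = rubric$items[.data$item_id]) |>
    group_by(.data$patient_id) |>
    summarise(total = sum(.data$points), .groups = "drop")
  out <- tibble(patient_id = cohort$patients$patient_id) |>
    left_join(totals, by = "patient_id") |>
    mutate(total = dplyr::coalesce(.data$total, 0))
  out$category <- risk_category(out$total, rubric)
  out
}

risk_category <- function(total, rubric) {
  dplyr::case_when(
    total >= rubric$threshold_likely ~ "likely",
    total >= rubric$threshold_followup ~ "followup",
    TRUE ~ "unlikely"
  )
}
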
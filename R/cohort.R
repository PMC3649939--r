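#' Construct and validate a cohort
#'
#' A cohort bundles registry-style longitudinal patient data with the symptom
#' catalog its events are scored against:
#'
#' * `patients` — one row per patient: `patient_id`, optional `sex`,
#'   `age_at_assessment`, `age_at_neuro_onset` (NA for patients diagnosed
#'   before any neurological sign), `age_at_diagnosis`, `age_at_last_visit`
#'   (the censoring anchor), `deceased`, `first_seizure_age`,
#'   `filipin_pattern` (`classic`/`variant`/`indifferent`/`not_done`),
#'   `alleles_identified` (0--2), `allele_types` (list column, one type per
#'   identified mutant allele), `sibling_group`.
#' * `events` — long table of first symptom manifestations:
#'   `patient_id`, `symptom_id`, `onset_age` (decimal years). A symptom
#'   appears at most once per patient and persists thereafter.
#' * `oxysterols` — optional plasma samples: `patient_id`, `age`, `triol`,
#'   `seven_kc` (ng/mL).
#' * `risk_answers` — optional long table of risk-index item answers:
#'   `patient_id`, `item_id`, `answer`.
#'
#' All ages are decimal years; no calendar dates are modelled.
#'
#' @param patients,events,oxysterols,risk_answers Data frames as above.
#' @param catalog An `npc_catalog` resolving every event's `symptom_id`.
#' @param provenance Free-form list (file source, or generator config/seed and
#'   simulation truths for synthetic cohorts).
#' @return A validated list of class `npc_cohort`.
#' @export
cohort <- function(patients, events, catalog,
                   oxysterols = NULL, risk_answers = NULL,
                   provenance = list()) {
  patients <- normalize_patients(as_tibble(patients))
  events <- normalize_events(as_tibble(events))
  oxy <- if (is.null(oxysterols)) {
    tibble(patient_id = character(), age = double(),
           triol = double(), seven_kc = double())
  } else as_tibble(oxysterols)
  ans <- if (is.null(risk_answers)) {
    tibble(patient_id = character(), item_id = character(), answer = logical())
  } else as_tibble(risk_answers)
  x <- structure(
    list(patients = patients, events = events, oxysterols = oxy,
         risk_answers = ans, catalog = catalog, provenance = provenance),
    class = "npc_cohort"
  )
  validate_cohort(x)
}

normalize_patients <- function(p) {
  defaults <- list(
    sex = NA_character_, age_at_neuro_onset = NA_real_,
    first_seizure_age = NA_real_, filipin_pattern = "not_done",
    alleles_identified = 0L, sibling_group = NA_character_,
    deceased = FALSE
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(p)) p[[nm]] <- defaults[[nm]]
  }
  if (!"allele_types" %in% names(p)) {
    p$allele_types <- purrr::map(seq_len(nrow(p)), function(i) character())
  }
  p$patient_id <- as.character(p$patient_id)
  p$sex <- as.character(p$sex)
  p$sibling_group <- as.character(p$sibling_group)
  p$deceased <- as.logical(p$deceased)
  p$filipin_pattern <- dplyr::coalesce(as.character(p$filipin_pattern), "not_done")
  p$alleles_identified <- as.integer(p$alleles_identified)
  num_cols <- c("age_at_assessment", "age_at_neuro_onset", "age_at_diagnosis",
                "age_at_last_visit", "first_seizure_age")
  for (nm in num_cols) p[[nm]] <- as.numeric(p[[nm]])
  p
}

normalize_events <- function(e) {
  if (nrow(e) == 0) {
    return(tibble(patient_id = character(), symptom_id = character(),
                  onset_age = double()))
  }
  tibble(patient_id = as.character(e$patient_id),
         symptom_id = as.character(e$symptom_id),
         onset_age = as.numeric(e$onset_age))
}

#' Validate a cohort's invariants
#'
#' Checks id uniqueness, catalog resolution of every event, age consistency
#' (all event onsets within `[0, age_at_last_visit]`), the first-seizure
#' anchor (equal to the earliest seizure-domain event onset when present),
#' allele bookkeeping and filipin codes. Violations raise a typed
#' `npccdb_validation_error` naming the patient and field; nothing is
#' silently coerced.
#'
#' @param x An `npc_cohort`.
#' @return `x`, invisibly usable (returned on success).
#' @export
validate_cohort <- function(x) {
  p <- x$patients
  e <- x$events
  if (nrow(p) == 0) {
    abort_npc("cohort has no patients", "npccdb_validation_error")
  }
  dup <- p$patient_id[duplicated(p$patient_id)]
  if (length(dup) > 0) {
    abort_npc(paste0("duplicate patient_id: ", paste(unique(dup), collapse = ", ")),
              "npccdb_validation_error")
  }
  required_age <- c("age_at_assessment", "age_at_diagnosis", "age_at_last_visit")
  for (nm in required_age) {
    bad <- p$patient_id[is.na(p[[nm]]) | p[[nm]] < 0]
    if (length(bad) > 0) {
      abort_npc(paste0("field `", nm, "` missing or negative for patient(s): ",
                       paste(head(bad, 5), collapse = ", ")),
                "npccdb_validation_error")
    }
  }
  bad_alleles <- p$patient_id[!p$alleles_identified %in% 0:2]
  if (length(bad_alleles) > 0) {
    abort_npc(paste0("alleles_identified must be 0, 1 or 2 for patient(s): ",
                     paste(bad_alleles, collapse = ", ")),
              "npccdb_validation_error")
  }
  n_types <- vapply(p$allele_types, length, integer(1))
  bad_types <- p$patient_id[n_types > 2]
  if (length(bad_types) > 0) {
    abort_npc(paste0("allele_types may hold at most 2 entries per patient: ",
                     paste(bad_types, collapse = ", ")),
              "npccdb_validation_error")
  }
  ok_filipin <- c("classic", "variant", "indifferent", "not_done")
  bad_fil <- p$patient_id[!p$filipin_pattern %in% ok_filipin]
  if (length(bad_fil) > 0) {
    abort_npc(paste0("filipin_pattern must be one of ",
                     paste(ok_filipin, collapse = "/"), " for: ",
                     paste(bad_fil, collapse = ", ")),
              "npccdb_validation_error")
  }
  if (nrow(e) > 0) {
    unknown <- setdiff(unique(e$symptom_id), x$catalog$symptom_id)
    if (length(unknown) > 0) {
      abort_npc(paste0("events reference symptom_id(s) absent from catalog: ",
                       paste(unknown, collapse = ", ")),
                "npccdb_validation_error")
    }
    orphan <- setdiff(unique(e$patient_id), p$patient_id)
    if (length(orphan) > 0) {
      abort_npc(paste0("events reference unknown patient_id(s): ",
                       paste(orphan, collapse = ", ")),
                "npccdb_validation_error")
    }
    dup_ev <- e[duplicated(e[c("patient_id", "symptom_id")]), ]
    if (nrow(dup_ev) > 0) {
      abort_npc(paste0("symptom recorded more than once for patient(s): ",
                       paste(unique(dup_ev$patient_id), collapse = ", ")),
                "npccdb_validation_error")
    }
    if (any(is.na(e$onset_age) | e$onset_age < 0)) {
      bad <- unique(e$patient_id[is.na(e$onset_age) | e$onset_age < 0])
      abort_npc(paste0("event onset_age missing or negative for patient(s): ",
                       paste(bad, collapse = ", ")),
                "npccdb_validation_error")
    }
    last_visit <- setNames(p$age_at_last_visit, p$patient_id)
    over <- e$onset_age > last_visit[e$patient_id] + 1e-9
    if (any(over)) {
      abort_npc(paste0("event onset after age_at_last_visit for patient(s): ",
                       paste(unique(e$patient_id[over]), collapse = ", ")),
                "npccdb_validation_error")
    }
    # first_seizure_age must anchor to the earliest seizure-domain event
    seiz_ids <- x$catalog$symptom_id[x$catalog$seizure_domain]
    se <- e[e$symptom_id %in% seiz_ids, ]
    fs <- setNames(rep(NA_real_, nrow(p)), p$patient_id)
    if (nrow(se) > 0) {
      first_seiz <- tapply(se$onset_age, se$patient_id, min)
      fs[names(first_seiz)] <- unname(first_seiz)
    }
    declared <- p$first_seizure_age
    mismatch <- !is.na(declared) &
      (is.na(fs[p$patient_id]) | abs(declared - fs[p$patient_id]) > 1e-9)
    if (any(mismatch)) {
      abort_npc(paste0("first_seizure_age does not match earliest seizure-domain ",
                       "event for patient(s): ",
                       paste(p$patient_id[mismatch], collapse = ", ")),
                "npccdb_validation_error")
    }
  }
  x
}

#' @export
print.npc_cohort <- function(x, ...) {
  n_neuro <- sum(!is.na(x$patients$age_at_neuro_onset))
  cat(sprintf("<npc_cohort> %d patients (%d with neurological onset), %d events\n",
              nrow(x$patients), n_neuro, nrow(x$events)))
  src <- x$provenance$source %||% x$provenance$generator %||% NULL
  if (!is.null(src)) cat("  provenance:", src, "\n")
  invisible(x)
}

# patients with a usable neurological onset (the t = 0 anchor)
neuro_patients <- function(cohort) {
  filter(cohort$patients, !is.na(.data$age_at_neuro_onset))
}
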
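#' Read a cohort from CSV tables or a JSON document
#'
#' CSV format: `path` is a directory holding `patients.csv` and a long-format
#' `events.csv` keyed by `(patient_id, symptom_id)`, plus optional
#' `oxysterols.csv` and `risk_answers.csv`. `allele_types` is stored
#' semicolon-joined. JSON format: `path` is a single nested document with a
#' `patients` array in which each record embeds its `events`,
#' `oxysterol_samples` and `risk_index_answers`.
#'
#' All invariants are checked on read; schema violations raise typed errors
#' naming the offending patient and field.
#'
#' @param path Directory (CSV) or file (JSON).
#' @param format `"csv"` or `"json"`.
#' @param catalog Symptom catalog used to resolve event ids
#'   (default [default_symptom_catalog()]).
#' @return A validated `npc_cohort`.
#' @export
read_cohort <- function(path, format = c("csv", "json"),
                        catalog = default_symptom_catalog()) {
  format <- arg_match(format)
  if (format == "csv") read_cohort_csv(path, catalog) else read_cohort_json(path, catalog)
}

read_cohort_csv <- function(dir, catalog) {
  pfile <- file.path(dir, "patients.csv")
  efile <- file.path(dir, "events.csv")
  if (!file.exists(pfile) || !file.exists(efile)) {
    abort_npc(paste0("expected patients.csv and events.csv under ", dir),
              "npccdb_io_error")
  }
  p <- readr::read_csv(pfile, show_col_types = FALSE)
  p$allele_types <- parse_allele_types(p$allele_types %||% rep("", nrow(p)))
  e <- readr::read_csv(efile, show_col_types = FALSE)
  oxy <- NULL
  if (file.exists(file.path(dir, "oxysterols.csv"))) {
    oxy <- readr::read_csv(file.path(dir, "oxysterols.csv"), show_col_types = FALSE)
  }
  ans <- NULL
  if (file.exists(file.path(dir, "risk_answers.csv"))) {
    ans <- readr::read_csv(file.path(dir, "risk_answers.csv"), show_col_types = FALSE)
  }
  cohort(p, e, catalog, oxysterols = oxy, risk_answers = ans,
         provenance = list(source = dir))
}

parse_allele_types <- function(x) {
  purrr::map(as.character(x), function(s) {
    if (is.na(s) || s == "") character() else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

read_cohort_json <- function(file, catalog) {
  if (!file.exists(file)) {
    abort_npc(paste0("file not found: ", file), "npccdb_io_error")
  }
  doc <- jsonlite::read_json(file, simplifyVector = FALSE)
  if (is.null(doc$patients)) {
    abort_npc("JSON cohort document has no `patients` array", "npccdb_io_error")
  }
  scal <- function(x, cast) if (is.null(x)) cast(NA) else cast(x)
  recs <- purrr::map(doc$patients, function(r) {
    tibble(
      patient_id = as.character(r$patient_id),
      sex = scal(r$sex, as.character),
      age_at_assessment = scal(r$age_at_assessment, as.numeric),
      age_at_neuro_onset = scal(r$age_at_neuro_onset, as.numeric),
      age_at_diagnosis = scal(r$age_at_diagnosis, as.numeric),
      age_at_last_visit = scal(r$age_at_last_visit, as.numeric),
      deceased = isTRUE(r$deceased),
      first_seizure_age = scal(r$first_seizure_age, as.numeric),
      filipin_pattern = scal(r$filipin_pattern, as.character),
      alleles_identified = scal(r$alleles_identified %||% 0L, as.integer),
      allele_types = list(as.character(unlist(r$allele_types %||% list()))),
      sibling_group = scal(r$sibling_group, as.character)
    )
  }) |> list_rbind()
  events <- purrr::map(doc$patients, function(r) {
    if (length(r$events) == 0) return(NULL)
    tibble(
      patient_id = as.character(r$patient_id),
      symptom_id = map_chr(r$events, ~ as.character(.x$symptom_id)),
      onset_age = map_dbl(r$events, ~ as.numeric(.x$onset_age))
    )
  }) |> list_rbind()
  oxy <- purrr::map(doc$patients, function(r) {
    if (length(r$oxysterol_samples) == 0) return(NULL)
    tibble(
      patient_id = as.character(r$patient_id),
      age = map_dbl(r$oxysterol_samples, ~ as.numeric(.x$age)),
      triol = map_dbl(r$oxysterol_samples, ~ as.numeric(.x$triol)),
      seven_kc = map_dbl(r$oxysterol_samples, ~ as.numeric(.x$seven_kc))
    )
  }) |> list_rbind()
  ans <- purrr::map(doc$patients, function(r) {
    a <- r$risk_index_answers
    if (length(a) == 0) return(NULL)
    tibble(patient_id = as.character(r$patient_id),
           item_id = names(a),
           answer = map_lgl(a, isTRUE))
  }) |> list_rbind()
  cohort(recs, events %||% tibble(), catalog,
         oxysterols = oxy, risk_answers = ans,
         provenance = list(source = file))
}

#' Write a cohort to CSV tables or a JSON document
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, ...))` returns a
#' cohort equal to `x` up to field order. Generator provenance (simulation
#' truths) is not serialized; a re-read cohort is treated as imported data.
#'
#' @param x An `npc_cohort`.
#' @param path Output directory (CSV) or file (JSON).
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, format = c("csv", "json")) {
  format <- arg_match(format)
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    p <- x$patients
    p$allele_types <- map_chr(p$allele_types, paste, collapse = ";")
    readr::write_csv(p, file.path(path, "patients.csv"), na = "")
    readr::write_csv(x$events, file.path(path, "events.csv"), na = "")
    if (nrow(x$oxysterols) > 0) {
      readr::write_csv(x$oxysterols, file.path(path, "oxysterols.csv"), na = "")
    }
    if (nrow(x$risk_answers) > 0) {
      readr::write_csv(x$risk_answers, file.path(path, "risk_answers.csv"), na = "")
    }
  } else {
    ev <- split(x$events, x$events$patient_id)
    ox <- split(x$oxysterols, x$oxysterols$patient_id)
    an <- split(x$risk_answers, x$risk_answers$patient_id)
    patients <- purrr::map(seq_len(nrow(x$patients)), function(i) {
      r <- as.list(x$patients[i, ])
      pid <- r$patient_id
      rec <- list(
        patient_id = pid,
        sex = r$sex,
        age_at_assessment = r$age_at_assessment,
        age_at_neuro_onset = r$age_at_neuro_onset,
        age_at_diagnosis = r$age_at_diagnosis,
        age_at_last_visit = r$age_at_last_visit,
        deceased = r$deceased,
        first_seizure_age = r$first_seizure_age,
        filipin_pattern = r$filipin_pattern,
        alleles_identified = r$alleles_identified,
        allele_types = r$allele_types[[1]],
        sibling_group = r$sibling_group
      )
      e <- ev[[pid]]
      if (!is.null(e) && nrow(e) > 0) {
        rec$events <- purrr::map(seq_len(nrow(e)), function(j) {
          list(symptom_id = e$symptom_id[j], onset_age = e$onset_age[j])
        })
      }
      o <- ox[[pid]]
      if (!is.null(o) && nrow(o) > 0) {
        rec$oxysterol_samples <- purrr::map(seq_len(nrow(o)), function(j) {
          list(age = o$age[j], triol = o$triol[j], seven_kc = o$seven_kc[j])
        })
      }
      a <- an[[pid]]
      if (!is.null(a) && nrow(a) > 0) {
        rec$risk_index_answers <- as.list(setNames(a$answer, a$item_id))
      }
      rec
    })
    jsonlite::write_json(list(patients = patients), path,
                         auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  invisible(path)
}
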
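#' Synthetic fixture cohort encoding published diagnostic marginals
#'
#' Builds a fully synthetic 42-patient cohort whose marginal counts equal the
#' published diagnostic-findings figures of the German-Swiss NP-C cohort:
#' 26 filipin-tested patients (17 classic, 8 variant, 1 indifferent), 36
#' patients with both mutant alleles identified, an 80-allele type breakdown
#' (62 missense, 2 splicing, 5 stop, 9 deletions, 2 insertions), 18 patients
#' with prolonged neonatal jaundice, 9 with isolated neonatal organomegaly,
#' 38 with splenomegaly, 38 with neurological involvement, and risk-index
#' categories 30 likely / 7 follow-up / 5 unlikely. Individual patient
#' records are placeholders; only the marginals are meaningful. Note the
#' published allele marginals are not jointly consistent at patient level
#' (77 identified vs 80 typed alleles); the fixture carries both as printed.
#'
#' @return An `npc_cohort` of 42 synthetic patients.
#' @export
marginals_fixture_cohort <- function() {
  n <- 42
  pid <- sprintf("F%02d", seq_len(n))
  neuro <- seq_len(38)                      # patients with neurological onset
  onset <- rep(NA_real_, n)
  onset[neuro] <- 5 + 0.1 * neuro
  diagnosis <- ifelse(is.na(onset), 1, onset + 4)
  last_visit <- diagnosis + 2

  filipin <- rep("not_done", n)
  filipin[1:17] <- "classic"
  filipin[18:25] <- "variant"
  filipin[26] <- "indifferent"

  alleles_identified <- c(rep(2L, 36), rep(1L, 5), 0L)
  type_pool <- c(rep("missense", 62), rep("splicing", 2), rep("nonsense", 5),
                 rep("deletion", 9), rep("insertion", 2))
  # 80 typed alleles over 42 patients: two for the first 38, one for the rest
  allele_types <- vector("list", n)
  k <- 0
  for (i in seq_len(n)) {
    take <- if (i <= 38) 2 else 1
    allele_types[[i]] <- type_pool[(k + 1):(k + take)]
    k <- k + take
  }

  patients <- tibble(
    patient_id = pid,
    sex = rep(c("F", "M"), length.out = n),
    age_at_assessment = last_visit,
    age_at_neuro_onset = onset,
    age_at_diagnosis = diagnosis,
    age_at_last_visit = last_visit,
    deceased = FALSE,
    first_seizure_age = NA_real_,
    filipin_pattern = filipin,
    alleles_identified = alleles_identified,
    allele_types = allele_types,
    sibling_group = NA_character_
  )

  events <- bind_rows(
    tibble(patient_id = pid[neuro], symptom_id = "splenomegaly", onset_age = 0.5),
    tibble(patient_id = pid[1:18], symptom_id = "neonatal_jaundice", onset_age = 0.1),
    tibble(patient_id = pid[1:9], symptom_id = "isolated_organomegaly", onset_age = 0.3)
  )

  # risk-index answers yielding 30 likely / 7 follow-up / 5 unlikely totals
  # under the default rubric (70, 40 and 0 points respectively)
  likely_items <- c("vsgp", "splenomegaly", "cognitive_impairment")
  answers <- bind_rows(
    tidyr::expand_grid(patient_id = pid[1:30], item_id = likely_items) |>
      mutate(answer = TRUE),
    tibble(patient_id = pid[31:37], item_id = "vsgp", answer = TRUE)
  )

  cohort(patients, events, default_symptom_catalog(),
         risk_answers = answers,
         provenance = list(source = "synthetic printed-marginals fixture"))
}
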
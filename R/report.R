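#' Integer percentage with half-away-from-zero rounding
#'
#' `round(100 * numerator / denominator)` with halves rounded away from zero
#' — the convention that reproduces published registry percentages (62 of 80
#' is 77.5 and prints as 78). Vectorized.
#'
#' @param numerator Non-negative integer count(s), at most `denominator`.
#' @param denominator Positive integer denominator(s).
#' @return Integer percentage(s).
#' @export
#' @examples
#' percent(62, 80)  # 78
#' percent(17, 26)  # 65
percent <- function(numerator, denominator) {
  if (any(denominator == 0)) {
    abort_npc("denominator must be positive", "npccdb_validation_error")
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    abort_npc("numerator must lie in [0, denominator]", "npccdb_validation_error")
  }
  as.integer(round_half_up(100 * numerator / denominator))
}

#' Descriptive cohort summary with counts and integer percentages
#'
#' Computes the diagnostic-findings layer of a cohort report: filipin
#' testing outcomes (percentages over tested patients), molecular findings
#' (patients with both alleles identified over all patients; allele-type
#' breakdown over all identified mutant alleles), neonatal/visceral history
#' and neurological involvement (over all patients), seizure prevalence,
#' risk-index category counts (when a rubric is given), and the
#' diagnostic-delay mean and SD over patients with a neurological onset.
#' Fields whose denominator is empty (e.g. filipin percentages in a cohort
#' without filipin testing) are reported with `NA` percentages, never by
#' dividing by zero.
#'
#' @param cohort An `npc_cohort`.
#' @param rubric Optional [risk_index_rubric()] for the category counts.
#' @return A list of class `npc_summary`: `counts` (tibble `metric`, `count`,
#'   `denominator`, `percent`), `delay_mean`, `delay_sd`, `n_patients`.
#' @export
cohort_summary <- function(cohort, rubric = NULL) {
  p <- cohort$patients
  n <- nrow(p)
  if (n == 0) abort_npc("empty cohort", "npccdb_validation_error")
  has_event <- function(sid) {
    length(unique(cohort$events$patient_id[cohort$events$symptom_id == sid]))
  }
  pct_or_na <- function(count, denom) {
    if (denom == 0) NA_integer_ else percent(count, denom)
  }
  tested <- sum(p$filipin_pattern != "not_done")
  types <- unlist(p$allele_types)
  alleles_total <- length(types)
  row <- function(metric, count, denom) {
    tibble(metric = metric, count = count, denominator = denom,
           percent = pct_or_na(count, denom))
  }
  counts <- bind_rows(
    row("filipin_tested", tested, n),
    row("filipin_classic", sum(p$filipin_pattern == "classic"), tested),
    row("filipin_variant", sum(p$filipin_pattern == "variant"), tested),
    row("filipin_indifferent", sum(p$filipin_pattern == "indifferent"), tested),
    row("two_alleles_identified", sum(p$alleles_identified == 2), n),
    row("alleles_missense", sum(types == "missense"), alleles_total),
    row("alleles_splicing", sum(types == "splicing"), alleles_total),
    row("alleles_nonsense", sum(types == "nonsense"), alleles_total),
    row("alleles_deletion", sum(types == "deletion"), alleles_total),
    row("alleles_insertion", sum(types == "insertion"), alleles_total),
    row("neonatal_jaundice", has_event("neonatal_jaundice"), n),
    row("isolated_organomegaly", has_event("isolated_organomegaly"), n),
    row("splenomegaly", has_event("splenomegaly"), n),
    row("neurological_involvement", sum(!is.na(p$age_at_neuro_onset)), n),
    row("seizures", sum(!is.na(p$first_seizure_age)), n)
  )
  if (!is.null(rubric)) {
    ri <- evaluate_risk_index(cohort, rubric)
    counts <- bind_rows(
      counts,
      row("risk_index_likely", sum(ri$category == "likely"), n),
      row("risk_index_followup", sum(ri$category == "followup"), n),
      row("risk_index_unlikely", sum(ri$category == "unlikely"), n)
    )
  }
  delay <- p$age_at_diagnosis - p$age_at_neuro_onset
  delay <- delay[!is.na(delay)]
  structure(
    list(counts = counts,
         delay_mean = if (length(delay) > 0) mean(delay) else NA_real_,
         delay_sd = if (length(delay) > 1) sd(delay) else NA_real_,
         n_patients = n),
    class = "npc_summary"
  )
}

#' @export
print.npc_summary <- function(x, ...) {
  cat(sprintf("<npc_summary> %d patients; diagnostic delay %.1f +/- %.1f y\n",
              x$n_patients, x$delay_mean, x$delay_sd))
  print(x$counts, n = nrow(x$counts))
  invisible(x)
}

#' @method tidy npc_summary
#' @export
tidy.npc_summary <- function(x, ...) x$counts
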
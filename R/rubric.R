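#' Construct a risk-index rubric
#'
#' A rubric is a Suspicion-Index-style screening instrument: a set of items
#' each worth a number of points, plus two category thresholds. A patient's
#' total is the sum of the points of the items answered `TRUE`; the category
#' is `unlikely` below the follow-up threshold, `followup` from there up to
#' (but excluding) the likely threshold, and `likely` at or above it.
#'
#' The published Suspicion Index item weights are treated as a user-supplied
#' rubric; [default_risk_rubric()] ships a synthetic stand-in whose item ids
#' match default catalog symptom ids so answers can be derived from a
#' patient's manifested symptoms.
#'
#' @param items Named numeric vector (or data frame with `item_id`, `points`)
#'   of item point values.
#' @param threshold_followup,threshold_likely Category thresholds
#'   (defaults 40 and 70; must satisfy `threshold_followup < threshold_likely`).
#' @return A list of class `npc_rubric`.
#' @export
risk_index_rubric <- function(items, threshold_followup = 40, threshold_likely = 70) {
  if (is.data.frame(items)) {
    items <- setNames(as.numeric(items$points), items$item_id)
  }
  if (length(items) == 0) {
    abort_npc("rubric must contain at least one item", "npccdb_validation_error")
  }
  if (is.null(names(items)) || any(names(items) == "") || anyDuplicated(names(items))) {
    abort_npc("rubric items must have unique names", "npccdb_validation_error")
  }
  if (!is.numeric(threshold_followup) || !is.numeric(threshold_likely) ||
      threshold_followup >= threshold_likely) {
    abort_npc("thresholds must satisfy threshold_followup < threshold_likely",
              "npccdb_validation_error")
  }
  structure(
    list(items = items,
         threshold_followup = threshold_followup,
         threshold_likely = threshold_likely),
    class = "npc_rubric"
  )
}

#' Load a risk-index rubric from YAML or JSON
#'
#' Expects top-level `items` (map item_id -> points) and optional
#' `threshold_followup` / `threshold_likely`.
#'
#' @param path Path to the rubric file.
#' @return An `npc_rubric`.
#' @export
load_risk_rubric <- function(path) {
  if (!file.exists(path)) {
    abort_npc(paste0("rubric file not found: ", path), "npccdb_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  risk_index_rubric(unlist(raw$items),
                    threshold_followup = raw$threshold_followup %||% 40,
                    threshold_likely = raw$threshold_likely %||% 70)
}

#' Default (synthetic) risk-index rubric
#'
#' A synthetic stand-in for the published Suspicion Index weights, keyed by
#' default-catalog symptom ids; strongly NP-C-specific signs (VSGP,
#' splenomegaly, cataplexy) score high, less specific cognitive/motor signs
#' score low, mirroring the published instrument's emphasis. Not validated
#' against the published item table.
#'
#' @return An `npc_rubric` with thresholds 40 (follow-up) and 70 (likely).
#' @export
default_risk_rubric <- function() {
  risk_index_rubric(c(
    vsgp = 40,
    gelastic_cataplexy = 20,
    splenomegaly = 20,
    neonatal_jaundice = 10,
    cognitive_impairment = 10,
    ataxia = 10,
    dysarthria = 10,
    swallowing_difficulties = 10,
    dystonia = 10,
    psychosis = 15,
    clumsiness = 5,
    impaired_fine_motor = 5,
    school_problems = 5,
    behavioral_problems = 5
  ))
}

#' @export
print.npc_rubric <- function(x, ...) {
  cat(sprintf("<npc_rubric> %d items; follow-up >= %g, likely >= %g\n",
              length(x$items), x$threshold_followup, x$threshold_likely))
  invisible(x)
}
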
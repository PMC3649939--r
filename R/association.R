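#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' Enumerates every 2x2 table with the observed margins, computes each
#' table's hypergeometric probability, and sums the probabilities of all
#' tables no more probable than the observed one (the two-sided
#' probability-ordering definition). Probabilities are evaluated in log
#' space via `lchoose`, which is accurate to ~1e-15 relative for all totals
#' handled here; a 1e-7 relative slack absorbs floating-point ties.
#'
#' @param table A 2x2 matrix (rows = exposure, columns = outcome) or a
#'   length-4 vector `c(a, b, c, d)` in row-major order; non-negative
#'   integers.
#' @return The two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 34/70
fisher_exact <- function(table) {
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2, 2))) {
      abort_npc("table must be 2x2", "npccdb_validation_error")
    }
    tab <- c(t(table))
  } else {
    if (length(table) != 4) {
      abort_npc("table must be 2x2 (or a length-4 vector)", "npccdb_validation_error")
    }
    tab <- as.numeric(table)
  }
  if (any(is.na(tab)) || any(tab < 0) || any(tab != floor(tab))) {
    abort_npc("table entries must be non-negative integers", "npccdb_validation_error")
  }
  a <- tab[1]; b <- tab[2]; c_ <- tab[3]; d <- tab[4]
  n_tot <- a + b + c_ + d
  if (n_tot == 0) {
    abort_npc("table total must be positive", "npccdb_validation_error")
  }
  r1 <- a + b
  c1 <- a + c_
  lo <- max(0, c1 - (n_tot - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  lp <- lchoose(r1, support) + lchoose(n_tot - r1, c1 - support) -
    lchoose(n_tot, c1)
  lp_obs <- lp[support == a]
  min(1, sum(exp(lp[lp <= lp_obs + log1p(1e-7)])))
}

#' Association between first seizures and accelerated progression
#'
#' For every patient with a first seizure and at least `window` years of
#' follow-up on both sides of it, computes the seizure-cleaned score
#' increment over the `window` years before and after the first seizure
#' (cleaning removes seizure-domain score points so the comparison is not
#' driven by the seizure itself). The patient is flagged accelerated when
#' the post/pre increment ratio reaches `accel_criterion`; a zero pre-window
#' increment is guarded by epsilon = half the smallest catalog weight. Each
#' seizure-free patient contributes the same flag evaluated at a matched
#' disease time (the years-since-onset of a randomly matched seizure
#' patient; seeded via `match_seed`), provided their follow-up covers it.
#' The resulting seizure-status x accelerated-flag table is tested with
#' [fisher_exact()].
#'
#' @param cohort An `npc_cohort`.
#' @param window Years before/after the first seizure (default 2).
#' @param accel_criterion Post/pre increment ratio flagging acceleration
#'   (default 2).
#' @param match_seed Optional integer making the control matching
#'   reproducible.
#' @return A list of class `npc_assoc`: `table` (2x2 matrix), `p_value`,
#'   and a `details` tibble of per-patient contributions.
#' @export
seizure_association <- function(cohort, window = 2, accel_criterion = 2,
                                match_seed = NULL) {
  pts <- neuro_patients(cohort)
  eps <- min(cohort$catalog$severity_weight) / 2
  seiz <- pts |>
    filter(!is.na(.data$first_seizure_age)) |>
    mutate(t_s = .data$first_seizure_age - .data$age_at_neuro_onset) |>
    filter(.data$t_s >= window - 1e-9,
           .data$age_at_last_visit >= .data$first_seizure_age + window - 1e-9)
  if (nrow(seiz) == 0) {
    abort_npc(paste0("no seizure patient with ", window,
                     " y of follow-up on both sides of the first seizure"),
              "npccdb_validation_error")
  }
  ctrl <- pts |> filter(is.na(.data$first_seizure_age))
  if (nrow(ctrl) == 0) {
    abort_npc("no seizure-free comparator patients", "npccdb_validation_error")
  }
  increment_flag <- function(pid, onset, t_mid) {
    pre <- score_at_age(cohort, pid, onset + t_mid, "cleaned") -
      score_at_age(cohort, pid, onset + t_mid - window, "cleaned")
    post <- score_at_age(cohort, pid, onset + t_mid + window, "cleaned") -
      score_at_age(cohort, pid, onset + t_mid, "cleaned")
    list(pre = pre, post = post,
         accelerated = post / max(pre, eps) >= accel_criterion)
  }
  seiz_rows <- purrr::map(seq_len(nrow(seiz)), function(i) {
    f <- increment_flag(seiz$patient_id[i], seiz$age_at_neuro_onset[i], seiz$t_s[i])
    tibble(patient_id = seiz$patient_id[i], group = "seizure",
           t_eval = seiz$t_s[i], delta_pre = f$pre, delta_post = f$post,
           accelerated = f$accelerated)
  }) |> list_rbind()
  draw_matches <- function() {
    sample(seiz$t_s, nrow(ctrl), replace = TRUE)
  }
  matched_t <- if (is.null(match_seed)) draw_matches() else
    withr::with_seed(match_seed, draw_matches())
  ctrl_rows <- purrr::map(seq_len(nrow(ctrl)), function(i) {
    t_m <- matched_t[i]
    fu <- ctrl$age_at_last_visit[i] - ctrl$age_at_neuro_onset[i]
    if (fu < t_m + window - 1e-9) return(NULL)
    f <- increment_flag(ctrl$patient_id[i], ctrl$age_at_neuro_onset[i], t_m)
    tibble(patient_id = ctrl$patient_id[i], group = "seizure_free",
           t_eval = t_m, delta_pre = f$pre, delta_post = f$post,
           accelerated = f$accelerated)
  }) |> list_rbind()
  if (is.null(ctrl_rows) || nrow(ctrl_rows) == 0) {
    abort_npc("no seizure-free comparator with enough follow-up at matched times",
              "npccdb_validation_error")
  }
  details <- bind_rows(seiz_rows, ctrl_rows)
  tab <- matrix(c(
    sum(seiz_rows$accelerated), sum(!seiz_rows$accelerated),
    sum(ctrl_rows$accelerated), sum(!ctrl_rows$accelerated)
  ), 2, 2, byrow = TRUE,
  dimnames = list(c("seizure", "seizure_free"),
                  c("accelerated", "not_accelerated")))
  structure(list(table = tab, p_value = fisher_exact(tab), details = details),
            class = "npc_assoc")
}

#' Risk-index sensitivity versus disease duration
#'
#' Dichotomizes patients (with known neurological onset and diagnosis) by
#' disease duration at diagnosis — shorter versus at least
#' `short_threshold` years — crosses that with whether the risk-index
#' category is `likely`, and tests the 2x2 table with [fisher_exact()]. A
#' negative association reproduces the observation that the screening score
#' under-calls patients early in the disease course.
#'
#' @param cohort An `npc_cohort` with risk-index answers.
#' @param rubric An [risk_index_rubric()].
#' @param short_threshold Duration cut in years (default 3; `short` means
#'   first neurological symptom fewer than 3 y before diagnosis).
#' @return An `npc_assoc` list: `table`, `p_value`, `details`.
#' @export
si_sensitivity_vs_duration <- function(cohort, rubric = default_risk_rubric(),
                                       short_threshold = 3) {
  pts <- neuro_patients(cohort)
  if (nrow(pts) == 0) {
    abort_npc("no patients with a neurological onset", "npccdb_validation_error")
  }
  ri <- evaluate_risk_index(cohort, rubric)
  details <- pts |>
    mutate(duration = .data$age_at_diagnosis - .data$age_at_neuro_onset,
           stratum = ifelse(.data$duration < short_threshold, "short", "long")) |>
    left_join(ri, by = "patient_id") |>
    mutate(likely = .data$category == "likely") |>
    select("patient_id", "duration", "stratum", "total", "category", "likely")
  if (length(unique(details$stratum)) < 2) {
    abort_npc("all patients fall in one duration stratum", "npccdb_validation_error")
  }
  tab <- matrix(c(
    sum(details$stratum == "short" & details$likely),
    sum(details$stratum == "short" & !details$likely),
    sum(details$stratum == "long" & details$likely),
    sum(details$stratum == "long" & !details$likely)
  ), 2, 2, byrow = TRUE,
  dimnames = list(c("short_duration", "long_duration"),
                  c("likely", "not_likely")))
  structure(list(table = tab, p_value = fisher_exact(tab), details = details),
            class = "npc_assoc")
}

#' @export
print.npc_assoc <- function(x, ...) {
  cat("<npc_assoc> Fisher exact p =", format(x$p_value, digits = 4), "\n")
  print(x$table)
  invisible(x)
}

#' Correlation of plasma oxysterol levels with the NPC-cdb score
#'
#' Per patient, averages analyte level and raw score over up to
#' `max_samples_per_patient` consecutive samples taken at scoreable ages,
#' then regresses mean level on mean score (ordinary least squares) for
#' cholestane-3beta,5alpha,6beta-triol and 7-ketocholesterol separately.
#' Samples are additionally flagged against the screening cut-offs
#' (24.5 ng/mL triol, 47.5 ng/mL 7-KC).
#'
#' @param cohort An `npc_cohort` with oxysterol samples.
#' @param max_samples_per_patient Samples averaged per patient (default 3).
#' @param cutoff_triol,cutoff_kc Screening cut-offs in ng/mL.
#' @return A list of class `npc_oxy`: `fits` (one row per analyte with
#'   `slope`, `slope_lower`, `slope_upper`, `intercept`, `r_squared`, `n`),
#'   `patients` (per-patient means), and `samples` with above-cut-off flags.
#' @export
oxysterol_correlation <- function(cohort, max_samples_per_patient = 3,
                                  cutoff_triol = 24.5, cutoff_kc = 47.5) {
  ox <- cohort$oxysterols
  lastv <- setNames(cohort$patients$age_at_last_visit, cohort$patients$patient_id)
  ox <- ox |> filter(.data$age <= lastv[.data$patient_id] + 1e-9)
  if (nrow(ox) == 0) {
    abort_npc("cohort has no oxysterol samples at scoreable ages",
              "npccdb_validation_error")
  }
  per_patient <- ox |>
    arrange(.data$patient_id, .data$age) |>
    group_by(.data$patient_id) |>
    slice(seq_len(max_samples_per_patient)) |>
    ungroup()
  per_patient$score <- map_dbl(seq_len(nrow(per_patient)), function(i) {
    score_at_age(cohort, per_patient$patient_id[i], per_patient$age[i], "raw")
  })
  means <- per_patient |>
    group_by(.data$patient_id) |>
    summarise(mean_triol = mean(.data$triol), mean_kc = mean(.data$seven_kc),
              mean_score = mean(.data$score), .groups = "drop")
  if (nrow(means) < 3) {
    abort_npc("oxysterol correlation needs at least 3 eligible patients",
              "npccdb_validation_error")
  }
  fit_one <- function(level, analyte) {
    f <- lm(level ~ means$mean_score)
    sm <- suppressWarnings(summary(f))  # degenerate (constant) levels allowed
    se <- sm$coefficients[2, 2]
    tibble(analyte = analyte, n = nrow(means),
           slope = unname(coef(f)[2]),
           slope_lower = unname(coef(f)[2]) - 1.96 * se,
           slope_upper = unname(coef(f)[2]) + 1.96 * se,
           intercept = unname(coef(f)[1]),
           r_squared = if (var(level) < 1e-12) 0 else sm$r.squared)
  }
  fits <- bind_rows(fit_one(means$mean_triol, "triol"),
                    fit_one(means$mean_kc, "seven_kc"))
  samples <- ox |>
    mutate(above_cutoff_triol = .data$triol > cutoff_triol,
           above_cutoff_kc = .data$seven_kc > cutoff_kc)
  structure(list(fits = fits, patients = means, samples = samples),
            class = "npc_oxy")
}

#' @export
print.npc_oxy <- function(x, ...) {
  cat("<npc_oxy> per-analyte OLS of mean level on mean score\n")
  print(x$fits)
  invisible(x)
}
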
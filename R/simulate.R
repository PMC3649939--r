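#' Configuration for the synthetic NP-C cohort generator
#'
#' Defaults encode the published cohort statistics the generator emulates:
#' neurological onset ages with mean 7.9 and SD 6.9 y (moment-matched
#' truncated normal), diagnostic delay with mean 5.7 and SD 7.6 y
#' (moment-matched gamma; a truncated normal cannot carry a coefficient of
#' variation above 1), a 4/42 fraction diagnosed before neurological onset,
#' a steady/fulminant/accelerated progression mix of 24/37, 7/37, 6/37, an
#' acceleration ratio of 2.9 (SD 1.1, floored at `accel_ratio_min`), a
#' breakpoint delay of 6.7 (SD 2.5) y after onset, 35% observed seizure
#' prevalence, and first seizures in the year preceding the breakpoint for
#' 4 of 6 accelerated patients.
#'
#' @param n_patients Number of patients to simulate.
#' @param neuro_onset_mean,neuro_onset_sd Realized moments (y) of the
#'   truncated-at-zero normal for age at neurological onset.
#' @param diag_delay_mean,diag_delay_sd Moments (y) of the gamma-distributed
#'   delay from neurological onset to diagnosis.
#' @param frac_pre_neuro_diagnosis Fraction of patients diagnosed before any
#'   neurological sign (these carry `NA` neurological onset and only visceral
#'   events).
#' @param progression_mix Named proportions for `steady`, `fulminant`,
#'   `accelerated`; must sum to 1.
#' @param accel_ratio_mean,accel_ratio_sd,accel_ratio_min Latent post/pre
#'   slope ratio of accelerated patients (truncated normal, realized moments
#'   matched when feasible).
#' @param accel_delay_mean,accel_delay_sd Breakpoint delay after neurological
#'   onset (y), truncated below at `min_breakpoint`.
#' @param min_breakpoint Smallest admissible breakpoint delay (y).
#' @param seizure_prevalence Observed fraction of patients with at least one
#'   seizure by last visit.
#' @param seizure_link_prob Probability that an accelerated patient's first
#'   seizure falls in the year preceding the breakpoint.
#' @param fulminant_speedup Constant factor by which fulminant patients
#'   traverse the nominal symptom sequence faster.
#' @param onset_sdlog Log-scale SD of the per-symptom log-normal onset
#'   offsets.
#' @param followup_min,followup_max Uniform follow-up (y) added after
#'   diagnosis to obtain the last-visit age.
#' @param frac_deceased,frac_filipin_tested,filipin_probs,allele_count_probs,
#'   allele_type_probs,frac_oxysterol_tested Demographic/diagnostic marginals
#'   (defaults mirror the published cohort's printed counts over n = 42).
#' @param oxy_triol_intercept,oxy_triol_slope,oxy_triol_sd,
#'   oxy_kc_intercept,oxy_kc_slope,oxy_kc_sd Linear score-to-oxysterol
#'   calibration with Gaussian noise (synthetic; ng/mL).
#' @param seed Integer seed; the generator is fully reproducible given
#'   `seed` + config.
#' @param catalog Symptom catalog carrying per-symptom `prevalence` and
#'   `median_onset` calibration columns.
#' @param rubric Risk-index rubric used to derive item answers from the
#'   symptoms manifested by diagnosis.
#' @return A list of class `npc_generator_config`.
#' @export
generator_config <- function(n_patients,
                             neuro_onset_mean = 7.9, neuro_onset_sd = 6.9,
                             diag_delay_mean = 5.7, diag_delay_sd = 7.6,
                             frac_pre_neuro_diagnosis = 4 / 42,
                             progression_mix = c(steady = 24 / 37,
                                                 fulminant = 7 / 37,
                                                 accelerated = 6 / 37),
                             accel_ratio_mean = 2.9, accel_ratio_sd = 1.1,
                             accel_ratio_min = 2,
                             accel_delay_mean = 6.7, accel_delay_sd = 2.5,
                             min_breakpoint = 2,
                             seizure_prevalence = 0.35,
                             seizure_link_prob = 4 / 6,
                             fulminant_speedup = 2,
                             onset_sdlog = 0.6,
                             followup_min = 1, followup_max = 10,
                             frac_deceased = 8 / 42,
                             frac_filipin_tested = 26 / 42,
                             filipin_probs = c(classic = 17 / 26,
                                               variant = 8 / 26,
                                               indifferent = 1 / 26),
                             allele_count_probs = c(`2` = 36 / 42,
                                                    `1` = 5 / 42,
                                                    `0` = 1 / 42),
                             allele_type_probs = c(missense = 62 / 80,
                                                   splicing = 2 / 80,
                                                   nonsense = 5 / 80,
                                                   deletion = 9 / 80,
                                                   insertion = 2 / 80),
                             frac_oxysterol_tested = 16 / 42,
                             oxy_triol_intercept = 30, oxy_triol_slope = 1.5,
                             oxy_triol_sd = 8,
                             oxy_kc_intercept = 80, oxy_kc_slope = 4,
                             oxy_kc_sd = 20,
                             seed = 1L,
                             catalog = default_symptom_catalog(),
                             rubric = default_risk_rubric()) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    abort_npc("n_patients must be >= 1", "npccdb_config_error")
  }
  props <- c(frac_pre_neuro_diagnosis, seizure_prevalence, seizure_link_prob,
             frac_deceased, frac_filipin_tested, frac_oxysterol_tested)
  if (any(props < 0 | props > 1)) {
    abort_npc("all proportions must lie in [0, 1]", "npccdb_config_error")
  }
  if (length(progression_mix) != 3 ||
      !setequal(names(progression_mix), c("steady", "fulminant", "accelerated"))) {
    abort_npc("progression_mix needs named entries steady/fulminant/accelerated",
              "npccdb_config_error")
  }
  if (abs(sum(progression_mix) - 1) > 1e-8 || any(progression_mix < 0)) {
    abort_npc("progression_mix must be non-negative and sum to 1",
              "npccdb_config_error")
  }
  sds <- c(neuro_onset_sd, diag_delay_sd, accel_ratio_sd, accel_delay_sd,
           onset_sdlog)
  if (any(sds < 0)) abort_npc("standard deviations must be >= 0", "npccdb_config_error")
  if (followup_min < 0 || followup_max < followup_min) {
    abort_npc("follow-up window must satisfy 0 <= followup_min <= followup_max",
              "npccdb_config_error")
  }
  cfg <- as.list(environment())
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "npc_generator_config")
}

# Calibrate the log-normal meanlog of one symptom so that the cohort-level
# marginal time-to-symptom KM median (mixture over progression archetypes,
# no censoring) equals the configured median. When prevalence is too low for
# the marginal survival to reach 0.5, the manifesting-subpopulation mixture
# median is targeted instead.
calibrate_meanlog <- function(p, m, sdlog, mix, speedup) {
  if (is.na(p) || is.na(m) || p <= 0) return(log(max(m, 1e-6)))
  lambda_at <- function(t) {
    # nominal disease time reached by observed time t, per archetype;
    # accelerated patients keep their base sequence (acceleration adds
    # events on top, see generate_cohort) so they warp like steady ones
    c(steady = t, fulminant = speedup * t, accelerated = t)
  }
  lam <- lambda_at(m)
  cdf_mix <- function(meanlog) {
    sum(mix * stats::plnorm(lam, meanlog, sdlog))
  }
  # marginal survival at m: 1 - p * cdf_mix; want == 0.5  <=>  cdf_mix == 0.5/p
  target <- if (p > 0.5 + 1e-9) 0.5 / p else 0.5
  f <- function(ml) cdf_mix(ml) - target
  lo <- log(m) - 6
  hi <- log(m) + 6
  if (f(lo) * f(hi) > 0) return(log(m))
  uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Generate a seeded synthetic cohort
#'
#' Draws a full registry-style cohort with the statistical structure the
#' downstream analyses assume: truncated-normal neurological onset ages,
#' gamma diagnostic delays (with a configured fraction diagnosed
#' pre-neurologically), per-symptom log-normal onset offsets calibrated so
#' cohort-level Kaplan-Meier medians recover the configured values, latent
#' progression archetypes (steady / fulminant / accelerated with a
#' changepoint and slope ratio), seizures linked to the year preceding the
#' breakpoint for a configured fraction of accelerated patients, last-visit
#' censoring, diagnostic marginals (filipin, alleles), score-correlated
#' oxysterol samples, and risk-index answers derived from the symptoms
#' manifested by diagnosis.
#'
#' All latent truths (archetype, breakpoint, slope ratio, seizure linkage)
#' are recorded in the cohort's provenance for parameter-recovery testing;
#' see [truth_table()].
#'
#' @param config An [generator_config()].
#' @return A validated `npc_cohort`.
#' @export
#' @examples
#' co <- generate_cohort(generator_config(50, seed = 7))
#' co
generate_cohort <- function(config) {
  if (!inherits(config, "npc_generator_config")) {
    abort_npc("config must come from generator_config()", "npccdb_config_error")
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  cat_tbl <- as_tibble(cfg$catalog) |> arrange(.data$symptom_id)
  mix <- cfg$progression_mix[c("steady", "fulminant", "accelerated")]

  parent_onset <- truncnorm_parent(cfg$neuro_onset_mean, cfg$neuro_onset_sd, 0)
  parent_b <- truncnorm_parent(cfg$accel_delay_mean, cfg$accel_delay_sd,
                               cfg$min_breakpoint)
  parent_r <- truncnorm_parent_safe(cfg$accel_ratio_mean, cfg$accel_ratio_sd,
                                    cfg$accel_ratio_min)
  if (cfg$diag_delay_sd > 0) {
    gshape <- (cfg$diag_delay_mean / cfg$diag_delay_sd)^2
    grate <- cfg$diag_delay_mean / cfg$diag_delay_sd^2
  }

  neuro_syms <- cat_tbl |>
    filter(.data$onset_reference == "neuro", !.data$seizure_domain)
  visc_syms <- cat_tbl |> filter(.data$onset_reference == "birth")
  seiz_syms <- cat_tbl |> filter(.data$seizure_domain)
  seizure_id <- if (nrow(seiz_syms) > 0) seiz_syms$symptom_id[1] else NA_character_
  seizure_median <- if (nrow(seiz_syms) > 0) seiz_syms$median_onset[1] %||% 6.5 else 6.5
  if (is.na(seizure_median)) seizure_median <- 6.5

  meanlogs <- map_dbl(seq_len(nrow(neuro_syms)), function(j) {
    calibrate_meanlog(neuro_syms$prevalence[j], neuro_syms$median_onset[j],
                      cfg$onset_sdlog, mix, cfg$fulminant_speedup)
  })

  # ---- patient-level draws (fixed order, then symptom draws patient-major) ----
  pre_neuro <- runif(n) < cfg$frac_pre_neuro_diagnosis
  onset <- rtruncnorm_q(runif(n), parent_onset)
  delay <- if (cfg$diag_delay_sd > 0) rgamma(n, shape = gshape, rate = grate) else
    rep(cfg$diag_delay_mean, n)
  diag_pre <- 0.1 + runif(n) * 1.9
  followup <- cfg$followup_min + runif(n) * (cfg$followup_max - cfg$followup_min)
  arch_u <- runif(n)
  arch <- names(mix)[pmin(3, findInterval(arch_u, c(0, cumsum(mix)),
                                          rightmost.closed = TRUE))]
  b_rel <- rtruncnorm_q(runif(n), parent_b)
  ratio <- rtruncnorm_q(runif(n), parent_r)
  linked_u <- runif(n)
  generic_u <- runif(n)
  seiz_time_u <- runif(n)
  sex <- ifelse(runif(n) < 0.5, "F", "M")
  deceased <- runif(n) < cfg$frac_deceased
  fil_tested <- runif(n) < cfg$frac_filipin_tested
  fil_u <- runif(n)
  allele_u <- runif(n)
  type_u1 <- runif(n)
  type_u2 <- runif(n)
  oxy_tested <- runif(n) < cfg$frac_oxysterol_tested
  oxy_n <- 1L + (runif(n) < 0.7) + (runif(n) < 0.4)
  oxy_age_u <- matrix(runif(3 * n), n, 3, byrow = TRUE)
  oxy_noise_t <- matrix(rnorm(3 * n), n, 3, byrow = TRUE)
  oxy_noise_k <- matrix(rnorm(3 * n), n, 3, byrow = TRUE)

  k <- nrow(neuro_syms)
  u_mat <- matrix(runif(n * k), n, k, byrow = TRUE)
  z_mat <- matrix(rnorm(n * k), n, k, byrow = TRUE)
  kv <- nrow(visc_syms)
  uv_mat <- matrix(runif(n * kv), n, kv, byrow = TRUE)
  mv_mat <- matrix(runif(n * kv), n, kv, byrow = TRUE)

  arch[pre_neuro] <- NA_character_
  onset[pre_neuro] <- NA_real_
  age_dx <- ifelse(pre_neuro, diag_pre, onset + delay)
  last_visit <- age_dx + followup
  accel <- !is.na(arch) & arch == "accelerated"
  # accelerated archetypes are study-observable: the record covers the
  # decline, which dominates the end of follow-up (3-5 y past breakpoint)
  last_visit[accel] <- pmax(
    age_dx[accel] + cfg$followup_min,
    onset[accel] + b_rel[accel] + 3 +
      2 * (followup[accel] - cfg$followup_min) /
      max(cfg$followup_max - cfg$followup_min, 1)
  )
  b_rel[!accel] <- NA_real_
  ratio[!accel] <- NA_real_

  # ---- seizures ----
  pi_acc <- unname(mix["accelerated"])
  eff_link <- if (pi_acc > 0) {
    min(cfg$seizure_link_prob, cfg$seizure_prevalence / pi_acc)
  } else cfg$seizure_link_prob
  pi_acc_link <- pi_acc * eff_link
  q_generic <- if (pi_acc_link < 1) {
    max(0, min(1, (cfg$seizure_prevalence - pi_acc_link) / (1 - pi_acc_link)))
  } else 0
  linked <- accel & linked_u < eff_link
  generic <- !pre_neuro & !linked & generic_u < q_generic
  seiz_rel <- rep(NA_real_, n)
  seiz_rel[linked] <- pmax(0, b_rel[linked] - seiz_time_u[linked])
  if (any(generic)) {
    fu_rel <- last_visit[generic] - onset[generic]
    ml <- log(seizure_median)
    cap <- stats::plnorm(fu_rel, ml, cfg$onset_sdlog)
    seiz_rel[generic] <- stats::qlnorm(seiz_time_u[generic] * cap, ml, cfg$onset_sdlog)
  }
  first_seizure_age <- onset + seiz_rel

  # ---- symptom events ----
  events <- vector("list", n)
  pid <- sprintf("P%04d", seq_len(n))
  for (i in seq_len(n)) {
    rows <- list()
    if (!pre_neuro[i] && k > 0) {
      manifest <- u_mat[i, ] < neuro_syms$prevalence
      offs <- exp(meanlogs + cfg$onset_sdlog * z_mat[i, ])
      if (!is.na(arch[i]) && arch[i] == "fulminant") offs <- offs / cfg$fulminant_speedup
      fu <- last_visit[i] - onset[i]
      base_off <- offs[manifest]
      base_ids <- neuro_syms$symptom_id[manifest]
      extra_off <- numeric(0)
      extra_ids <- character(0)
      if (!is.na(arch[i]) && arch[i] == "accelerated") {
        # acceleration: from the breakpoint on, the remaining signs (own
        # pending ones first, then the closest prevalence misses) are
        # recruited at the constant rate that multiplies the observed
        # score slope by the latent ratio
        b <- b_rel[i]
        pre <- base_off <= b
        pool <- which(!manifest)
        pool <- pool[order(u_mat[i, pool] - neuro_syms$prevalence[pool])]
        # initial *steady* progression: the manifested pre-breakpoint signs
        # are laid out at a constant score rate over (0, b], topped up from
        # the closest prevalence misses when the own pre-course is too flat
        pre_ids <- base_ids[pre][order(base_off[pre])]
        pre_w <- neuro_syms$severity_weight[match(pre_ids, neuro_syms$symptom_id)]
        overflow <- character(0)
        if (sum(pre_w) > 2.5 * b && length(pre_w) > 1) {
          # "rather stable" initial course: cap the pre-break rate, late
          # overflow signs arrive with the acceleration instead
          n_keep <- max(1, which(cumsum(pre_w) <= 2.5 * b) |> max(1))
          overflow <- pre_ids[-seq_len(n_keep)]
          pre_ids <- pre_ids[seq_len(n_keep)]
          pre_w <- pre_w[seq_len(n_keep)]
        }
        need_w <- 1.5 * b - sum(pre_w)
        if (need_w > 0 && length(pool) > 0) {
          cum_pool <- cumsum(neuro_syms$severity_weight[pool])
          n_fill <- which(cum_pool >= need_w)[1]
          if (is.na(n_fill)) n_fill <- length(pool)
          fill <- pool[seq_len(n_fill)]
          pool <- pool[-seq_len(n_fill)]
          pre_ids <- c(pre_ids, neuro_syms$symptom_id[fill])
          pre_w <- c(pre_w, neuro_syms$severity_weight[fill])
        }
        pre_off <- b * cumsum(pre_w) / sum(pre_w)
        s_pre <- sum(pre_w) / b
        post_rate <- ratio[i] * s_pre
        own_post <- which(manifest)[base_off > b]
        own_post_ids <- neuro_syms$symptom_id[own_post][order(offs[own_post])]
        queue_ids <- c(overflow, own_post_ids, neuro_syms$symptom_id[pool])
        w_q <- neuro_syms$severity_weight[match(queue_ids, neuro_syms$symptom_id)]
        t_q <- b + cumsum(w_q) / post_rate
        keep_q <- t_q <= fu
        extra_off <- c(pre_off, t_q[keep_q])
        extra_ids <- c(pre_ids, queue_ids[keep_q])
        base_off <- numeric(0)
        base_ids <- character(0)
      }
      off_all <- c(base_off, extra_off)
      ids_all <- c(base_ids, extra_ids)
      keep <- off_all <= fu
      if (any(keep)) {
        rows$neuro <- tibble(patient_id = pid[i],
                             symptom_id = ids_all[keep],
                             onset_age = round(onset[i] + off_all[keep], 1))
      }
    }
    if (kv > 0) {
      manifest_v <- mv_mat[i, ] < visc_syms$prevalence
      if (any(manifest_v)) {
        age_v <- visc_syms$onset_min[manifest_v] +
          uv_mat[i, manifest_v] *
          (visc_syms$onset_max[manifest_v] - visc_syms$onset_min[manifest_v])
        keep_v <- age_v <= last_visit[i]
        if (any(keep_v)) {
          rows$visc <- tibble(patient_id = pid[i],
                              symptom_id = visc_syms$symptom_id[manifest_v][keep_v],
                              onset_age = round(age_v[keep_v], 1))
        }
      }
    }
    if (!is.na(seiz_rel[i]) && !is.na(seizure_id)) {
      rows$seiz <- tibble(patient_id = pid[i], symptom_id = seizure_id,
                          onset_age = round(first_seizure_age[i], 1))
    }
    events[[i]] <- bind_rows(rows)
  }
  events <- bind_rows(events)
  # rounding to 0.1-y registry resolution can nudge an onset past the visit
  last_by_pid <- setNames(last_visit, pid)
  if (nrow(events) > 0) {
    events$onset_age <- pmin(events$onset_age, last_by_pid[events$patient_id])
    events <- distinct(events, .data$patient_id, .data$symptom_id, .keep_all = TRUE)
  }
  first_seizure_age <- round(first_seizure_age, 1)
  first_seizure_age <- pmin(first_seizure_age, last_visit)

  # ---- diagnostic marginals ----
  fil_pattern <- rep("not_done", n)
  fp <- cfg$filipin_probs / sum(cfg$filipin_probs)
  fil_pattern[fil_tested] <- names(fp)[findInterval(fil_u[fil_tested],
                                                    c(0, cumsum(fp)),
                                                    rightmost.closed = TRUE)]
  ap <- cfg$allele_count_probs / sum(cfg$allele_count_probs)
  allele_n <- as.integer(names(ap))[findInterval(allele_u, c(0, cumsum(ap)),
                                                 rightmost.closed = TRUE)]
  tp <- cfg$allele_type_probs / sum(cfg$allele_type_probs)
  pick_type <- function(u) names(tp)[findInterval(u, c(0, cumsum(tp)),
                                                  rightmost.closed = TRUE)]
  allele_types <- purrr::map(seq_len(n), function(i) {
    if (allele_n[i] == 0) return(character())
    us <- c(type_u1[i], type_u2[i])[seq_len(allele_n[i])]
    pick_type(us)
  })

  patients <- tibble(
    patient_id = pid, sex = sex,
    age_at_assessment = round(last_visit, 1),
    age_at_neuro_onset = round(onset, 1),
    age_at_diagnosis = round(age_dx, 1),
    age_at_last_visit = round(last_visit, 1),
    deceased = deceased,
    first_seizure_age = first_seizure_age,
    filipin_pattern = fil_pattern,
    alleles_identified = allele_n,
    allele_types = allele_types,
    sibling_group = NA_character_
  )
  # rounding consistency: events may not exceed the rounded last visit
  if (nrow(events) > 0) {
    lv <- setNames(patients$age_at_last_visit, patients$patient_id)
    events$onset_age <- pmin(events$onset_age, lv[events$patient_id])
  }
  patients$first_seizure_age <- pmin(patients$first_seizure_age,
                                     patients$age_at_last_visit)

  # ---- oxysterol samples (score-correlated, synthetic calibration) ----
  oxy <- vector("list", n)
  for (i in which(oxy_tested)) {
    m <- oxy_n[i]
    ages <- sort(pmax(0, patients$age_at_last_visit[i] -
                        oxy_age_u[i, seq_len(m)] * 2))
    sc <- map_dbl(ages, function(a) {
      sum(cat_tbl$severity_weight[match(
        events$symptom_id[events$patient_id == pid[i] & events$onset_age <= a],
        cat_tbl$symptom_id)])
    })
    oxy[[i]] <- tibble(
      patient_id = pid[i], age = round(ages, 1),
      triol = round(pmax(5, cfg$oxy_triol_intercept + cfg$oxy_triol_slope * sc +
                           cfg$oxy_triol_sd * oxy_noise_t[i, seq_len(m)]), 1),
      seven_kc = round(pmax(10, cfg$oxy_kc_intercept + cfg$oxy_kc_slope * sc +
                              cfg$oxy_kc_sd * oxy_noise_k[i, seq_len(m)]), 1)
    )
  }
  oxy <- bind_rows(oxy)

  # ---- risk-index answers: item true iff matching symptom manifested by dx ----
  items <- names(cfg$rubric$items)
  ans <- tidyr::expand_grid(patient_id = pid, item_id = items)
  ev_key <- paste(events$patient_id, events$symptom_id)
  ev_age <- setNames(events$onset_age, ev_key)
  dx <- setNames(patients$age_at_diagnosis, patients$patient_id)
  key <- paste(ans$patient_id, ans$item_id)
  ans$answer <- !is.na(ev_age[key]) & ev_age[key] <= dx[ans$patient_id] + 1e-9
  ans <- as_tibble(ans)

  truth <- tibble(
    patient_id = pid,
    pre_neuro = pre_neuro,
    archetype = arch,
    breakpoint = round(b_rel, 4),
    slope_ratio = round(ratio, 4),
    seizure_linked = linked,
    first_seizure_rel = seiz_rel
  )
  cfg_rec <- unclass(cfg)
  cfg_rec$catalog <- NULL
  cfg_rec$rubric <- NULL
  cohort(patients, events, cfg$catalog,
         oxysterols = oxy, risk_answers = ans,
         provenance = list(generator = "npccdb::generate_cohort",
                           seed = cfg$seed, config = cfg_rec, truth = truth))
}

#' Simulation truth table of a generated cohort
#'
#' Returns the per-patient latent quantities recorded by [generate_cohort()]:
#' progression archetype, breakpoint delay and slope ratio (accelerated
#' patients), and seizure linkage. Fails on imported cohorts, which carry no
#' simulation provenance.
#'
#' @param cohort An `npc_cohort`.
#' @return A tibble with one row per patient.
#' @export
truth_table <- function(cohort) {
  tr <- cohort$provenance$truth
  if (is.null(tr)) {
    abort_npc("no simulation provenance: truth_table() requires a generated cohort",
              "npccdb_provenance_error")
  }
  as_tibble(tr)
}
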
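#' Kaplan-Meier product-limit fit
#'
#' Nonparametric estimate of the survival function
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} from right-censored
#' durations, with Greenwood standard errors, log-log transformed pointwise
#' confidence bounds (kept inside \[0, 1\]), the median survival time
#' (smallest \eqn{t} with \eqn{\hat S(t) \le 0.5}; undefined if the curve
#' never reaches 0.5), a Brookmeyer-Crowley confidence interval for the
#' median obtained by inverting the pointwise bounds, and the restricted mean
#' up to the largest observed time. Ties between events and censorings at the
#' same time are resolved events-first (standard convention).
#'
#' @param durations Non-negative follow-up times (years).
#' @param event_observed Logical, `TRUE` where the event was observed and
#'   `FALSE` where the duration is censored.
#' @param conf_level Confidence level for pointwise and median intervals.
#' @return An object of class `npc_km`; see [tidy.npc_km()] and
#'   [glance.npc_km()].
#' @export
#' @examples
#' fit <- km_fit(c(1, 2, 3), c(TRUE, FALSE, TRUE))
#' glance(fit)$median  # 3
km_fit <- function(durations, event_observed, conf_level = 0.95) {
  if (length(durations) == 0 || length(durations) != length(event_observed)) {
    abort_npc("durations and event_observed must be equal-length and non-empty",
              "npccdb_validation_error")
  }
  if (any(is.na(durations)) || any(durations < 0)) {
    abort_npc("durations must be non-negative and non-missing",
              "npccdb_validation_error")
  }
  event_observed <- as.logical(event_observed)
  n <- length(durations)
  times <- sort(unique(durations[event_observed]))
  if (length(times) > 0) {
    # exact-value matching: every duration belongs to exactly one event time
    n_risk <- map_dbl(times, ~ sum(durations >= .x))
    n_event <- map_dbl(times, ~ sum(event_observed & durations == .x))
    n_censor <- map_dbl(times, ~ sum(!event_observed & durations == .x))
    surv <- cumprod(1 - n_event / n_risk)
    # Greenwood: Var(S) = S^2 * sum d / (n (n - d))
    gw <- cumsum(ifelse(n_risk > n_event,
                        n_event / (n_risk * (n_risk - n_event)), 0))
    se <- surv * sqrt(gw)
    z <- qnorm(1 - (1 - conf_level) / 2)
    # log-log transform undefined at S = 0 or 1: bounds left NA there
    ll <- ifelse(surv > 0 & surv < 1, se / (surv * abs(log(surv))), NA_real_)
    lower <- surv^exp(z * ll)
    upper <- surv^exp(-z * ll)
    data <- tibble(time = times, n_risk = n_risk, n_event = n_event,
                   n_censor = n_censor, survival = surv, std_err = se,
                   lower = lower, upper = upper)
  } else {
    data <- tibble(time = double(), n_risk = double(), n_event = double(),
                   n_censor = double(), survival = double(),
                   std_err = double(), lower = double(), upper = double())
  }
  med <- km_crossing(data$time, data$survival)
  med_lo <- km_crossing(data$time, data$lower)
  med_hi <- km_crossing(data$time, data$upper)
  tmax <- max(durations)
  rmean <- km_rmean(data, tmax)
  structure(
    list(data = data, n = n, n_events = sum(event_observed),
         median = med, median_ci = c(lower = med_lo, upper = med_hi),
         rmean = rmean, rmean_tmax = tmax, conf_level = conf_level),
    class = "npc_km"
  )
}

# smallest event time at which the (possibly NA-holed) curve drops to <= 0.5
km_crossing <- function(time, value) {
  hit <- which(!is.na(value) & value <= 0.5 + 1e-12)
  if (length(hit) == 0) NA_real_ else time[min(hit)]
}

km_rmean <- function(data, tmax) {
  if (nrow(data) == 0) return(tmax)
  ts <- c(0, data$time, tmax)
  ss <- c(1, data$survival)
  widths <- diff(pmin(ts, tmax))
  sum(ss * widths[seq_along(ss)])
}

#' @export
print.npc_km <- function(x, ...) {
  cat(sprintf("<npc_km> n = %d, events = %d, median = %s [%s, %s]\n",
              x$n, x$n_events, format(x$median),
              format(x$median_ci[1]), format(x$median_ci[2])))
  invisible(x)
}

#' Tidy a Kaplan-Meier fit
#'
#' @param x An `npc_km`.
#' @param ... Unused.
#' @return One row per event time: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, `std_err`, `lower`, `upper`.
#' @method tidy npc_km
#' @export
tidy.npc_km <- function(x, ...) x$data

#' One-row summary of a Kaplan-Meier fit
#'
#' @param x An `npc_km`.
#' @param ... Unused.
#' @return Tibble with `n`, `events`, `median`, `median_lower`,
#'   `median_upper`, `rmean`, `rmean_tmax`.
#' @method glance npc_km
#' @export
glance.npc_km <- function(x, ...) {
  tibble(n = x$n, events = x$n_events, median = x$median,
         median_lower = unname(x$median_ci[1]),
         median_upper = unname(x$median_ci[2]),
         rmean = x$rmean, rmean_tmax = x$rmean_tmax)
}

#' Censored time-to-symptom curve normalized to neurological onset
#'
#' For each patient with a neurological onset: duration is
#' `onset_age - age_at_neuro_onset` if the symptom manifested (event) or
#' `age_at_last_visit - age_at_neuro_onset` otherwise (censored). Symptom
#' manifestations recorded before neurological onset are clamped to 0 with a
#' warning.
#'
#' @param cohort An `npc_cohort`.
#' @param symptom_id Catalog symptom id.
#' @param conf_level Confidence level passed to [km_fit()].
#' @return An `npc_km`.
#' @export
symptom_onset_curve <- function(cohort, symptom_id, conf_level = 0.95) {
  if (!symptom_id %in% cohort$catalog$symptom_id) {
    abort_npc(paste0("unknown symptom_id: ", symptom_id), "npccdb_validation_error")
  }
  pts <- neuro_patients(cohort)
  if (nrow(pts) == 0) {
    abort_npc("no patients with a neurological onset", "npccdb_validation_error")
  }
  ev <- cohort$events |>
    filter(.data$symptom_id == !!symptom_id,
           .data$patient_id %in% pts$patient_id)
  onset <- setNames(pts$age_at_neuro_onset, pts$patient_id)
  lastv <- setNames(pts$age_at_last_visit, pts$patient_id)
  dur <- lastv - onset
  observed <- rep(FALSE, nrow(pts))
  names(dur) <- names(observed) <- pts$patient_id
  if (nrow(ev) > 0) {
    rel <- ev$onset_age - onset[ev$patient_id]
    if (any(rel < -1e-9)) {
      warn(sprintf("%d pre-onset manifestation(s) of '%s' clamped to 0",
                   sum(rel < -1e-9), symptom_id))
      rel <- pmax(rel, 0)
    }
    dur[ev$patient_id] <- rel
    observed[ev$patient_id] <- TRUE
  }
  km_fit(unname(dur), unname(observed), conf_level = conf_level)
}

#' Rank symptoms by Kaplan-Meier median onset
#'
#' Restricts to symptoms whose manifestation frequency among patients with a
#' neurological onset strictly exceeds `min_frequency`, fits
#' [symptom_onset_curve()] for each, and sorts ascending by KM median
#' (undefined medians last), breaking ties by descending frequency and then
#' by id.
#'
#' @param cohort An `npc_cohort`.
#' @param symptom_ids Symptoms to consider; defaults to all non-visceral
#'   catalog entries.
#' @param min_frequency Frequency threshold in \[0, 1\] (default 0.4,
#'   strictly-greater comparison).
#' @return A tibble `symptom_id`, `frequency`, `median`, `median_lower`,
#'   `median_upper`, ordered by appearance during the disease course.
#' @export
rank_symptoms <- function(cohort, symptom_ids = NULL, min_frequency = 0.4) {
  if (is.null(symptom_ids)) {
    symptom_ids <- cohort$catalog$symptom_id[cohort$catalog$category != "visceral"]
  }
  if (length(symptom_ids) == 0) {
    abort_npc("symptom_ids must be non-empty", "npccdb_validation_error")
  }
  if (!is.numeric(min_frequency) || min_frequency < 0 || min_frequency > 1) {
    abort_npc("min_frequency must lie in [0, 1]", "npccdb_validation_error")
  }
  pts <- neuro_patients(cohort)
  if (nrow(pts) == 0) {
    abort_npc("no patients with a neurological onset", "npccdb_validation_error")
  }
  freq <- cohort$events |>
    filter(.data$patient_id %in% pts$patient_id,
           .data$symptom_id %in% symptom_ids) |>
    count(.data$symptom_id) |>
    mutate(frequency = .data$n / nrow(pts))
  keep <- freq |> filter(.data$frequency > min_frequency)
  rows <- purrr::map(keep$symptom_id, function(sid) {
    g <- glance(symptom_onset_curve(cohort, sid))
    tibble(symptom_id = sid,
           frequency = keep$frequency[keep$symptom_id == sid],
           median = g$median, median_lower = g$median_lower,
           median_upper = g$median_upper)
  }) |> list_rbind()
  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble(symptom_id = character(), frequency = double(),
                  median = double(), median_lower = double(),
                  median_upper = double()))
  }
  rows |> arrange(is.na(.data$median), .data$median,
                  desc(.data$frequency), .data$symptom_id)
}

#' Symptom manifestation relative to diagnosis
#'
#' Per-patient delta `onset_age - age_at_diagnosis` for patients manifesting
#' the symptom (negative values: the symptom preceded the diagnosis), with
#' mean, SD and median.
#'
#' @param cohort An `npc_cohort`.
#' @param symptom_id Catalog symptom id.
#' @return A one-row tibble `symptom_id`, `n`, `mean`, `sd`, `median` with a
#'   `deltas` list column of the per-patient tibble.
#' @export
onset_relative_to_diagnosis <- function(cohort, symptom_id) {
  if (!symptom_id %in% cohort$catalog$symptom_id) {
    abort_npc(paste0("unknown symptom_id: ", symptom_id), "npccdb_validation_error")
  }
  ev <- cohort$events |> filter(.data$symptom_id == !!symptom_id)
  if (nrow(ev) == 0) {
    abort_npc(paste0("no patient manifests '", symptom_id, "'"),
              "npccdb_validation_error")
  }
  dx <- setNames(cohort$patients$age_at_diagnosis, cohort$patients$patient_id)
  deltas <- tibble(patient_id = ev$patient_id,
                   delta = unname(ev$onset_age - dx[ev$patient_id]))
  tibble(symptom_id = symptom_id, n = nrow(deltas),
         mean = mean(deltas$delta), sd = sd(deltas$delta),
         median = median(deltas$delta), deltas = list(deltas))
}
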
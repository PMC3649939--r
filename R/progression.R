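#' Cohort-level score trend with mean +/- SD envelope
#'
#' Averages score trajectories per grid time over the patients still under
#' follow-up at that time, and fits an ordinary least squares line to the
#' mean score versus time. Grid times supported by fewer than `min_patients`
#' trajectories are kept in the envelope but excluded from the line fit: a
#' handful of long-followed patients do not define a cohort mean, and the
#' deep right tail of the follow-up distribution would otherwise dominate
#' the fit.
#'
#' @param trajectories Long tibble from [score_trajectories()] with at least
#'   two patients on a common grid step.
#' @param min_patients Minimum trajectories under follow-up for a grid time
#'   to enter the OLS fit. Default: 5 percent of the cohort (at least 3).
#' @return An object of class `npc_trend` with elements `slope`, `intercept`,
#'   `r_squared` and the `envelope` tibble (`t`, `mean`, `sd`, `n`).
#' @export
cohort_trend <- function(trajectories, min_patients = NULL) {
  trajectories <- as_tibble(trajectories)
  if (nrow(trajectories) == 0) {
    abort_npc("empty trajectory grid", "npccdb_validation_error")
  }
  n_pat <- length(unique(trajectories$patient_id))
  if (n_pat < 2) {
    abort_npc("cohort_trend needs at least two trajectories",
              "npccdb_validation_error")
  }
  steps <- trajectories |>
    group_by(.data$patient_id) |>
    summarise(step = if (n() > 1) min(diff(sort(.data$t))) else NA_real_,
              .groups = "drop")
  uniq <- unique(round(steps$step[!is.na(steps$step)], 9))
  if (length(uniq) > 1) {
    abort_npc("trajectories are not on a common grid step", "npccdb_validation_error")
  }
  env <- trajectories |>
    group_by(t = .data$t) |>
    summarise(mean = mean(.data$score), sd = sd(.data$score), n = n(),
              .groups = "drop") |>
    arrange(.data$t)
  if (is.null(min_patients)) min_patients <- max(3, ceiling(0.05 * n_pat))
  min_patients <- min(min_patients, n_pat)
  fit_data <- env |> filter(.data$n >= min_patients)
  if (nrow(fit_data) < 2) fit_data <- env
  sst <- sum((fit_data$mean - mean(fit_data$mean))^2)
  fit <- lm(mean ~ t, data = fit_data)
  sse <- sum(fit$residuals^2)
  r2 <- if (sst < 1e-12) 1 else max(0, 1 - sse / sst)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, envelope = env, fit_times = fit_data$t),
    class = "npc_trend"
  )
}

#' @export
print.npc_trend <- function(x, ...) {
  cat(sprintf("<npc_trend> mean score = %.3f * t + %.3f (R^2 = %.3f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @method tidy npc_trend
#' @export
tidy.npc_trend <- function(x, ...) x$envelope

#' @method glance npc_trend
#' @export
glance.npc_trend <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         n_times = nrow(x$envelope))
}

#' Continuous two-segment least-squares fit with exhaustive breakpoint search
#'
#' Fits, for every admissible breakpoint on the trajectory's own grid, the
#' continuous piecewise-linear model
#' \eqn{y = \beta_0 + \beta_1 t + \beta_2 (t - b)_+} (segments joined at
#' \eqn{b}), and returns the breakpoint minimizing the residual sum of
#' squares, the two segment slopes, their ratio, and the single-line SSE for
#' model comparison. The search is exhaustive (annual trajectories have at
#' most a few dozen points), avoiding iterative-fit convergence issues; ties
#' resolve to the earliest breakpoint.
#'
#' @param trajectory Tibble with columns `t` and `score` for one patient.
#' @param min_points_per_segment Minimum grid points on each side of the
#'   breakpoint (default 3).
#' @return A list: `status` (`"ok"` or `"insufficient_data"`), `breakpoint`,
#'   `slope_pre`, `slope_post`, `slope_ratio` (post/pre when the pre-slope is
#'   positive), `sse_two`, `sse_one`, `n`.
#' @export
fit_two_segment <- function(trajectory, min_points_per_segment = 3) {
  trajectory <- as_tibble(trajectory)
  if ("patient_id" %in% names(trajectory) &&
      length(unique(trajectory$patient_id)) > 1) {
    abort_npc("fit_two_segment takes a single patient's trajectory",
              "npccdb_validation_error")
  }
  ord <- order(trajectory$t)
  t <- trajectory$t[ord]
  y <- trajectory$score[ord]
  n <- length(t)
  if (n < 2 * min_points_per_segment) {
    return(list(status = "insufficient_data", breakpoint = NA_real_,
                slope_pre = NA_real_, slope_post = NA_real_,
                slope_ratio = NA_real_, sse_two = NA_real_,
                sse_one = NA_real_, n = n))
  }
  one <- lm.fit(cbind(1, t), y)
  sse_one <- sum(one$residuals^2)
  cands <- t[vapply(t, function(b) {
    sum(t <= b) >= min_points_per_segment && sum(t >= b) >= min_points_per_segment
  }, logical(1))]
  best <- NULL
  for (b in cands) {
    fit <- lm.fit(cbind(1, t, pmax(t - b, 0)), y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(b = b, sse = sse, coef = fit$coefficients)
    }
  }
  slope_pre <- unname(best$coef[2])
  slope_post <- unname(best$coef[2] + best$coef[3])
  ratio <- if (is.finite(slope_pre) && slope_pre > 1e-12) {
    slope_post / slope_pre
  } else NA_real_
  list(status = "ok", breakpoint = best$b,
       slope_pre = slope_pre, slope_post = slope_post, slope_ratio = ratio,
       sse_two = best$sse, sse_one = sse_one, n = n)
}

#' Classify one trajectory as steady, fulminant or accelerated
#'
#' Implements the cohort's progression typology: *fulminant* if every annual
#' score strictly exceeds the cohort mean at the corresponding time;
#' otherwise *accelerated* if the continuous two-segment fit yields a
#' post/pre slope ratio at or above `accel_ratio_threshold`, a breakpoint at
#' least `min_breakpoint_delay` years after neurological onset, and the
#' two-segment model improves on the single line by an F criterion at
#' `f_alpha` with (1, n - 4) degrees of freedom; otherwise *steady*.
#' Trajectories with fewer than `2 * min_points_per_segment` points are
#' labelled `insufficient_data`.
#'
#' @param trajectory One patient's annual trajectory (`t`, `score`, and
#'   optionally `patient_id`).
#' @param envelope Cohort envelope (`t`, `mean`) from [cohort_trend()] (its
#'   `envelope` element) on the same grid.
#' @param accel_ratio_threshold Minimum post/pre slope ratio (default 2).
#' @param min_breakpoint_delay Minimum breakpoint delay after onset in years
#'   (default 2).
#' @param min_points_per_segment Passed to [fit_two_segment()].
#' @param f_alpha Significance level of the two-segment-vs-line F test.
#' @return One-row tibble: `patient_id`, `label`, `breakpoint`, `slope_pre`,
#'   `slope_post`, `slope_ratio`.
#' @export
classify_progression <- function(trajectory, envelope,
                                 accel_ratio_threshold = 2,
                                 min_breakpoint_delay = 2,
                                 min_points_per_segment = 3,
                                 f_alpha = 0.05) {
  trajectory <- as_tibble(trajectory)
  pid <- if ("patient_id" %in% names(trajectory)) trajectory$patient_id[1] else NA_character_
  if (is.data.frame(envelope) && !"mean" %in% names(envelope)) {
    abort_npc("envelope needs columns t and mean", "npccdb_validation_error")
  }
  env_mean <- setNames(envelope$mean, sprintf("%.9g", envelope$t))
  keys <- sprintf("%.9g", trajectory$t)
  if (any(!keys %in% names(env_mean))) {
    abort_npc("trajectory grid does not align with the cohort envelope",
              "npccdb_validation_error")
  }
  out <- function(label, fit = NULL) {
    tibble(patient_id = pid, label = label,
           breakpoint = fit$breakpoint %||% NA_real_,
           slope_pre = fit$slope_pre %||% NA_real_,
           slope_post = fit$slope_post %||% NA_real_,
           slope_ratio = fit$slope_ratio %||% NA_real_)
  }
  if (nrow(trajectory) < 2 * min_points_per_segment) {
    return(out("insufficient_data"))
  }
  if (all(trajectory$score > env_mean[keys] + 1e-12)) {
    return(out("fulminant"))
  }
  fit <- fit_two_segment(trajectory, min_points_per_segment)
  if (fit$status != "ok") return(out("insufficient_data"))
  n <- fit$n
  gain <- fit$sse_one - fit$sse_two
  f_sig <- FALSE
  if (gain > 1e-9 * max(1, fit$sse_one) && n > 4) {
    if (fit$sse_two < 1e-12) {
      f_sig <- TRUE  # exact piecewise structure
    } else {
      f_stat <- gain / (fit$sse_two / (n - 4))
      f_sig <- pf(f_stat, 1, n - 4, lower.tail = FALSE) <= f_alpha
    }
  }
  accel <- !is.na(fit$slope_ratio) &&
    fit$slope_ratio >= accel_ratio_threshold &&
    fit$breakpoint >= min_breakpoint_delay &&
    f_sig
  out(if (accel) "accelerated" else "steady", fit)
}

#' Classify every trajectory in a cohort
#'
#' Builds annual score trajectories, the cohort mean envelope, and applies
#' [classify_progression()] per patient.
#'
#' @param cohort An `npc_cohort`.
#' @param grid_step Trajectory grid step in years (default 1).
#' @param variant Score variant used for classification (default `"raw"`).
#' @param ... Passed to [classify_progression()].
#' @return A tibble of progression calls, one row per patient with a
#'   neurological onset.
#' @export
classify_cohort <- function(cohort, grid_step = 1, variant = "raw", ...) {
  traj <- score_trajectories(cohort, grid_step = grid_step, variant = variant)
  env <- cohort_trend(traj)$envelope
  traj |>
    group_by(.data$patient_id) |>
    dplyr::group_split() |>
    purrr::map(classify_progression, envelope = env, ...) |>
    list_rbind()
}
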
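#' Plot a Kaplan-Meier curve
#'
#' Step plot of the survival (not-yet-manifested) fraction with the
#' pointwise confidence band and, when defined, the median marked.
#'
#' @param object An `npc_km`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot npc_km
#' @export
autoplot.npc_km <- function(object, ...) {
  d <- tidy(object)
  start <- tibble(time = 0, survival = 1, lower = NA_real_, upper = NA_real_)
  d2 <- bind_rows(start, d[c("time", "survival", "lower", "upper")])
  p <- ggplot2::ggplot(d2, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "years since neurological onset",
                  y = "fraction without symptom") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
  if (any(!is.na(d$lower))) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$lower),
                                linetype = "dashed", na.rm = TRUE) +
      ggplot2::geom_step(ggplot2::aes(y = .data$upper),
                         linetype = "dashed", na.rm = TRUE)
  }
  if (!is.na(object$median)) {
    p <- p + ggplot2::geom_vline(xintercept = object$median, linetype = "dotted")
  }
  p
}

#' Plot score trajectories with an optional cohort envelope
#'
#' @param trajectories Long tibble from [score_trajectories()].
#' @param envelope Optional envelope tibble (`t`, `mean`, `sd`) from
#'   [cohort_trend()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, envelope = NULL) {
  p <- ggplot2::ggplot(trajectories,
                       ggplot2::aes(x = .data$t, y = .data$score,
                                    group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "years since neurological onset", y = "NPC-cdb score")
  if (!is.null(envelope)) {
    p <- p +
      ggplot2::geom_ribbon(
        data = envelope,
        ggplot2::aes(x = .data$t, ymin = .data$mean - .data$sd,
                     ymax = .data$mean + .data$sd),
        inherit.aes = FALSE, fill = "gold", alpha = 0.35
      ) +
      ggplot2::geom_line(
        data = envelope,
        ggplot2::aes(x = .data$t, y = .data$mean),
        inherit.aes = FALSE, linewidth = 1
      )
  }
  p
}

#' Plot the cohort trend fit
#'
#' @param object An `npc_trend`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot npc_trend
#' @export
autoplot.npc_trend <- function(object, ...) {
  env <- object$envelope
  ggplot2::ggplot(env, ggplot2::aes(x = .data$t, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "gold", alpha = 0.35) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(x = "years since neurological onset",
                  y = "mean NPC-cdb score",
                  subtitle = sprintf("y = %.2f x + %.2f (R² = %.2f)",
                                     object$slope, object$intercept,
                                     object$r_squared))
}
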
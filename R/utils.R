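# internal helpers shared across modules

# round half away from zero; base round() is half-to-even which does not
# reproduce printed registry percentages (77.5 must become 78)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

abort_npc <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "npccdb_error"), ...)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, allow_na = FALSE) {
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min) {
    abort_npc(
      sprintf("`%s` must be a single number >= %s.", name, format(min)),
      "npccdb_validation_error"
    )
  }
  invisible(x)
}

# Parent parameters (mean, sd) of a normal truncated below at `lower` whose
# *realized* moments equal (target_mean, target_sd). Feasible only when the
# coefficient of variation of (X - lower) is < 1; callers check that.
# truncnorm_parent_safe() falls back to matching the mean exactly with the
# largest spread the truncation admits when the configured sd is infeasible.
truncnorm_parent_safe <- function(target_mean, target_sd, lower = 0) {
  m <- target_mean - lower
  if (target_sd > 0 && m > 0 && target_sd / m >= 0.999) {
    target_sd <- 0.85 * m
  }
  truncnorm_parent(target_mean, target_sd, lower)
}

truncnorm_parent <- function(target_mean, target_sd, lower = 0) {
  if (target_sd == 0) {
    return(list(mean = target_mean, sd = 0, lower = lower))
  }
  m <- target_mean - lower
  if (m <= 0 || target_sd / m >= 0.999) {
    abort_npc(
      "truncated-normal moments infeasible (CV of excess over the bound must be < 1)",
      "npccdb_config_error"
    )
  }
  obj <- function(par) {
    mu <- par[1]
    sg <- exp(par[2])
    a <- -mu / sg
    lam <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
    mean_t <- mu + sg * lam
    var_t <- sg^2 * (1 + a * lam - lam^2)
    (mean_t - m)^2 + (sqrt(max(var_t, 0)) - target_sd)^2
  }
  fit <- stats::optim(c(m, log(target_sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mean = fit$par[1] + lower, sd = exp(fit$par[2]), lower = lower)
}

# inverse-CDF draw from the truncated normal described by truncnorm_parent();
# one uniform consumed per draw keeps the random stream layout stable
rtruncnorm_q <- function(u, parent) {
  if (parent$sd == 0) return(rep(parent$mean, length(u)))
  p_lo <- stats::pnorm(parent$lower, parent$mean, parent$sd)
  stats::qnorm(p_lo + u * (1 - p_lo), parent$mean, parent$sd)
}

`%||%` <- rlang::`%||%`
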
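make_traj <- function(pid, t, y) tibble::tibble(patient_id = pid, t = t, score = y)

test_that("cohort_trend recovers exact lines", {
  t <- 0:10
  tr <- dplyr::bind_rows(make_traj("a", t, 2 * t + 1), make_traj("b", t, 2 * t + 1))
  fit <- cohort_trend(tr, min_patients = 2)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  # means of y = t and y = 3t give slope 2 with perfect fit
  tr2 <- dplyr::bind_rows(make_traj("a", t, t), make_traj("b", t, 3 * t))
  fit2 <- cohort_trend(tr2, min_patients = 2)
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1)

  expect_error(cohort_trend(make_traj("a", t, t)),
               class = "npccdb_validation_error")
  expect_error(cohort_trend(tr[0, ]), class = "npccdb_validation_error")
})

test_that("two-segment fit recovers an exact piecewise trajectory", {
  t <- 0:12
  y <- ifelse(t <= 6, t, 6 + 3 * (t - 6))
  f <- fit_two_segment(make_traj("p", t, y))
  expect_equal(f$status, "ok")
  expect_equal(f$breakpoint, 6)
  expect_equal(f$slope_pre, 1, tolerance = 1e-9)
  expect_equal(f$slope_post, 3, tolerance = 1e-9)
  expect_equal(f$slope_ratio, 3, tolerance = 1e-9)
  expect_lt(f$sse_two, 1e-18)
})

test_that("a pure line is a degenerate changepoint with equal slopes", {
  t <- 0:9
  f <- fit_two_segment(make_traj("p", t, 2 * t))
  expect_equal(f$slope_pre, f$slope_post, tolerance = 1e-9)
  expect_equal(f$slope_ratio, 1, tolerance = 1e-9)
  expect_equal(f$sse_two, f$sse_one, tolerance = 1e-12)
})

test_that("short trajectories signal insufficient data, not an error", {
  f <- fit_two_segment(make_traj("p", 0:4, c(0, 1, 2, 3, 4)))
  expect_equal(f$status, "insufficient_data")
})

test_that("two-segment SSE never exceeds the one-line SSE", {
  withr::local_seed(41)
  for (i in 1:25) {
    t <- 0:sample(8:20, 1)
    y <- cumsum(stats::rpois(length(t), 2)) + stats::rnorm(length(t), 0, 0.5)
    f <- fit_two_segment(make_traj("p", t, y))
    expect_lte(f$sse_two, f$sse_one + 1e-9)
  }
})

test_that("noisy changepoint recovery succeeds in most replicates", {
  withr::local_seed(42)
  t <- 0:12
  truth <- ifelse(t <= 6, t, 6 + 3 * (t - 6))
  hits <- 0
  ratios <- c()
  for (i in 1:30) {
    y <- truth + stats::rnorm(length(t), 0, 0.5)
    f <- fit_two_segment(make_traj("p", t, y))
    hits <- hits + (abs(f$breakpoint - 6) <= 1)
    ratios <- c(ratios, f$slope_ratio)
  }
  expect_gte(hits / 30, 0.9)
  expect_gt(mean(ratios), 2.5)
  expect_lt(mean(ratios), 3.5)
})

test_that("classification follows the fulminant/accelerated/steady typology", {
  t <- 0:10
  env <- tibble::tibble(t = t, mean = 2 * t, sd = 1, n = 50)

  # everywhere strictly above the mean -> fulminant
  above <- classify_progression(make_traj("f", t, 2 * t + 1), env)
  expect_equal(above$label, "fulminant")

  # exactly the mean -> steady ("above" is strict)
  onmean <- classify_progression(make_traj("s", t, 2 * t), env)
  expect_equal(onmean$label, "steady")

  # slope 1 -> 3 elbow crossing the mean -> accelerated with ratio 3
  y <- ifelse(t <= 5, t, 5 + 3 * (t - 5))
  acc <- classify_progression(make_traj("a", t, y), env)
  expect_equal(acc$label, "accelerated")
  expect_equal(acc$breakpoint, 5)
  expect_equal(acc$slope_ratio, 3, tolerance = 1e-9)

  # grids must align with the envelope
  expect_error(
    classify_progression(make_traj("x", t + 0.5, y), env),
    class = "npccdb_validation_error"
  )

  short <- classify_progression(make_traj("i", 0:3, c(0, 1, 2, 3)), env[1:4, ])
  expect_equal(short$label, "insufficient_data")
})

test_that("progression labels are invariant to uniform weight rescaling", {
  co <- small_generated_cohort(n = 80, seed = 43)
  calls <- classify_cohort(co)
  co2 <- co
  cat_tbl <- tibble::as_tibble(co$catalog)
  cat_tbl$severity_weight <- cat_tbl$severity_weight * 7.3
  co2$catalog <- symptom_catalog(cat_tbl)
  calls2 <- classify_cohort(co2)
  expect_equal(calls$label, calls2$label)
  expect_equal(calls$breakpoint, calls2$breakpoint)
  expect_equal(calls$slope_ratio, calls2$slope_ratio, tolerance = 1e-9)
})
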
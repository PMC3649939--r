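# Independent oracles and small fixture builders shared across tests.

# Brute-force product-limit estimate in exact rational arithmetic
# (numerator/denominator integers, reduced by gcd at every step).
# Independent of km_fit: direct counting, explicit fraction products.
km_oracle <- function(durations, observed) {
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  times <- sort(unique(durations[observed]))
  num <- 1
  den <- 1
  surv_num <- numeric(length(times))
  surv_den <- numeric(length(times))
  for (j in seq_along(times)) {
    t <- times[j]
    n_i <- sum(durations >= t)
    d_i <- sum(observed & durations == t)
    num <- num * (n_i - d_i)
    den <- den * n_i
    g <- gcd(num, den)
    num <- num / g
    den <- den / g
    surv_num[j] <- num
    surv_den[j] <- den
  }
  median <- NA_real_
  hit <- which(2 * surv_num <= surv_den)
  if (length(hit) > 0) median <- times[min(hit)]
  list(time = times, survival = surv_num / surv_den,
       num = surv_num, den = surv_den, median = median)
}

# Two-sided Fisher p by hypergeometric enumeration through stats::dhyper —
# a different route than the package's lchoose-based implementation.
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b
  c1 <- a + c_
  n_tot <- a + b + c_ + d
  lo <- max(0, c1 - (n_tot - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n_tot - c1, r1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# minimal two-symptom catalog used by hand-arithmetic scoring tests;
# "ataxia" deliberately flagged as seizure-domain to exercise cleaning
tiny_catalog <- function(ataxia_seizure = FALSE) {
  symptom_catalog(tibble::tibble(
    symptom_id = c("clumsiness", "ataxia"),
    label = c("Clumsiness", "Ataxia"),
    category = c("motor", if (ataxia_seizure) "seizure" else "motor"),
    severity_weight = c(1, 3),
    seizure_domain = c(FALSE, ataxia_seizure)
  ), version = "tiny")
}

# one hand-built patient: neurological onset at 3, events at ages 3 + c(0, 2)
tiny_cohort <- function(ataxia_seizure = FALSE) {
  cohort(
    patients = tibble::tibble(
      patient_id = "A", age_at_assessment = 10, age_at_neuro_onset = 3,
      age_at_diagnosis = 5, age_at_last_visit = 10
    ),
    events = tibble::tibble(
      patient_id = c("A", "A"),
      symptom_id = c("clumsiness", "ataxia"),
      onset_age = c(3, 5)
    ),
    catalog = tiny_catalog(ataxia_seizure)
  )
}

small_generated_cohort <- function(n = 40, seed = 99, ...) {
  generate_cohort(generator_config(n, seed = seed, ...))
}
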
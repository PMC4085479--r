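RISK_FACTORS <- c("DM", "OB", "HT", "HC", "CD", "CS")

#' Cohort specification
#'
#' Describes the simulated study population: 120 subjects by default,
#' aged 25-85, 68 women and 52 men, of whom 57 are free of
#' cerebrovascular risk factors and 63 carry at least one — diabetes
#' mellitus (15), obesity (10), hypertension (40), hypercholesterolemia
#' (28), cardiac disease (24), cigarette smoking (13) — with a
#' co-occurrence pattern of 25/18/12/7/1 subjects carrying 1-5 factors.
#' For other cohort sizes the counts are scaled proportionally and
#' reconciled so that the factor totals equal the multi-factor totals.
#'
#' @param n_subjects cohort size.
#' @param prevalence named per-factor affected counts.
#' @param multi_counts subjects with exactly 1..5 factors.
#' @param age_range years, min and max.
#' @param sex_counts named counts (female, male).
#' @param seed master seed fixing roster, latent parameters and every
#'   sample of every recording generated from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 120L,
                        prevalence = NULL, multi_counts = NULL,
                        age_range = c(25, 85),
                        sex_counts = c(female = 68, male = 52),
                        seed = 1L) {
  base_prev <- c(DM = 15, OB = 10, HT = 40, HC = 28, CD = 24, CS = 13)
  base_multi <- c(25, 18, 12, 7, 1)
  r <- n_subjects / 120
  if (is.null(prevalence)) prevalence <- round(base_prev * r)
  if (is.null(multi_counts)) {
    multi_counts <- round(base_multi * r)
    # reconcile: total factor slots must equal sum(k * multi_k)
    slots <- sum(prevalence)
    fixed <- sum(seq(2, 5) * multi_counts[2:5])
    multi_counts[1] <- slots - fixed
    while (multi_counts[1] < 0) {   # too many multi-factor subjects
      j <- max(which(multi_counts[2:5] > 0)) + 1L
      multi_counts[j] <- multi_counts[j] - 1L
      multi_counts[1] <- multi_counts[1] + j
    }
  }
  if (sum(seq_along(multi_counts) * multi_counts) != sum(prevalence))
    stopf("infeasible prevalence: factor totals (%d) != multi-factor slots (%d)",
          sum(prevalence), sum(seq_along(multi_counts) * multi_counts))
  if (sum(multi_counts) > n_subjects)
    stopf("infeasible prevalence: more affected subjects than cohort size")
  if (any(prevalence > sum(multi_counts)))
    stopf("infeasible prevalence: a factor count exceeds the affected count")
  if (any(prevalence > n_subjects)) stopf("prevalence counts exceed cohort size")
  structure(list(n_subjects = as.integer(n_subjects),
                 prevalence = prevalence,
                 multi_counts = multi_counts,
                 age_range = age_range, sex_counts = sex_counts,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Randomized factor assignment with fixed per-factor totals and a fixed
# per-subject factor-count sequence; greedy quota sampling with retries.
assign_factors <- function(k_per_subject, quota, max_tries = 200L) {
  nf <- length(quota)
  for (try in seq_len(max_tries)) {
    q <- quota
    out <- matrix(FALSE, nrow = length(k_per_subject), ncol = nf,
                  dimnames = list(NULL, names(quota)))
    ok <- TRUE
    for (i in order(-k_per_subject)) {
      k <- k_per_subject[i]
      avail <- which(q > 0)
      if (length(avail) < k) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else
        sample(avail, k, prob = q[avail])
      out[i, pick] <- TRUE
      q[pick] <- q[pick] - 1L
    }
    if (ok && all(q == 0)) return(out)
  }
  stopf("could not realize the requested factor co-occurrence pattern")
}

#' Generate a subject roster with risk labels and latent baselines
#'
#' Assigns risk factors to match the spec's prevalence and
#' co-occurrence counts, then draws each subject's latent baseline
#' movement parameters from population distributions: agonist log-delay
#' `mu1 ~ N(-1.6, 0.15)` with a mild age-related slowing, log-spread
#' `sigma1 ~ N(0.35, 0.05)` truncated below, reaction latency
#' `t0 ~ N(0.22, 0.03) s`, and a per-subject amplitude scale.  The
#' same master seed always reproduces the identical roster.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` of class `cohort` with id, demographics, one
#'   logical column per risk factor, and baseline latent columns.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, "roster"))
  n <- spec$n_subjects
  n_aff <- sum(spec$multi_counts)
  k_count <- c(rep(seq_along(spec$multi_counts), spec$multi_counts),
               rep(0L, n - n_aff))
  k_count <- sample(k_count)            # shuffle affected/healthy positions
  fac <- matrix(FALSE, n, length(RISK_FACTORS),
                dimnames = list(NULL, RISK_FACTORS))
  aff <- which(k_count > 0)
  if (length(aff))
    fac[aff, ] <- assign_factors(k_count[aff], spec$prevalence[RISK_FACTORS])
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  sex <- sample(rep(names(spec$sex_counts), spec$sex_counts))[seq_len(n)]
  roster <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = age, sex = sex,
    n_factors = k_count,
    stringsAsFactors = FALSE)
  roster <- cbind(roster, as.data.frame(fac))
  # latent baselines; age slows the log-time delay slightly
  roster$baseline_mu1 <- rnorm(n, -1.6, 0.15) + 0.004 * (age - 55)
  roster$baseline_sigma1 <- pmax(0.15, rnorm(n, 0.35, 0.05))
  roster$baseline_t0 <- pmax(0.10, rnorm(n, 0.22, 0.03))
  roster$d_scale <- pmax(0.7, rnorm(n, 1, 0.08))
  # effect-adjusted values default to the baselines (identity effects)
  roster$mu1 <- roster$baseline_mu1
  roster$sigma1 <- roster$baseline_sigma1
  roster$t0 <- roster$baseline_t0
  roster$mad_mult <- 1
  class(roster) <- c("cohort", "data.frame")
  attr(roster, "spec") <- spec
  roster
}

#' Risk-factor effect configuration
#'
#' The generative link between carrying a risk factor and the latent
#' movement parameters — an explicit, documented fiction whose only job
#' is to give the pipeline a recoverable signal: per factor, an additive
#' shift of the log-time delay `mu1` (timing slowing), a multiplicative
#' factor on `sigma1` (response spread), an additive shift of the
#' reaction latency `t0` (s), and a multiplicative factor on the
#' within-subject trial spread.  Effects of co-occurring factors combine
#' additively on the log scale (multiplicatively for the factors).  An
#' empty call is the identity (zero-effect) configuration.
#'
#' @param ... per-factor entries, e.g.
#'   `DM = list(mu1_shift = 0.1, t0_shift = 0.03)`; omitted fields
#'   default to the identity.
#' @return list of class `effect_config`.
#' @export
effect_config <- function(...) {
  entries <- list(...)
  if (length(entries) && is.null(names(entries)))
    stopf("effects must be named by risk factor")
  bad <- setdiff(names(entries), RISK_FACTORS)
  if (length(bad)) stopf("unknown risk factor(s): %s", paste(bad, collapse = ", "))
  full <- setNames(vector("list", length(RISK_FACTORS)), RISK_FACTORS)
  for (f in RISK_FACTORS) {
    e <- entries[[f]] %||% list()
    full[[f]] <- list(
      mu1_shift = e$mu1_shift %||% 0,
      sigma1_mult = e$sigma1_mult %||% 1,
      t0_shift = e$t0_shift %||% 0,
      mad_mult = e$mad_mult %||% 1)
    if (full[[f]]$sigma1_mult <= 0 || full[[f]]$mad_mult <= 0)
      stopf("multiplicative effect factors must be > 0")
  }
  structure(full, class = "effect_config")
}

#' Default moderate risk effects
#'
#' A documented default linking each factor to a mild deterioration of
#' timing and consistency, sized so that the simulated pipeline lands in
#' the 0.6-0.9 AUC range typical of the real battery.
#' @return an [effect_config()].
#' @export
default_risk_effects <- function() {
  effect_config(
    DM = list(mu1_shift = 0.12, sigma1_mult = 1.15, t0_shift = 0.035, mad_mult = 1.4),
    CD = list(mu1_shift = 0.10, sigma1_mult = 1.12, t0_shift = 0.030, mad_mult = 1.3),
    HT = list(mu1_shift = 0.07, sigma1_mult = 1.08, t0_shift = 0.020, mad_mult = 1.2),
    HC = list(mu1_shift = 0.06, sigma1_mult = 1.06, t0_shift = 0.015, mad_mult = 1.2),
    OB = list(mu1_shift = 0.06, sigma1_mult = 1.08, t0_shift = 0.020, mad_mult = 1.2),
    CS = list(mu1_shift = 0.03, sigma1_mult = 1.03, t0_shift = 0.008, mad_mult = 1.1))
}

#' Strong diabetes-only effect used in sensitivity studies
#' @return an [effect_config()] in which only DM carries (large) effects.
#' @export
strong_dm_effects <- function() {
  effect_config(DM = list(mu1_shift = 0.25, sigma1_mult = 1.3,
                          t0_shift = 0.06, mad_mult = 1.5))
}

#' Apply risk effects to a cohort's latent parameters
#'
#' Shifts each subject's effect-adjusted latent columns (`mu1`,
#' `sigma1`, `t0`, `mad_mult`) according to the factors the subject
#' carries; additive shifts add, multiplicative factors multiply
#' (i.e. combine additively on the log scale).  A zero-effect
#' configuration returns the baselines unchanged.
#'
#' @param cohort a [generate_cohort()] roster.
#' @param effects an [effect_config()].
#' @return the cohort with updated latent columns.
#' @export
apply_risk_effects <- function(cohort, effects = effect_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(effects, "effect_config"))
  mu_shift <- t_shift <- numeric(nrow(cohort))
  s_mult <- m_mult <- rep(1, nrow(cohort))
  for (f in RISK_FACTORS) {
    has <- cohort[[f]]
    e <- effects[[f]]
    mu_shift[has] <- mu_shift[has] + e$mu1_shift
    t_shift[has] <- t_shift[has] + e$t0_shift
    s_mult[has] <- s_mult[has] * e$sigma1_mult
    m_mult[has] <- m_mult[has] * e$mad_mult
  }
  cohort$mu1 <- cohort$baseline_mu1 + mu_shift
  cohort$sigma1 <- cohort$baseline_sigma1 * s_mult
  cohort$t0 <- cohort$baseline_t0 + t_shift
  cohort$mad_mult <- m_mult
  cohort
}

#' Draw exponentially distributed foreperiod delays
#'
#' The delay between trial arming and stimulus emission has a flat
#' hazard: regardless of how long the subject has waited, the
#' probability of emission in the next instant is constant.  Draws are
#' exponential with rate `rate` and redrawn until they fall in
#' `(0, max_s]`, so a delay never exceeds 10 s.
#'
#' @param n number of delays.
#' @param rate hazard rate (1/s) before truncation.
#' @param max_s upper truncation bound (s).
#' @return numeric vector of delays.
#' @export
stimulus_delay <- function(n = 1L, rate = 0.4, max_s = 10) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- rexp(n - length(out), rate)
    out <- c(out, d[d > 0 & d <= max_s])
  }
  out
}
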
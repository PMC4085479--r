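# Trapezoidal quadrature used by the oracle computations in the tests.
trapz <- function(t, y) {
  n <- length(t)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n])) / 2
}

# Shared generators for synthesis/extraction round-trip tests.  The
# delta-lognormal draw ranges span rapid reaching movements with an
# antagonist braking burst arriving distinctly after the agonist.

random_delta_params <- function() {
  t0 <- runif(1, 0.05, 0.3)
  D1 <- runif(1, 120, 200)
  mu1 <- runif(1, -1.9, -1.3)
  s1 <- runif(1, 0.25, 0.45)
  D2 <- D1 * runif(1, 0.08, 0.25)
  mu2 <- mu1 + runif(1, 0.2, 0.5)
  s2 <- s1 * runif(1, 1, 1.4)
  delta_lognormal_params(t0, D1, mu1, s1, D2, mu2, s2)
}

delta_trial_of <- function(p, rate = 200, quantum = 0.01) {
  mu2 <- p$antagonist$mu; s2 <- p$antagonist$sigma
  dur <- ceiling((p$t0 + max(qlnorm(0.9995, p$agonist$mu, p$agonist$sigma),
                             qlnorm(0.9995, mu2, s2)) + 0.1) * rate) / rate
  synthesize_trial(p, sampling_spec(rate = rate, duration = dur,
                                    quantum = quantum))
}

delta_param_vec <- function(p) {
  c(t0 = p$t0, D1 = p$agonist$D, mu1 = p$agonist$mu, s1 = p$agonist$sigma,
    D2 = p$antagonist$D, mu2 = p$antagonist$mu, s2 = p$antagonist$sigma)
}

# A well-separated three-stroke triangle (task #6 archetype).
triangle_params <- function(size = 90, gap = 0.32) {
  headings <- c(0, 2 * pi / 3, 4 * pi / 3)
  t0s <- 0.3 + cumsum(c(0, gap, gap))
  sigma_lognormal_params(lapply(1:3, function(i)
    sigma_stroke(t0s[i], D = size, mu = -1.7, sigma = 0.28,
                 theta_s = headings[i], theta_e = headings[i])))
}

# An alternating omega-lognormal train with n_lobes components.
oscillation_params <- function(n_lobes = 10, half_period = 0.35,
                               D = 30, sigma = 0.2) {
  t0s <- 0.5 + (seq_len(n_lobes) - 1) * half_period
  comps <- lapply(t0s, function(t0)
    lognormal_component(t0, D, log(0.5 * half_period) + sigma^2, sigma))
  omega_lognormal_params(comps[seq(1, n_lobes, 2)],
                         if (n_lobes > 1) comps[seq(2, n_lobes, 2)] else list())
}

# Small synthetic feature cohort for classifier tests: `k_noise` noise
# features plus optionally one informative feature with the given effect
# size (in within-class SD units).
feature_cohort <- function(n = 60, n_pos = 15, k_noise = 19, effect = 0) {
  y <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))
  x <- as.data.frame(matrix(rnorm(n * k_noise), n))
  names(x) <- sprintf("noise_%02d", seq_len(k_noise))
  if (effect != 0) x$informative <- rnorm(n) + effect * y
  list(x = x, y = y)
}
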
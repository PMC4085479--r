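# Append a short pen-up tail to a recording: the pen leaves the tablet
# between trials, which the validity rules require.
add_pen_tail <- function(rec, n_tail = 6L) {
  dt <- median(diff(rec$t))
  n <- length(rec$t)
  tt <- c(rec$t, rec$t[n] + dt * seq_len(n_tail))
  trial_recording(tt,
                  c(rec$x, rep(rec$x[n], n_tail)),
                  c(rec$y, rep(rec$y[n], n_tail)),
                  c(rec$pen_down, rep(FALSE, n_tail)),
                  meta = rec$meta)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# One rapid reaching trial (SRT/CRT/SAT archetype): delta-lognormal
# speed profile triggered after an exponentially distributed foreperiod.
make_point_trial <- function(subj, cfg, idx, amp, direction = 0,
                             mt_target = NA, inject = "none", rate = 200) {
  stim <- stimulus_delay(1L)
  latency <- subj$t0 + (cfg$decision_delay %||% 0) +
    rnorm(1, 0, 0.02 * subj$mad_mult)
  latency <- max(0.12, latency)
  t0 <- stim + latency
  if (inject == "anticipated") {
    # the motion onset (not just the command) must precede the stimulus
    stim <- stim + 0.5
    t0 <- max(0.05, stim - runif(1, 0.15, 0.3))
  }
  if (inject == "short_amp") amp <- runif(1, 95, 124)
  mu1 <- clamp(subj$mu1 + rnorm(1, 0, 0.06 * subj$mad_mult), -2.6, -0.7)
  if (is.finite(mt_target)) {
    # speed/accuracy trade-off: movement time grows with task difficulty
    mu1 <- clamp(log(mt_target / 1.3) + rnorm(1, 0, 0.05 * subj$mad_mult),
                 -2.8, -0.3)
  }
  sigma1 <- clamp(subj$sigma1 * exp(rnorm(1, 0, 0.08 * subj$mad_mult)), 0.18, 0.8)
  d2f <- clamp(rnorm(1, 0.15, 0.03), 0.04, 0.35)
  D1 <- amp / (1 - d2f)
  D2 <- D1 * d2f
  mu2 <- mu1 + 0.3 + rnorm(1, 0, 0.05)
  sigma2 <- clamp(sigma1 * 1.2, 0.18, 0.9)
  p <- delta_lognormal_params(t0, D1, mu1, sigma1, D2, mu2, sigma2)
  tail_t <- max(stats::qlnorm(0.9995, mu1, sigma1), stats::qlnorm(0.9995, mu2, sigma2))
  dur <- ceiling((t0 + tail_t + 0.1) * rate) / rate
  rec <- synthesize_trial(p, sampling_spec(rate = rate, duration = dur),
                          origin = c(0, 0), direction = direction,
                          meta = list(subject_id = subj$subject_id,
                                      task_id = cfg$task_id,
                                      trial_index = idx,
                                      stimulus_onset = stim,
                                      stimulus_kind = cfg$stimulus,
                                      learning = FALSE,
                                      injected = inject,
                                      true_params = list(t0 = t0, D1 = D1,
                                                         mu1 = mu1, sigma1 = sigma1,
                                                         D2 = D2, mu2 = mu2,
                                                         sigma2 = sigma2)))
  add_pen_tail(rec)
}

make_triangle_trial <- function(subj, cfg, idx, size, rotation, rate = 200) {
  stim <- stimulus_delay(1L)
  latency <- max(0.12, subj$t0 + rnorm(1, 0, 0.02 * subj$mad_mult))
  headings <- if (rotation == "ccw") c(0, 2 * pi / 3, 4 * pi / 3)
              else c(0, -2 * pi / 3, -4 * pi / 3)
  t0s <- stim + latency + cumsum(c(0, 0.30 + rnorm(2, 0, 0.02)))
  strokes <- lapply(1:3, function(i) {
    sigma_stroke(t0s[i],
                 D = size * (1 + rnorm(1, 0, 0.02)),
                 mu = clamp(subj$mu1 + rnorm(1, 0, 0.05 * subj$mad_mult), -2.4, -1.0),
                 sigma = clamp(subj$sigma1 * exp(rnorm(1, 0, 0.06)), 0.2, 0.5),
                 theta_s = headings[i] + rnorm(1, 0, 0.02),
                 theta_e = headings[i] + rnorm(1, 0, 0.02))
  })
  p <- sigma_lognormal_params(strokes)
  dur <- ceiling((t0s[3] + 0.5) * rate) / rate
  rec <- synthesize_trial(p, sampling_spec(rate = rate, duration = dur),
                          meta = list(subject_id = subj$subject_id,
                                      task_id = cfg$task_id, trial_index = idx,
                                      stimulus_onset = stim,
                                      stimulus_kind = cfg$stimulus,
                                      learning = FALSE, injected = "none",
                                      size = size, rotation = rotation))
  add_pen_tail(rec)
}

# Fixed per-subject pseudo-signature template: a seeded 8-25 component
# sigma-lognormal pattern, redrawn with small jitter at every trial.
signature_template <- function(subj) {
  set.seed(derive_seed(4242L, subj$subject_id, round(subj$baseline_mu1 * 1e6)))
  K <- sample(8:25, 1)
  list(K = K,
       gaps = runif(K, 0.06, 0.14),
       D = runif(K, 5, 40),
       mu = runif(K, -2.2, -1.5),
       sigma = runif(K, 0.18, 0.45),
       theta_s = runif(K, -pi, pi),
       sweep = runif(K, -0.8, 0.8))
}

make_signature_trial <- function(subj, cfg, idx, session_seed, rate = 200) {
  tpl <- signature_template(subj)
  # template lookup resets the stream; restore a trial-specific one
  set.seed(derive_seed(session_seed, "sigtrial", cfg$task_id, idx))
  j <- subj$mad_mult
  t0s <- 0.3 + cumsum(tpl$gaps * exp(rnorm(tpl$K, 0, 0.05 * j)))
  strokes <- lapply(seq_len(tpl$K), function(i) {
    th_s <- tpl$theta_s[i] + rnorm(1, 0, 0.05 * j)
    sigma_stroke(t0s[i],
                 D = tpl$D[i] * exp(rnorm(1, 0, 0.05 * j)),
                 mu = clamp(tpl$mu[i] + subj$mu1 - subj$baseline_mu1 +
                              rnorm(1, 0, 0.04 * j), -2.6, -1.0),
                 sigma = clamp(tpl$sigma[i] * subj$sigma1 / subj$baseline_sigma1 *
                                 exp(rnorm(1, 0, 0.04 * j)), 0.15, 0.6),
                 theta_s = th_s, theta_e = th_s + tpl$sweep[i])
  })
  ord <- order(vapply(strokes, `[[`, 0, "t0"))
  p <- sigma_lognormal_params(strokes[ord])
  dur <- ceiling((max(t0s) + 0.6) * rate) / rate
  rec <- synthesize_trial(p, sampling_spec(rate = rate, duration = dur),
                          meta = list(subject_id = subj$subject_id,
                                      task_id = cfg$task_id, trial_index = idx,
                                      stimulus_kind = "none",
                                      learning = FALSE, injected = "none"))
  add_pen_tail(rec)
}

make_oscillation_trial <- function(subj, cfg, idx, rate = 200) {
  stim <- 0.5
  start <- stim + max(0.12, subj$t0 + rnorm(1, 0, 0.02 * subj$mad_mult))
  paced_end <- stim + cfg$duration
  total_end <- paced_end + (cfg$continuation %||% 0)
  if (cfg$kind == "metronome") {
    h_base <- cfg$half_period
  } else {
    # maximal-speed oscillation: half-period tied to the subject's latent
    # timing, slower subjects oscillate slower
    h_base <- clamp(0.30 * exp(subj$mu1 + 1.6) + rnorm(1, 0, 0.02), 0.18, 0.6)
  }
  t0s <- numeric(0)
  tcur <- start
  while (tcur < total_end - 0.35) {
    t0s <- c(t0s, tcur)
    h <- if (cfg$kind == "metronome" && tcur >= paced_end)
      h_base * exp(rnorm(1, 0, 0.05 * subj$mad_mult))   # unpaced drift
    else h_base * exp(rnorm(1, 0, 0.02 * subj$mad_mult))
    tcur <- tcur + h
  }
  K <- length(t0s)
  sigma_o <- 0.2
  comps <- lapply(seq_len(K), function(i)
    lognormal_component(t0s[i],
                        D = max(5, 30 + rnorm(1, 0, 2 * subj$mad_mult)),
                        mu = log(0.5 * h_base) + sigma_o^2 + rnorm(1, 0, 0.03),
                        sigma = clamp(sigma_o * exp(rnorm(1, 0, 0.05)), 0.12, 0.4)))
  fwd <- comps[seq(1, K, by = 2)]
  bwd <- if (K >= 2) comps[seq(2, K, by = 2)] else list()
  p <- omega_lognormal_params(fwd, bwd)
  dur <- ceiling((total_end + 0.6) * rate) / rate
  meta <- list(subject_id = subj$subject_id, task_id = cfg$task_id,
               trial_index = idx, stimulus_onset = stim,
               stimulus_kind = cfg$stimulus, learning = FALSE,
               injected = "none", half_period = h_base)
  if (cfg$kind == "metronome")
    meta$segments <- list(adaptation = c(stim, paced_end),
                          steady = c(paced_end, total_end))
  rec <- synthesize_trial(p, sampling_spec(rate = rate, duration = dur),
                          meta = meta)
  add_pen_tail(rec)
}

#' Simulate one subject's session for one task
#'
#' Generates the task's full trial list with per-trial parameter jitter
#' drawn around the subject's (effect-adjusted) latent baselines.
#' Point-stroke tasks draw foreperiods from [stimulus_delay()], choice
#' trials add a decisional latency increment and a random direction,
#' the speed/accuracy task scales movement time with the Fitts index of
#' difficulty, stroke-sequence tasks produce triangle or signature
#' patterns, and oscillation tasks produce alternating lognormal trains
#' (metronome-paced with an unpaced continuation for task #8).  A
#' configurable fraction of point-stroke trials violates the validity
#' rules (anticipated starts, short amplitudes) to exercise the
#' validator.
#'
#' @param subj one-row subject slice of a [generate_cohort()] roster
#'   (after [apply_risk_effects()]).
#' @param task a task id (`"1"`..`"9"`) or [task_config()].
#' @param seed seed for this subject-task stream.
#' @param invalid_frac fraction of point-stroke trials with an injected
#'   protocol violation.
#' @param n_trials optional trial-count override (point-stroke tasks).
#' @param rate sampling rate (Hz).
#' @return list of [trial_recording()] objects.
#' @export
generate_session <- function(subj, task, seed = 1L, invalid_frac = 0.08,
                             n_trials = NULL, rate = 200) {
  cfg <- if (inherits(task, "task_config")) task else task_config(task)
  set.seed(derive_seed(seed, "session", subj$subject_id, cfg$task_id))
  trials <- list()
  if (cfg$archetype == "point_stroke" && cfg$kind != "sat") {
    # the protocol records until the required number of VALID trials is
    # reached, so sessions keep going past injected violations
    target <- n_trials %||% cfg$min_valid_trials %||% cfg$n_trials
    n_valid <- 0L; i <- 0L
    while (n_valid < target && i < 3L * target) {
      i <- i + 1L
      inject <- if (runif(1) < invalid_frac)
        sample(c("anticipated", "short_amp"), 1) else "none"
      direction <- if (cfg$kind == "crt") sample(c(0, pi), 1) else 0
      rec <- make_point_trial(subj, cfg, i,
                              amp = runif(1, 137, 168) *
                                clamp(subj$d_scale, 0.97, 1.15),
                              direction = direction,
                              inject = inject, rate = rate)
      # the generator knows its ground truth: a trial is valid by
      # construction unless a protocol violation was injected (the tests
      # verify this against validate_trial independently)
      if (inject == "none") n_valid <- n_valid + 1L
      trials[[i]] <- rec
    }
  } else if (cfg$archetype == "point_stroke") {       # speed/accuracy
    grid <- expand.grid(rep = seq_len(cfg$repetitions),
                        distance = cfg$distances, width = cfg$widths)
    for (i in seq_len(nrow(grid))) {
      id_diff <- log2(2 * grid$distance[i] / grid$width[i])
      mt <- (0.10 + 0.07 * id_diff) * clamp(exp(subj$mu1 + 1.6), 0.8, 1.3)
      trials[[i]] <- make_point_trial(subj, cfg, i, amp = grid$distance[i],
                                      mt_target = mt, inject = "none",
                                      rate = rate)
      trials[[i]]$meta$distance <- grid$distance[i]
      trials[[i]]$meta$width <- grid$width[i]
    }
  } else if (cfg$archetype == "stroke_sequence" && cfg$kind == "triangle") {
    grid <- expand.grid(rep = seq_len(cfg$repetitions),
                        rotation = cfg$rotations, size = cfg$sizes,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid)))
      trials[[i]] <- make_triangle_trial(subj, cfg, i, grid$size[i],
                                         grid$rotation[i], rate = rate)
  } else if (cfg$archetype == "stroke_sequence") {    # signatures
    n <- n_trials %||% cfg$n_trials
    for (i in seq_len(n))
      trials[[i]] <- make_signature_trial(subj, cfg, i,
                                          session_seed = derive_seed(
                                            seed, "session", subj$subject_id,
                                            cfg$task_id),
                                          rate = rate)
  } else {                                            # oscillation
    n <- n_trials %||% cfg$n_trials
    for (i in seq_len(n)) {
      trials[[i]] <- make_oscillation_trial(subj, cfg, i, rate = rate)
      if (cfg$kind == "metronome" && i == 1L)
        trials[[i]]$meta$learning <- TRUE    # first metronome trial is practice
    }
  }
  trials
}
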
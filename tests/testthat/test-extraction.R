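test_that("speed profiles reproduce uniform motion and respect pen-up gaps", {
  t <- seq(0, 1, by = 0.005)
  rec <- trial_recording(t, 100 * t, rep(0, length(t)))
  sp <- compute_speed_profile(rec, smooth = FALSE)
  interior <- sp$v[3:(length(sp$v) - 2)]
  expect_equal(interior, rep(100, length(interior)), tolerance = 1e-9)
  sps <- compute_speed_profile(rec)     # filtered: still flat to 1e-6
  expect_equal(sps$v[5:(length(sps$v) - 4)],
               rep(100, length(sps$v) - 8), tolerance = 1e-6)
  # a pen-up gap splits the profile; the position jump across it must not
  # leak into any velocity sample
  down <- rep(TRUE, length(t)); down[90:110] <- FALSE
  x2 <- 100 * t; x2[111:length(t)] <- x2[111:length(t)] + 500
  rec2 <- trial_recording(t, x2, rep(0, length(t)), down)
  sp2 <- compute_speed_profile(rec2, smooth = FALSE)
  expect_equal(sort(unique(sp2$segment)), c(1, 2))
  expect_lt(max(sp2$v), 150)
  expect_error(compute_speed_profile(
    trial_recording(t[1:5], t[1:5], t[1:5])), "insufficient")
})

test_that("reconstruction SNR measures residual power in dB", {
  v <- sin(seq(0, 10, by = 0.01))^2 * 100
  expect_equal(reconstruction_snr(v, v), 100)
  expect_equal(reconstruction_snr(v, rep(0, length(v))), 0)
  set.seed(5)
  noise <- rnorm(length(v))
  noise <- noise * sqrt(sum(v^2) / sum(noise^2) / 10^(20 / 10))
  expect_equal(reconstruction_snr(v, v + noise), 20, tolerance = 0.5)
  expect_error(reconstruction_snr(rep(0, 10), rep(0, 10)), "zero power")
})

test_that("delta-lognormal fits recover the generating parameters", {
  p <- delta_lognormal_params(0.05, 150, -1.6, 0.35, 30, -1.3, 0.45)
  rec <- delta_trial_of(p)
  sp <- compute_speed_profile(rec, smooth = FALSE)
  fit <- fit_delta_lognormal(sp)
  expect_gte(fit$snr_db, 40)
  expect_true(fit$converged)
  est <- delta_param_vec(fit$params)
  expect_equal(est[["t0"]], 0.05, tolerance = 0.005 / 0.05)
  expect_equal(est[["D1"]], 150, tolerance = 0.02)
  expect_equal(est[["mu1"]], -1.6, tolerance = 0.05 / 1.6)
  expect_equal(est[["s1"]], 0.35, tolerance = 0.05 / 0.35)
  # idempotence: refitting the model's own reconstruction changes nothing
  rec2 <- delta_trial_of(fit$params, quantum = 0)
  fit2 <- fit_delta_lognormal(compute_speed_profile(rec2, smooth = FALSE))
  expect_equal(delta_param_vec(fit2$params), est, tolerance = 1e-3)
})

test_that("fitted SNR degrades monotonically as observation noise grows", {
  p <- delta_lognormal_params(0.08, 140, -1.65, 0.32, 20, -1.35, 0.4)
  rec <- delta_trial_of(p)
  sp <- compute_speed_profile(rec, smooth = FALSE)
  snrs <- vapply(seq_along(c(35, 25, 15)), function(k) {
    target <- c(35, 25, 15)[k]
    set.seed(100 + k)
    noise <- rnorm(length(sp$v))
    noise <- noise * sqrt(sum(sp$v^2) / sum(noise^2) / 10^(target / 10))
    spn <- sp
    spn$v <- pmax(sp$v + noise, 0)
    spn$vx <- spn$vy <- NULL
    spn$provenance$quantum <- NA
    fit_delta_lognormal(spn)$snr_db
  }, 0)
  expect_true(all(diff(snrs) < 0))
})

test_that("noisy trials still localize the command onset", {
  # white measurement noise injected at the position level, sized for a
  # 25 dB velocity-domain SNR, then the standard smoothed profile: the
  # median onset error over seeded replicates stays below 10 ms
  set.seed(31)
  errs <- vapply(1:10, function(k) {
    p <- random_delta_params()
    rec <- delta_trial_of(p)
    sp0 <- compute_speed_profile(rec, smooth = FALSE)
    sigma_v <- sqrt(mean(sp0$v^2)) / 10^(25 / 20)
    sigma_x <- sigma_v * sqrt(2) / 200      # central-difference gain
    recn <- rec
    recn$x <- rec$x + rnorm(length(rec$x), 0, sigma_x)
    recn$y <- rec$y + rnorm(length(rec$y), 0, sigma_x)
    recn$meta$sampling$quantum <- NA        # noise, not quantization
    fit <- fit_delta_lognormal(compute_speed_profile(recn, cutoff_hz = 15))
    abs(fit$params$t0 - p$t0)
  }, 0)
  expect_lt(median(errs), 0.010)
})

test_that("sigma-lognormal extraction recovers stroke structure", {
  # a single stroke yields exactly one component
  p1 <- sigma_lognormal_params(list(sigma_stroke(0.2, 120, -1.6, 0.3, 0.4, 0.4)))
  rec1 <- synthesize_trial(p1, sampling_spec(rate = 200, duration = 1.2))
  fit1 <- fit_sigma_lognormal(compute_speed_profile(rec1, smooth = FALSE))
  expect_length(fit1$params$strokes, 1)
  expect_gte(fit1$snr_db, 25)
  # three-stroke triangle: three components at 25 dB or better
  p3 <- triangle_params(size = 90)
  rec3 <- synthesize_trial(p3, sampling_spec(rate = 200, duration = 2.2))
  fit3 <- fit_sigma_lognormal(compute_speed_profile(rec3, smooth = FALSE))
  expect_length(fit3$params$strokes, 3)
  expect_gte(fit3$snr_db, 25)
  # the loop bound caps the component count
  fit_cap <- fit_sigma_lognormal(compute_speed_profile(rec3, smooth = FALSE),
                                 max_components = 2L)
  expect_lte(length(fit_cap$params$strokes), 2)
})

test_that("omega-lognormal extraction handles oscillation trains", {
  p <- oscillation_params(n_lobes = 10, half_period = 0.35)
  rec <- synthesize_trial(p, sampling_spec(rate = 200, duration = 4.6))
  sp <- compute_speed_profile(rec, smooth = FALSE)
  fit <- fit_omega_lognormal(sp)
  N <- length(fit$params$forward); M <- length(fit$params$backward)
  expect_equal(N + M, 10)
  expect_lte(abs(N - M), 1)
  expect_gte(fit$snr_db, 20)
  # an explicit axis equal to the movement axis gives the same model
  fit_x <- fit_omega_lognormal(sp, axis = c(1, 0))
  expect_equal(length(fit_x$params$forward), N)
  expect_equal(fit_x$params$forward[[1]]$t0, fit$params$forward[[1]]$t0,
               tolerance = 1e-6)
  expect_error(
    fit_omega_lognormal(compute_speed_profile(
      synthesize_trial(
        sigma_lognormal_params(list(sigma_stroke(0.2, 100, -1.6, 0.3, 0, 0))),
        sampling_spec(rate = 200, duration = 1)), smooth = FALSE)),
    "insufficient oscillation")
})

test_that("trial validation applies the protocol rejection rules", {
  subj <- list(subject_id = "S001", t0 = 0.22, mu1 = -1.6, sigma1 = 0.35,
               mad_mult = 1, d_scale = 1)
  mk <- function(amp, t0_offset = 0.3, stim = 1) {
    p <- delta_lognormal_params(stim + t0_offset, amp / 0.85, -1.6, 0.35,
                                amp / 0.85 * 0.15, -1.3, 0.42)
    rec <- synthesize_trial(p, sampling_spec(rate = 200,
                                             duration = stim + t0_offset + 1))
    rec$meta$task_id <- "2"; rec$meta$stimulus_onset <- stim
    n <- length(rec$t)
    rec$pen_down[(n - 3):n] <- FALSE
    rec
  }
  ok <- validate_trial(mk(150))
  expect_true(ok$valid)
  expect_length(ok$reasons, 0)
  short <- validate_trial(mk(120))
  expect_false(short$valid)
  expect_true("amplitude_below_minimum" %in% short$reasons)
  early <- validate_trial(mk(150, t0_offset = -0.15))
  expect_false(early$valid)
  expect_true("anticipated_start" %in% early$reasons)
  # purity: identical recording, identical report
  r <- mk(150)
  expect_identical(validate_trial(r), validate_trial(r))
  # missing pen lift at the end of the recording
  r2 <- mk(150); r2$pen_down[] <- TRUE
  expect_true("no_pen_lift_between_trials" %in% validate_trial(r2)$reasons)
  expect_error(validate_trial(trial_recording(1:10 / 10, 1:10, 1:10,
                                              meta = list(task_id = "99"))),
               "unknown task")
})
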
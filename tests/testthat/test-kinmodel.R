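test_that("lognormal component density is supported on (t0, Inf) and normalized", {
  c1 <- lognormal_component(0.2, 100, -1.7, 0.4)
  expect_identical(eval_lognormal(0.1, c1), 0)
  expect_identical(eval_lognormal(0.2, c1), 0)
  tt <- seq(0.2, 100.2, by = 1e-4)
  expect_equal(trapz(tt, eval_lognormal(tt, c1)), 1, tolerance = 1e-6)
  # property: normalization holds across the valid shape range
  set.seed(11)
  for (i in 1:12) {
    mu <- runif(1, -3, 0); sg <- runif(1, 0.05, 1)
    ci <- lognormal_component(0, 1, mu, sg)
    tt <- seq(0, 100, by = 5e-5)
    expect_equal(trapz(tt, eval_lognormal(tt, ci)), 1, tolerance = 1e-6)
  }
})

test_that("lognormal mode sits at t0 + exp(mu - sigma^2)", {
  c1 <- lognormal_component(0, 1, -1.7, 0.4)
  tt <- seq(0.05, 0.4, by = 1e-5)
  i <- which.max(eval_lognormal(tt, c1))
  expect_lt(abs(tt[i] - exp(-1.7 - 0.4^2)), 1.1e-5)   # within one grid step
  expect_equal(tt[i], 0.1556726, tolerance = 1e-4)
})

test_that("component construction rejects invalid shapes", {
  expect_error(lognormal_component(0, 100, -1.7, 0), "sigma")
  expect_error(lognormal_component(0, 100, -1.7, -0.2), "sigma")
  expect_error(lognormal_component(0, -5, -1.7, 0.3), "D must be")
  expect_warning(lognormal_component(0, 100, -5, 0.3), "typical")
})

test_that("delta-lognormal speed superposes agonist and antagonist", {
  p0 <- delta_lognormal_params(0.05, 150, -1.6, 0.35, 0, -1.3, 0.45)
  tt <- seq(0, 2, by = 1e-3)
  expect_equal(delta_lognormal_speed(tt, p0),
               150 * eval_lognormal(tt, p0$agonist))
  # frozen dense-grid oracle for the worked parameter set
  p <- delta_lognormal_params(0.05, 150, -1.6, 0.35, 30, -1.3, 0.45)
  tt <- seq(0.05, 3, by = 1e-5)
  v <- delta_lognormal_speed(tt, p)
  expect_equal(max(v), 805.288, tolerance = 1e-4)
  expect_equal(tt[which.max(v)], 0.22598, tolerance = 1e-3)
  expect_error(delta_lognormal_params(0.05, 100, -1.6, 0.35, 120, -1.3, 0.45),
               "D1 > D2")
})

test_that("delta-lognormal displacement equals D1 - D2", {
  set.seed(21)
  for (i in 1:20) {
    p <- random_delta_params()
    tt <- seq(0, p$t0 + 20, by = 5e-4)
    expect_equal(trapz(tt, delta_lognormal_speed(tt, p)),
                 p$agonist$D - p$antagonist$D,
                 tolerance = 1e-3)
  }
})

test_that("stroke direction follows the erf law between theta_s and theta_e", {
  s <- sigma_stroke(0.1, 80, -1.5, 0.3, theta_s = 0, theta_e = pi / 2)
  # erf argument zero at t = t0 + exp(mu): direction at the angular midpoint
  expect_equal(stroke_direction(0.1 + exp(-1.5), s), pi / 4)
  # frozen reference-erf value at t = t0 + 0.5
  expect_equal(stroke_direction(0.6, s), 1.5651762, tolerance = 1e-6)
  # limit conventions
  expect_equal(stroke_direction(c(0.05, 0.1), s), c(0, 0))
  expect_equal(stroke_direction(1e6, s), pi / 2, tolerance = 1e-9)
  s2 <- sigma_stroke(0.1, 80, -1.5, 0.3, 1, 1)
  expect_equal(stroke_direction(seq(0, 2, 0.1), s2), rep(1, 21))
})

test_that("sigma-lognormal velocity superposes directed strokes", {
  s <- sigma_stroke(0.1, 80, -1.6, 0.3, 0, 0)
  p <- sigma_lognormal_params(list(s))
  tt <- seq(0, 2, by = 1e-3)
  v <- sigma_lognormal_velocity(tt, p)
  expect_equal(v$vy, rep(0, length(tt)))
  expect_equal(v$vx, 80 * eval_lognormal(tt, s))
  # lognormal skew: the speed lobe is not symmetric about its peak
  i <- which.max(v$vx)
  k <- min(i - 1, length(tt) - i)
  expect_gt(max(abs(v$vx[(i - k):(i + k)] - rev(v$vx[(i - k):(i + k)]))),
            0.05 * max(v$vx))
  # two well-separated identical strokes travel twice the distance
  p2 <- sigma_lognormal_params(list(
    sigma_stroke(0.1, 80, -1.6, 0.3, 0, 0),
    sigma_stroke(1.6, 80, -1.6, 0.3, 0, 0)))
  tt <- seq(0, 4, by = 5e-4)
  v2 <- sigma_lognormal_velocity(tt, p2)
  expect_equal(trapz(tt, sqrt(v2$vx^2 + v2$vy^2)), 160, tolerance = 0.01)
  expect_error(sigma_lognormal_params(list()), "at least one")
  expect_error(sigma_lognormal_params(list(
    sigma_stroke(1, 10, -1.6, 0.3, 0, 0),
    sigma_stroke(0.5, 10, -1.6, 0.3, 0, 0))), "ordered")
})

test_that("a closed stroke sequence returns to its start point", {
  p <- triangle_params(size = 90)
  tt <- seq(0, 3, by = 5e-4)
  v <- sigma_lognormal_velocity(tt, p)
  end_err <- sqrt(trapz(tt, v$vx)^2 + trapz(tt, v$vy)^2)
  path <- trapz(tt, sqrt(v$vx^2 + v$vy^2))
  expect_lt(end_err, 0.01 * path)
})

test_that("omega-lognormal alternating trains behave as specified", {
  # degenerate single forward component reduces to one lognormal
  p1 <- omega_lognormal_params(list(lognormal_component(0.2, 50, -1.6, 0.3)),
                               list())
  tt <- seq(0, 3, by = 1e-3)
  expect_equal(omega_lognormal_speed(tt, p1),
               50 * eval_lognormal(tt, p1$forward[[1]]))
  # widely separated 10-component train: 9 interior sign changes
  p <- oscillation_params(n_lobes = 10, half_period = 1.2, sigma = 0.15)
  tt <- seq(0, 14, by = 1e-3)
  v <- omega_lognormal_speed(tt, p)
  live <- abs(v) > 1e-6
  sgn <- sign(v[live])
  expect_equal(sum(diff(sgn) != 0), 9)
  # displacement bookkeeping
  expect_equal(trapz(tt, v), 5 * 30 - 5 * 30, tolerance = 1e-3)
  # count constraint
  mk <- function(t0) lognormal_component(t0, 10, -1.6, 0.2)
  expect_error(omega_lognormal_params(list(mk(0.1), mk(0.9), mk(1.7)),
                                      list(mk(0.5))), "N - M")
  expect_error(omega_lognormal_params(list(mk(0.1), mk(0.5)), list(mk(0.9))),
               "alternate")
})

test_that("synthesized trials emulate the digitizer sampling chain", {
  p <- delta_lognormal_params(0.05, 150, -1.6, 0.35, 30, -1.3, 0.45)
  rec <- synthesize_trial(p, sampling_spec(rate = 200, duration = 1.2))
  expect_s3_class(rec, "trial_recording")
  expect_equal(unique(round(diff(rec$t), 12)), 0.005)
  expect_false(rec$meta$truncated)
  # quantization bound versus the unquantized chain
  rec0 <- synthesize_trial(p, sampling_spec(rate = 200, duration = 1.2,
                                            quantum = 0))
  expect_lte(max(abs(rec$x - rec0$x)), 0.005 + 1e-12)
  # zero-amplitude command set yields a constant trace
  pz <- delta_lognormal_params(0.05, 0, -1.6, 0.35, 0, -1.3, 0.45,
                               strict = FALSE)
  recz <- synthesize_trial(pz, sampling_spec(rate = 200, duration = 0.5),
                           origin = c(3, 4))
  expect_equal(unique(recz$x), 3)
  expect_equal(unique(recz$y), 4)
  # a too-short window flags truncation
  rec_short <- synthesize_trial(p, sampling_spec(rate = 200, duration = 0.22))
  expect_true(rec_short$meta$truncated)
})

test_that("parameter sets round-trip through JSON", {
  pd <- random_delta_params()
  expect_equal(delta_param_vec(params_from_json(params_to_json(pd))),
               delta_param_vec(pd))
  ps <- triangle_params()
  ps2 <- params_from_json(params_to_json(ps))
  expect_equal(ps2$strokes[[2]]$theta_e, ps$strokes[[2]]$theta_e)
  po <- oscillation_params(5)
  po2 <- params_from_json(params_to_json(po))
  expect_equal(length(po2$forward), 3)
  expect_equal(po2$backward[[2]]$t0, po$backward[[2]]$t0)
})
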
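test_that("the default cohort reproduces the study composition", {
  cohort <- generate_cohort(cohort_spec(seed = 3))
  expect_equal(nrow(cohort), 120)
  expect_equal(sum(cohort$n_factors == 0), 57)
  prev <- colSums(cohort[, c("DM", "OB", "HT", "HC", "CD", "CS")])
  expect_equal(unname(prev), c(15, 10, 40, 28, 24, 13))
  expect_equal(as.integer(table(cohort$n_factors[cohort$n_factors > 0])),
               c(25L, 18L, 12L, 7L, 1L))
  expect_true(all(cohort$age >= 25 & cohort$age <= 85))
  expect_equal(sum(cohort$sex == "female"), 68)
  # determinism under the master seed
  again <- generate_cohort(cohort_spec(seed = 3))
  expect_identical(cohort, again)
  expect_false(identical(cohort$DM,
                         generate_cohort(cohort_spec(seed = 4))$DM))
  # an all-healthy cohort
  healthy <- generate_cohort(cohort_spec(
    prevalence = setNames(rep(0, 6), c("DM", "OB", "HT", "HC", "CD", "CS")),
    multi_counts = rep(0L, 5), seed = 3))
  expect_true(all(healthy$n_factors == 0))
  expect_error(cohort_spec(prevalence = c(DM = 100, OB = 0, HT = 0, HC = 0,
                                          CD = 0, CS = 0),
                           multi_counts = c(10, 0, 0, 0, 0)),
               "infeasible")
})

test_that("risk effects shift latent parameters additively on the right scale", {
  cohort <- generate_cohort(cohort_spec(seed = 5))
  null_c <- apply_risk_effects(cohort, effect_config())
  expect_equal(null_c$mu1, cohort$baseline_mu1)
  expect_equal(null_c$t0, cohort$baseline_t0)
  eff <- effect_config(DM = list(mu1_shift = 0.3, t0_shift = 0.05,
                                 sigma1_mult = 1.2),
                       HT = list(mu1_shift = 0.1))
  shifted <- apply_risk_effects(cohort, eff)
  dm_only <- shifted$DM & !shifted$HT
  both <- shifted$DM & shifted$HT
  expect_equal(shifted$mu1[dm_only], cohort$baseline_mu1[dm_only] + 0.3)
  if (any(both))
    expect_equal(shifted$mu1[both], cohort$baseline_mu1[both] + 0.4)
  expect_equal(shifted$sigma1[dm_only],
               cohort$baseline_sigma1[dm_only] * 1.2)
  expect_true(all(shifted$mu1[shifted$DM] > cohort$baseline_mu1[shifted$DM]))
})

test_that("the trial-spread multiplier scales within-subject variability", {
  cohort <- generate_cohort(cohort_spec(seed = 6))
  subj <- cohort[1, ]
  draw_sd <- function(mult) {
    s <- subj; s$mad_mult <- mult
    trials <- generate_session(s, "2", seed = 77, invalid_frac = 0,
                               n_trials = 40)
    sd(vapply(trials, function(r) r$meta$true_params$mu1, 0))
  }
  expect_equal(draw_sd(2) / draw_sd(1), 2, tolerance = 0.5)
})

test_that("foreperiod delays have a flat hazard truncated at 10 s", {
  set.seed(8)
  d <- stimulus_delay(10000)
  expect_lte(max(d), 10)
  expect_gt(min(d), 0)
  # truncated-exponential mean: 1/lambda - 10 / (exp(10 lambda) - 1)
  expect_equal(mean(d), 2.31343, tolerance = 0.1)
  set.seed(8); d2 <- stimulus_delay(10000)
  expect_identical(d, d2)
})

test_that("simulated sessions follow the task protocols", {
  cohort <- apply_risk_effects(generate_cohort(cohort_spec(seed = 9)),
                               effect_config())
  subj <- cohort[3, ]
  srt <- generate_session(subj, "2", seed = 12)
  reports <- lapply(srt, validate_trial)
  expect_gte(sum(vapply(reports, `[[`, TRUE, "valid")), 15)
  amps <- vapply(srt, function(r) {
    d <- which(r$pen_down)
    sqrt((r$x[d[length(d)]] - r$x[d[1]])^2 + (r$y[d[length(d)]] - r$y[d[1]])^2)
  }, 0)
  valid <- vapply(reports, `[[`, TRUE, "valid")
  expect_true(all(amps[valid] >= 130))
  # injected anticipated starts are caught downstream
  bad <- generate_session(subj, "2", seed = 13, invalid_frac = 1, n_trials = 4)
  kinds <- vapply(bad, function(r) r$meta$injected, "")
  reps <- lapply(bad, validate_trial)
  for (i in seq_along(bad)) {
    if (kinds[i] == "anticipated")
      expect_true("anticipated_start" %in% reps[[i]]$reasons)
    if (kinds[i] == "short_amp")
      expect_true("amplitude_below_minimum" %in% reps[[i]]$reasons)
  }
  # the speed/accuracy task covers its 4 x 4 x 2 factorial design
  sat <- generate_session(subj, "5", seed = 14)
  expect_length(sat, 32)
  cond <- t(vapply(sat, function(r) c(r$meta$distance, r$meta$width), c(0, 0)))
  expect_equal(nrow(unique(cond)), 16)
  # triangles: 2 rotations x 3 sizes x 2 repetitions
  tri <- generate_session(subj, "6", seed = 15)
  expect_length(tri, 12)
  # sessions are deterministic under the seed
  srt_b <- generate_session(subj, "2", seed = 12)
  expect_identical(srt[[1]]$x, srt_b[[1]]$x)
  expect_identical(length(srt), length(srt_b))
})

test_that("signature sessions reuse a stable per-subject template", {
  cohort <- apply_risk_effects(generate_cohort(cohort_spec(seed = 10)),
                               effect_config())
  subj <- cohort[5, ]
  s1 <- generate_session(subj, "1", seed = 21)
  s9 <- generate_session(subj, "9", seed = 21)
  expect_length(s1, 4)
  expect_length(s9, 1)
  # same underlying component count across the two signature tasks
  f1 <- fit_sigma_lognormal(compute_speed_profile(s1[[1]], smooth = FALSE),
                            refine_max = 0)
  expect_gte(length(f1$params$strokes), 4)
  # trials differ (jitter) but durations are comparable
  expect_false(identical(s1[[1]]$x, s1[[2]]$x))
})

test_that("oscillation sessions pace and then release the metronome", {
  cohort <- apply_risk_effects(generate_cohort(cohort_spec(seed = 11)),
                               effect_config())
  subj <- cohort[7, ]
  osc <- generate_session(subj, "7", seed = 31)
  expect_length(osc, 1)
  expect_gt(max(osc[[1]]$t), 10)
  met <- generate_session(subj, "8", seed = 32)
  expect_length(met, 2)
  expect_true(met[[1]]$meta$learning)     # first metronome trial is practice
  expect_false(met[[2]]$meta$learning)
  segs <- met[[2]]$meta$segments
  expect_equal(segs$steady[2] - segs$steady[1], 5)
  expect_equal(segs$adaptation[2] - segs$adaptation[1], 10)
})
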
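# --- shared fitting machinery ------------------------------------------

# Hooke-Jeeves pattern search with box constraints: derivative-free
# refinement from an optimum found by gradient-based least squares.
# Returns list(par, value, n_eval).
pattern_search <- function(f, x0, lower, upper, step,
                           shrink = 0.5, tol = 1e-7, max_eval = 400L) {
  clamp <- function(x) pmin(upper, pmax(lower, x))
  x <- clamp(x0)
  fx <- f(x)
  n_eval <- 1L
  base <- x; fbase <- fx
  while (n_eval < max_eval && max(step) > tol) {
    improved <- FALSE
    xe <- base; fe <- fbase
    for (j in seq_along(x)) {
      for (s in c(step[j], -step[j])) {
        cand <- xe; cand[j] <- cand[j] + s
        cand <- clamp(cand)
        fc <- f(cand); n_eval <- n_eval + 1L
        if (fc < fe) { xe <- cand; fe <- fc; improved <- TRUE; break }
      }
    }
    if (improved) {
      # pattern move: double the successful displacement
      pat <- clamp(xe + (xe - base))
      fp <- f(pat); n_eval <- n_eval + 1L
      if (fp < fe) { base <- pat; fbase <- fp } else { base <- xe; fbase <- fe }
    } else {
      step <- step * shrink
    }
  }
  list(par = base, value = fbase, n_eval = n_eval)
}

# Signed speed along the net displacement axis when planar components are
# available; raw magnitude otherwise.
signed_speed <- function(sp) {
  if (!is.null(sp$vx) && !is.null(sp$vy)) {
    ux <- trapz_int(sp$t, sp$vx)
    uy <- trapz_int(sp$t, sp$vy)
    nrm <- sqrt(ux^2 + uy^2)
    if (nrm > 1e-9) return((sp$vx * ux + sp$vy * uy) / nrm)
  }
  sp$v
}

# Weighted log-time moments of a speed lobe given a candidate onset time;
# the analytic initialization of a single-lognormal fit.
logtime_moments <- function(t, w, t0) {
  m <- t > t0 & w > 0
  if (sum(m) < 4L) return(NULL)
  lt <- log(t[m] - t0); ww <- w[m] / sum(w[m])
  mu <- sum(ww * lt)
  s2 <- sum(ww * (lt - mu)^2)
  if (!is.finite(mu) || s2 <= 0) return(NULL)
  list(mu = mu, sigma = sqrt(s2))
}

make_fit_result <- function(params, sp_t, observed, model_v, n_iterations,
                            converged) {
  rmse <- sqrt(mean((observed - model_v)^2))
  snr <- tryCatch(reconstruction_snr(observed, model_v), error = function(e) 0)
  structure(list(params = params, snr_db = snr, rmse = rmse,
                 n_iterations = n_iterations, converged = converged,
                 t = sp_t, observed = observed, model_v = model_v),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: SNR %.1f dB, RMSE %.3g mm/s, %d iterations%s\n",
              class(x$params)[1], x$snr_db, x$rmse, x$n_iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# --- delta-lognormal ----------------------------------------------------

# Parameter vector layout used by the optimizer:
# (t0, D1, mu1, sigma1, D2, mu2, sigma2)
delta_model_v <- function(t, p) {
  v <- p[2] * dlnorm(pmax(t - p[1], 0), p[3], p[4])
  if (p[5] > 0) v <- v - p[5] * dlnorm(pmax(t - p[1], 0), p[6], p[7])
  v
}

# Analytic displacement of the delta-lognormal model at the sample times.
delta_model_disp <- function(t, p) {
  x <- p[2] * plnorm(t - p[1], p[3], p[4])
  if (p[5] > 0) x <- x - p[5] * plnorm(t - p[1], p[6], p[7])
  x
}

# Closed-form gradients of the delta-lognormal displacement with respect
# to (t0, D1, mu1, sigma1, D2, mu2, sigma2), as columns of a matrix.
delta_pos_grads <- function(t, p) {
  x <- pmax(t - p[1], 0)
  pos <- x > 0
  z1 <- z2 <- phi1 <- phi2 <- numeric(length(t))
  lx <- log(x[pos])
  z1[pos] <- (lx - p[3]) / p[4]; z2[pos] <- (lx - p[6]) / p[7]
  phi1[pos] <- stats::dnorm(z1[pos]); phi2[pos] <- stats::dnorm(z2[pos])
  L1 <- dlnorm(x, p[3], p[4]); L2 <- dlnorm(x, p[6], p[7])
  cbind(t0 = -(p[2] * L1 - p[5] * L2),
        D1 = plnorm(x, p[3], p[4]),
        mu1 = -p[2] * phi1 / p[4],
        s1 = -p[2] * phi1 * z1 / p[4],
        D2 = -plnorm(x, p[6], p[7]),
        mu2 = p[5] * phi2 / p[7],
        s2 = p[5] * phi2 * z2 / p[7])
}

# Measurement-domain operator: what the speed-profile stage would report
# for a noiseless trace of the model — analytic positions at the sample
# times pushed through the same finite differencing (and, when the
# observed profile was smoothed, the same zero-phase filter).  Fitting
# against this, rather than the analytic velocity, cancels the
# differentiation bias that the observation carries.
delta_as_observed <- function(t, p, filt = NULL) {
  v <- finite_diff(t, delta_model_disp(t, p))
  if (!is.null(filt)) v <- zerophase_filter(filt, v)
  v
}

delta_stage1_init <- function(t, s) {
  A <- trapz_int(t, s)                      # net displacement D1 - D2
  ip <- which.max(s)
  tp <- t[ip]; vp <- s[ip]
  # backward extrapolation of the rising edge (20% -> 80% of peak) to v = 0
  pre <- seq_len(ip)
  i20 <- pre[which(s[pre] >= 0.2 * vp)[1]]
  i80 <- pre[which(s[pre] >= 0.8 * vp)[1]]
  t0_edge <- if (!is.na(i20) && !is.na(i80) && t[i80] > t[i20]) {
    sl <- (s[i80] - s[i20]) / (t[i80] - t[i20])
    t[i20] - s[i20] / sl
  } else tp - 0.15
  # antagonist seed from a terminal negative lobe when present
  neg <- -trapz_int(t, pmin(s, 0))
  D2 <- if (neg > 0.01 * A) neg else 0.05 * A
  D1 <- A + D2
  # onset candidates: the moment method is biased by the antagonist, so a
  # small grid of onsets is scored and the best SSE retained
  cand_t0 <- unique(pmax(0, c(t0_edge, t0_edge - 0.02, t0_edge - 0.05,
                              t0_edge + 0.01, tp - exp(-1.6))))
  best <- NULL
  for (t0 in cand_t0[cand_t0 < tp]) {
    mm <- logtime_moments(t, pmax(s, 0), t0)
    if (is.null(mm)) next
    mu2 <- mm$mu + 0.3; s2 <- min(1.4, mm$sigma * 1.2)
    p <- c(t0, D1, mm$mu, max(0.06, min(1.4, mm$sigma)), D2, mu2, s2)
    sse <- sum((s - delta_model_v(t, p))^2)
    if (is.null(best) || sse < best$sse) best <- list(p = p, sse = sse)
  }
  if (is.null(best)) {
    best <- list(p = c(max(0, tp - 0.2), D1, log(0.2), 0.3, D2, log(0.25), 0.4))
  }
  best$p
}

# Deflation initialization: fit the agonist alone on the region up to
# just past the peak (where the antagonist contribution is small), then
# explain the post-peak residual D1*L1 - s as the antagonist and read its
# (D2, mu2, sigma2) off closed-form log-time moments about the shared t0.
delta_deflation_init <- function(t, s, p0) {
  ip <- which.max(s); tp <- t[ip]
  cut <- tp + 0.3 * (tp - p0[1])
  seg <- which(t <= cut & s > 0)
  if (length(seg) < 6L) return(NULL)
  obj_ag <- function(q)
    sum((s[seg] - q[2] * dlnorm(pmax(t[seg] - q[1], 0), q[3], q[4]))^2)
  q0 <- c(p0[1], p0[2], p0[3], p0[4])
  lo <- c(max(0, p0[1] - 0.05), 0.3 * p0[2], -4, 0.05)
  hi <- c(tp, 3 * p0[2], 1, 1.5)
  ag <- optim(pmin(hi, pmax(lo, q0)), obj_ag, method = "L-BFGS-B",
              lower = lo, upper = hi,
              control = list(maxit = 120L,
                             parscale = c(0.05, p0[2], 0.2, 0.1), factr = 1e6))
  q <- ag$par
  r <- q[2] * dlnorm(pmax(t - q[1], 0), q[3], q[4]) - s
  r[t <= tp] <- 0
  r <- pmax(r, 0)
  if (sum(r) <= 0) return(NULL)
  mm <- logtime_moments(t, r, q[1])
  if (is.null(mm)) return(NULL)
  D2 <- max(trapz_int(t, r), 1e-3)
  c(q[1], q[2], q[3], q[4], D2, mm$mu, max(0.06, min(1.4, mm$sigma)))
}

#' Fit the delta-lognormal model to a speed profile
#'
#' Cascaded stages: (1) analytic initialization — command onset from
#' backward extrapolation of the rising edge, agonist shape from
#' weighted log-time moments, amplitudes from displacement and any
#' terminal negative lobe, plus a deflation estimate of the antagonist;
#' (2) bounded nonlinear least squares (Levenberg-Marquardt with
#' analytic Jacobian) on all seven parameters, multi-started over a grid
#' of antagonist variants because the agonist/antagonist split has
#' several local basins; (3) derivative-free pattern-search refinement
#' from the stage-2 optimum — first on the least-squares objective, then
#' (when the recording's quantization step is known) on a forward model
#' that reproduces the digitizer's rounding exactly, whose global
#' minimum sits at the generating parameters.  When the reconstruction
#' SNR remains below `restart_snr_db`, three jittered restarts (fixed
#' sub-seeds) are attempted and the best fit kept.
#'
#' The least-squares objective matches the model to the observation in
#' the measurement domain (the model's analytic positions pushed through
#' the same finite-difference/filter operator as the data) and carries a
#' displacement channel weighted by the noise-variance ratio `rate^2/2`;
#' both choices are needed to keep the near-degenerate antagonist split
#' identifiable at tablet resolution.
#'
#' @param sp a [compute_speed_profile()] result containing one dominant
#'   speed lobe (a rapid reaching movement).
#' @param restart_snr_db SNR threshold (dB) triggering jittered restarts.
#' @param max_iter iteration cap for each least-squares run.
#' @return a `fit_result` whose `params` is a [delta_lognormal_params()].
#' @export
fit_delta_lognormal <- function(sp, restart_snr_db = 15, max_iter = 120L) {
  if (!inherits(sp, "speed_profile")) stopf("sp must be a speed_profile")
  t <- sp$t; s <- signed_speed(sp)
  if (max(s) <= 0) stopf("profile has no positive speed lobe")
  # fit on the active window only (a margin before onset and after the
  # return to rest); long pre-stimulus and trailing rest phases carry no
  # information and dominate the cost otherwise
  dt <- median(diff(t))
  act <- which(abs(s) > 0.02 * max(s))
  i1 <- max(1L, act[1] - round(0.15 / dt))
  i2 <- min(length(t), act[length(act)] + round(0.3 / dt))
  t <- t[i1:i2]; s <- s[i1:i2]
  A <- max(trapz_int(t, s), 0.1 * trapz_int(t, abs(s)))
  ip <- which.max(s); tp <- t[ip]
  filt <- if (is.finite(sp$provenance$cutoff_hz %||% NA))
    signal::butter(2, sp$provenance$cutoff_hz / (sp$provenance$rate / 2),
                   type = "low") else NULL
  # bounds: the braking burst is smaller than the drive (net displacement
  # A = D1 - D2 with D2/D1 well below 1 for reaching strokes), which also
  # stops noise-fitting from escaping into huge-overlap solutions
  lower <- c(max(0, t[1] - 0.05), 0.2 * A, -4, 0.05, 0,       -4, 0.05)
  upper <- c(tp,                  2.5 * A,  1, 1.5,  1.2 * A,  1, 1.5)
  scale <- c(0.05, A, 0.2, 0.1, 0.3 * A, 0.2, 0.1)
  # joint velocity + displacement residual: the displacement channel is
  # obtained by the same cumulative-trapezoid operator on both sides, so
  # its noise is position-quantization-sized while the velocity channel
  # carries differentiated (rate-amplified) noise; weighting by the
  # noise-standard-deviation ratio rate/sqrt(2) keeps the agonist /
  # antagonist split identifiable
  d_obs <- cumtrapz_int(t, s)
  rate <- sp$provenance$rate %||% 200
  qm <- sp$provenance$quantum %||% NA
  # velocity-channel noise floor implied by position quantization alone
  sigma_q <- if (is.finite(qm) && qm > 0) qm * rate / sqrt(6) else 0.5
  # quick velocity-only pre-fit to gauge the actual noise level: when
  # measurement noise dominates quantization, the displacement channel
  # no longer has a precision advantage and must be demoted accordingly
  p0 <- delta_stage1_init(t, s)
  pre <- tryCatch(suppressWarnings(
    minpack.lm::nls.lm(p0, fn = function(p) s - delta_as_observed(t, p, filt),
                       control = minpack.lm::nls.lm.control(maxiter = 40L))),
    error = function(e) NULL)
  sigma_est <- if (!is.null(pre)) max(sd(pre$fvec), sigma_q) else sigma_q
  quant_limited <- sigma_est < 3 * sigma_q
  # the displacement channel is a quantization-regime device: its noise
  # advantage (and the GLS weight below) presuppose that rounding is the
  # dominant error; under real measurement noise its integral is a
  # random walk and would bias the fit, so it is switched off
  w_disp <- if (quant_limited) rate / sqrt(2) else 0
  resid_f <- function(p) {
    mv <- delta_as_observed(t, p, filt)
    c(s - mv, w_disp * (d_obs - cumtrapz_int(t, mv)))
  }
  # the measurement operator is linear, so the closed-form position
  # gradients pass straight through it into the Jacobian
  jac_f <- function(p) {
    G <- delta_pos_grads(t, p)
    J <- matrix(0, 2L * length(t), 7L)
    for (j in seq_len(7L)) {
      gv <- finite_diff(t, G[, j])
      if (!is.null(filt)) gv <- zerophase_filter(filt, gv)
      J[, j] <- c(-gv, -w_disp * cumtrapz_int(t, gv))
    }
    J
  }
  obj <- function(p) sum(resid_f(p)^2)
  stage2 <- function(q, maxiter = max_iter) {
    st <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(pmin(upper, pmax(lower, q)), lower, upper,
                         resid_f, jac_f,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-12, ftol = 1e-12))),
      error = function(e) NULL)
    if (is.null(st)) return(NULL)
    list(par = st$par, value = sum(st$fvec^2), iter = st$niter,
         conv = st$info %in% 1:4)
  }

  inits <- list(p0)
  defl <- delta_deflation_init(t, s, p0)
  if (!is.null(defl)) inits <- c(inits, list(defl))
  net <- p0[2] - p0[5]
  for (f2 in c(0.06, 0.12, 0.18, 0.25, 0.32)) for (dmu in c(0.2, 0.35, 0.5))
    for (rs in c(1.0, 1.3)) {
      q <- p0
      q[5] <- net * f2 / (1 - f2); q[2] <- net + q[5]
      q[6] <- p0[3] + dmu; q[7] <- max(0.06, min(1.4, p0[4] * rs))
      inits[[length(inits) + 1L]] <- q
    }
  runs <- Filter(Negate(is.null), lapply(inits, stage2))
  if (!length(runs)) stopf("least-squares stage failed from every initialization")
  st2 <- runs[[which.min(vapply(runs, `[[`, 0, "value"))]]
  n_it <- sum(vapply(runs, `[[`, 0, "iter"))
  st3 <- pattern_search(obj, st2$par, lower, upper,
                        step = scale * 0.02, max_eval = 200L)
  best <- if (st3$value < st2$value)
    list(par = st3$par, value = st3$value, iter = n_it + st3$n_eval,
         conv = TRUE)
  else c(st2[c("par", "value")], list(iter = n_it + st3$n_eval,
                                      conv = st2$conv))
  snr0 <- tryCatch(reconstruction_snr(s, delta_as_observed(t, best$par, filt)),
                   error = function(e) 0)
  if (snr0 < restart_snr_db) {
    for (k in 1:3) {
      set.seed(derive_seed(8191L, k))
      jit <- p0 * (1 + rnorm(7, 0, 0.15)) + c(rnorm(1, 0, 0.02), rep(0, 6))
      st <- stage2(jit)
      if (!is.null(st) && st$value < best$value)
        best <- c(st[c("par", "value")],
                  list(iter = best$iter + st$iter, conv = st$conv))
    }
  }
  # quantization-exact refinement: the digitizer's rounding is part of
  # the forward model, so at the generating parameters the rounded model
  # positions coincide with the recorded ones and the residual nearly
  # vanishes.  The rounded objective separates antagonist basins that
  # the smooth objective cannot, so it both selects among the
  # least-squares candidates and polishes the winner; it has vanishing
  # gradients, which is what the derivative-free pattern search is for.
  if (is.finite(qm) && qm > 0 && quant_limited) {
    obj_q <- function(p) {
      pos <- round(delta_model_disp(t, p) / qm) * qm
      mv <- finite_diff(t, pos)
      if (!is.null(filt)) mv <- zerophase_filter(filt, mv)
      sum((s - mv)^2)
    }
    vals <- vapply(runs, `[[`, 0, "value")
    cand <- runs[order(vals)[seq_len(min(8L, length(runs)))]]
    cand <- c(cand, list(best))
    polished <- lapply(cand, function(cd)
      pattern_search(obj_q, cd$par, lower, upper,
                     step = scale * 0.02, max_eval = 300L, tol = 1e-9))
    key <- vapply(polished, function(pl)
      # rounded-residual first; ties broken toward the smaller antagonist
      pl$value + 1e-6 * pl$par[5] / A, 0)
    win <- polished[[which.min(key)]]
    stq <- pattern_search(obj_q, win$par, lower, upper,
                          step = scale * 0.01, max_eval = 600L, tol = 1e-9)
    best$par <- stq$par
    best$iter <- best$iter + stq$n_eval + sum(vapply(polished, `[[`, 0L, "n_eval"))
  }
  p <- best$par
  params <- delta_lognormal_params(p[1], p[2], p[3], p[4], p[5], p[6], p[7],
                                   strict = FALSE)
  make_fit_result(params, t, s, delta_as_observed(t, p, filt),
                  n_iterations = as.integer(best$iter),
                  converged = isTRUE(best$conv) && p[2] > p[5])
}
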
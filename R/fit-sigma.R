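# Locate the lobe containing index `ip` in the (non-negative) speed trace
# `w`: walk outward from the peak until the trace falls below `frac` of
# the peak or starts rising again (a neighbouring lobe).
lobe_bounds <- function(w, ip, frac = 0.05) {
  th <- frac * w[ip]
  i1 <- ip
  while (i1 > 1L && w[i1 - 1L] > th && w[i1 - 1L] <= w[i1]) i1 <- i1 - 1L
  i2 <- ip
  n <- length(w)
  while (i2 < n && w[i2 + 1L] > th && w[i2 + 1L] <= w[i2]) i2 <- i2 + 1L
  c(i1, i2)
}

# Fit one lognormal magnitude profile D * dlnorm(t - t0, mu, sigma) to a
# non-negative lobe `w` over samples [i1, i2]; analytic moment init over
# a small grid of onset candidates, then bounded least squares.
fit_single_lognormal <- function(t, w, i1, i2, max_iter = 200L) {
  seg <- i1:i2
  ts <- t[seg]; ws <- w[seg]
  ip <- seg[which.max(ws)]
  tp <- t[ip]
  D0 <- max(trapz_int(ts, ws), 1e-6)
  span <- max(ts[length(ts)] - ts[1], 0.02)
  cand_t0 <- pmax(0, c(ts[1] - 0.1 * span, ts[1] - 0.3 * span,
                       ts[1] - 0.7 * span, tp - exp(-1.6)))
  best <- NULL
  for (t0 in unique(cand_t0[cand_t0 < tp])) {
    mm <- logtime_moments(ts, ws, t0)
    if (is.null(mm)) next
    p <- c(t0, D0, mm$mu, max(0.06, min(1.4, mm$sigma)))
    sse <- sum((ws - p[2] * dlnorm(pmax(ts - p[1], 0), p[3], p[4]))^2)
    if (is.null(best) || sse < best$sse) best <- list(p = p, sse = sse)
  }
  if (is.null(best)) best <- list(p = c(max(0, tp - 0.2), D0, log(0.2), 0.3))
  lower <- c(max(0, ts[1] - 2 * span), 0.05 * D0, -4, 0.05)
  upper <- c(tp, 10 * D0, 1, 1.5)
  obj <- function(p) sum((ws - p[2] * dlnorm(pmax(ts - p[1], 0), p[3], p[4]))^2)
  st <- optim(pmin(upper, pmax(lower, best$p)), obj, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(maxit = max_iter,
                             parscale = c(0.05, D0, 0.2, 0.1), factr = 1e5))
  st$par
}

# Circular mean direction of a velocity sample window.
mean_angle <- function(vx, vy) atan2(sum(vy), sum(vx))

sigma_stroke_velocity <- function(t, p) {
  # p = (t0, D, mu, sigma, theta_s, theta_e)
  mag <- p[2] * dlnorm(pmax(t - p[1], 0), p[3], p[4])
  phi <- rep(p[5], length(t))
  m <- t > p[1]
  phi[m] <- p[5] + (p[6] - p[5]) * plnorm(t[m] - p[1], p[3], p[4])
  list(vx = mag * cos(phi), vy = mag * sin(phi))
}

#' Fit the sigma-lognormal model to a planar velocity profile
#'
#' Greedy stroke extraction: the most prominent remaining speed lobe
#' (between consecutive speed minima) is located, one stroke is fitted
#' to it — lognormal magnitude plus start/end direction angles taken
#' from the trajectory tangents at the lobe boundaries — its velocity
#' contribution is subtracted, and the loop repeats until the
#' reconstruction SNR gain drops below `min_gain_db` or `max_components`
#' is reached.  A final joint bounded least-squares refinement over all
#' stroke parameters is run when the model is small enough to make it
#' worthwhile.
#'
#' @param sp a [compute_speed_profile()] result with `vx`, `vy`.
#' @param max_components cap on the number of extracted strokes.
#' @param min_gain_db stop when one more stroke improves SNR by less.
#' @param refine_max joint refinement is run when the number of strokes
#'   does not exceed this (it is quadratic in component count).
#' @return a `fit_result` whose `params` is a [sigma_lognormal_params()].
#' @export
fit_sigma_lognormal <- function(sp, max_components = 40L, min_gain_db = 1,
                                refine_max = 12L) {
  if (!inherits(sp, "speed_profile")) stopf("sp must be a speed_profile")
  if (is.null(sp$vx) || is.null(sp$vy)) stopf("planar velocity (vx, vy) required")
  t <- sp$t
  rx <- sp$vx; ry <- sp$vy
  p0 <- sum(sp$vx^2 + sp$vy^2)
  if (p0 == 0) stopf("empty model: profile has no motion")
  vmax <- max(sp$v)
  strokes <- list()
  snr_prev <- 0
  for (k in seq_len(max_components)) {
    rv <- sqrt(rx^2 + ry^2)
    ip <- which.max(rv)
    if (rv[ip] < 0.02 * vmax) break
    b <- lobe_bounds(rv, ip)
    p4 <- fit_single_lognormal(t, rv, b[1], b[2])
    nb <- max(3L, (b[2] - b[1]) %/% 4L)
    th_s <- mean_angle(rx[b[1]:min(b[1] + nb, b[2])],
                       ry[b[1]:min(b[1] + nb, b[2])])
    th_e <- mean_angle(rx[max(b[2] - nb, b[1]):b[2]],
                       ry[max(b[2] - nb, b[1]):b[2]])
    # keep the sweep continuous: bring theta_e within pi of theta_s
    th_e <- th_s + ((th_e - th_s + pi) %% (2 * pi)) - pi
    # local refinement of the full stroke on a window around the lobe
    wpad <- (b[2] - b[1]) + 4L
    win <- max(1L, b[1] - wpad):min(length(t), b[2] + wpad)
    lower <- c(max(0, t[b[1]] - 0.5), 0.05 * p4[2], -4, 0.05, th_s - 1.5, th_e - 1.5)
    upper <- c(t[ip], 10 * p4[2], 1, 1.5, th_s + 1.5, th_e + 1.5)
    obj <- function(p) {
      mv <- sigma_stroke_velocity(t[win], p)
      sum((rx[win] - mv$vx)^2 + (ry[win] - mv$vy)^2)
    }
    st <- optim(pmin(upper, pmax(lower, c(p4, th_s, th_e))), obj,
                method = "L-BFGS-B", lower = lower, upper = upper,
                control = list(maxit = 150L,
                               parscale = c(0.05, p4[2], 0.2, 0.1, 0.3, 0.3),
                               factr = 1e5))
    mv <- sigma_stroke_velocity(t, st$par)
    rx_new <- rx - mv$vx; ry_new <- ry - mv$vy
    snr_new <- 10 * log10(p0 / max(sum(rx_new^2 + ry_new^2), 1e-12))
    if (snr_new - snr_prev < min_gain_db && k > 1L) break
    rx <- rx_new; ry <- ry_new
    snr_prev <- snr_new
    strokes[[length(strokes) + 1L]] <- st$par
  }
  if (!length(strokes)) stopf("empty model: no speed lobe could be fitted")
  pm <- do.call(rbind, strokes)
  pm <- pm[order(pm[, 1]), , drop = FALSE]
  if (nrow(pm) <= refine_max) {
    flat0 <- as.vector(t(pm))
    K <- nrow(pm)
    lower <- rep(c(0, 1e-3, -4, 0.05, -2 * pi, -2 * pi), K)
    upper <- rep(c(max(t), Inf, 1, 1.5, 2 * pi, 2 * pi), K)
    lower[seq(5, 6 * K, by = 6)] <- flat0[seq(5, 6 * K, by = 6)] - 1
    upper[seq(5, 6 * K, by = 6)] <- flat0[seq(5, 6 * K, by = 6)] + 1
    lower[seq(6, 6 * K, by = 6)] <- flat0[seq(6, 6 * K, by = 6)] - 1
    upper[seq(6, 6 * K, by = 6)] <- flat0[seq(6, 6 * K, by = 6)] + 1
    objj <- function(p) {
      m <- matrix(p, ncol = 6, byrow = TRUE)
      mx <- numeric(length(t)); my <- numeric(length(t))
      for (i in seq_len(nrow(m))) {
        mv <- sigma_stroke_velocity(t, m[i, ])
        mx <- mx + mv$vx; my <- my + mv$vy
      }
      sum((sp$vx - mx)^2 + (sp$vy - my)^2)
    }
    st <- optim(flat0, objj, method = "L-BFGS-B", lower = lower, upper = upper,
                control = list(maxit = 200L, factr = 1e6,
                               parscale = rep(c(0.05, mean(pm[, 2]), 0.2, 0.1,
                                                0.3, 0.3), K)))
    if (st$value <= objj(flat0)) {
      pm <- matrix(st$par, ncol = 6, byrow = TRUE)
      pm <- pm[order(pm[, 1]), , drop = FALSE]
    }
  }
  params <- sigma_lognormal_params(lapply(seq_len(nrow(pm)), function(i)
    sigma_stroke(pm[i, 1], pm[i, 2], pm[i, 3], pm[i, 4], pm[i, 5], pm[i, 6])))
  mv <- sigma_lognormal_velocity(t, params)
  make_fit_result(params, t, sp$v, sqrt(mv$vx^2 + mv$vy^2),
                  n_iterations = nrow(pm), converged = TRUE)
}
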
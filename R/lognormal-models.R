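#' Lognormal neuromuscular component
#'
#' One impulse response of a neuromuscular system in the lognormal family
#' of rapid-movement models: a command of amplitude `D` issued at time
#' `t0` produces a speed contribution `D * dlnorm(t - t0, mu, sigma)`.
#' `mu` is the log-time delay and `sigma` the log-response spread of the
#' system; both live on a logarithmic time scale.
#'
#' Parameters far outside the range typical of rapid human movements
#' (`mu` in \[-4, 1\], `sigma` in \[0.05, 1.5\], `t0 >= 0`) trigger a
#' warning but are accepted; `sigma <= 0` and `D <= 0` are errors.
#'
#' @param t0 command onset time (s).
#' @param D command amplitude (mm).
#' @param mu log-time delay (log-s).
#' @param sigma log-response spread (> 0).
#' @return An object of class `lognormal_component`.
#' @export
lognormal_component <- function(t0, D, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stopf("sigma must be > 0 (got %g)", sigma)
  if (!is.finite(D) || D < 0) stopf("D must be >= 0 (got %g)", D)
  if (!is.finite(t0) || !is.finite(mu)) stopf("t0 and mu must be finite")
  if (t0 < 0 || mu < -4 || mu > 1 || sigma < 0.05 || sigma > 1.5)
    warnf("component (t0=%g, mu=%g, sigma=%g) outside typical rapid-movement range",
          t0, mu, sigma)
  structure(list(t0 = t0, D = D, mu = mu, sigma = sigma),
            class = "lognormal_component")
}

#' Evaluate a time-shifted lognormal density
#'
#' The normalized impulse response of one neuromuscular component:
#' `1 / (sigma * sqrt(2*pi) * (t - t0)) * exp(-(log(t - t0) - mu)^2 / (2 sigma^2))`
#' for `t > t0` and exactly 0 at or before the command onset.  Integrates
#' to 1 over `(t0, Inf)`.
#'
#' @param t numeric vector of times (s).
#' @param c a [lognormal_component()].
#' @return density values (1/s), same length as `t`.
#' @export
eval_lognormal <- function(t, c) {
  if (!inherits(c, "lognormal_component")) stopf("c must be a lognormal_component")
  out <- numeric(length(t))
  m <- t > c$t0
  out[m] <- dlnorm(t[m] - c$t0, meanlog = c$mu, sdlog = c$sigma)
  out
}

#' Delta-lognormal parameter set
#'
#' A rapid reaching movement modelled as the synergy of an agonist
#' component pushing the pen toward the target and an antagonist braking
#' it, both triggered at the same command onset `t0`.  The signed speed
#' is `D1*L1(t) - D2*L2(t)`.
#'
#' @param t0 shared command onset (s).
#' @param D1,mu1,sigma1 agonist amplitude (mm) and lognormal shape.
#' @param D2,mu2,sigma2 antagonist amplitude (mm, `0 <= D2 < D1` under
#'   strict validation) and lognormal shape.
#' @param strict enforce `D1 > D2 >= 0` (net forward displacement);
#'   extraction code may relax this while reporting unconverged fits.
#' @return object of class `delta_lognormal_params`.
#' @export
delta_lognormal_params <- function(t0, D1, mu1, sigma1, D2, mu2, sigma2,
                                   strict = TRUE) {
  if (strict && (D2 < 0 || D2 >= D1))
    stopf("delta-lognormal requires D1 > D2 >= 0 (got D1=%g, D2=%g)", D1, D2)
  agonist <- lognormal_component(t0, D1, mu1, sigma1)
  antagonist <- lognormal_component(t0, D2, mu2, sigma2)
  structure(list(agonist = agonist, antagonist = antagonist, t0 = t0),
            class = "delta_lognormal_params")
}

#' Signed speed of a delta-lognormal movement
#'
#' @param t numeric vector of times (s).
#' @param p a [delta_lognormal_params()].
#' @return signed speed (mm/s) along the movement axis.
#' @export
delta_lognormal_speed <- function(t, p) {
  if (!inherits(p, "delta_lognormal_params")) stopf("p must be delta_lognormal_params")
  if (p$agonist$t0 != p$antagonist$t0)
    stopf("agonist and antagonist must share the same command onset t0")
  v <- p$agonist$D * eval_lognormal(t, p$agonist)
  if (p$antagonist$D > 0)
    v <- v - p$antagonist$D * eval_lognormal(t, p$antagonist)
  v
}

#' Sigma-lognormal stroke
#'
#' One component of a complex planar movement: a lognormal speed profile
#' travelling along a circle-arc whose tangent direction evolves from
#' `theta_s` to `theta_e` following an error-function law in log time.
#'
#' @param t0,D,mu,sigma lognormal component parameters.
#' @param theta_s,theta_e start and end trajectory direction angles (rad).
#' @return object of class `sigma_stroke`.
#' @export
sigma_stroke <- function(t0, D, mu, sigma, theta_s, theta_e) {
  if (!is.finite(theta_s) || !is.finite(theta_e)) stopf("stroke angles must be finite")
  base <- lognormal_component(t0, D, mu, sigma)
  structure(c(base, list(theta_s = theta_s, theta_e = theta_e)),
            class = c("sigma_stroke", "lognormal_component"))
}

#' Direction profile of a sigma-lognormal stroke
#'
#' `phi(t) = theta_s + (theta_e - theta_s)/2 * (1 + erf((log(t - t0) - mu) / (sigma*sqrt(2))))`,
#' which is `theta_s + (theta_e - theta_s) * plnorm(t - t0, mu, sigma)`:
#' the direction sweeps from `theta_s` to `theta_e` as the lognormal mass
#' is traversed.  At or before the command onset the limit value
#' `theta_s` is returned.
#'
#' @param t numeric vector of times (s).
#' @param s a [sigma_stroke()].
#' @return direction angles (rad), same length as `t`.
#' @export
stroke_direction <- function(t, s) {
  if (!inherits(s, "sigma_stroke")) stopf("s must be a sigma_stroke")
  phi <- rep(s$theta_s, length(t))
  m <- t > s$t0
  phi[m] <- s$theta_s +
    (s$theta_e - s$theta_s) * plnorm(t[m] - s$t0, meanlog = s$mu, sdlog = s$sigma)
  phi
}

#' Sigma-lognormal parameter set
#'
#' An ordered superposition of [sigma_stroke()] components describing an
#' arbitrarily complex planar movement (stroke sequences, signatures).
#'
#' @param strokes list of [sigma_stroke()] objects, ordered by
#'   nondecreasing onset time (ties keep list order).
#' @return object of class `sigma_lognormal_params`.
#' @export
sigma_lognormal_params <- function(strokes) {
  if (length(strokes) < 1L) stopf("at least one stroke is required")
  if (!all(vapply(strokes, inherits, TRUE, "sigma_stroke")))
    stopf("all elements must be sigma_stroke objects")
  t0s <- vapply(strokes, `[[`, 0, "t0")
  if (is.unsorted(t0s)) stopf("strokes must be ordered by nondecreasing t0")
  structure(list(strokes = strokes), class = "sigma_lognormal_params")
}

#' Planar velocity of a sigma-lognormal movement
#'
#' Superposition of the stroke velocities
#' `sum_i D_i * L_i(t) * (cos(phi_i(t)), sin(phi_i(t)))`.
#'
#' @param t numeric vector of times (s).
#' @param p a [sigma_lognormal_params()].
#' @return list with components `vx` and `vy` (mm/s).
#' @export
sigma_lognormal_velocity <- function(t, p) {
  if (!inherits(p, "sigma_lognormal_params")) stopf("p must be sigma_lognormal_params")
  vx <- numeric(length(t)); vy <- numeric(length(t))
  for (s in p$strokes) {
    mag <- s$D * eval_lognormal(t, s)
    phi <- stroke_direction(t, s)
    vx <- vx + mag * cos(phi)
    vy <- vy + mag * sin(phi)
  }
  list(vx = vx, vy = vy)
}

#' Omega-lognormal parameter set
#'
#' An oscillatory 1-D movement modelled as an alternating sum of forward
#' (positive) and backward (negative) lognormal components; the counts of
#' the two trains may differ by at most one and their onsets must
#' strictly alternate.
#'
#' @param forward,backward lists of [lognormal_component()] objects.
#' @return object of class `omega_lognormal_params`.
#' @export
omega_lognormal_params <- function(forward, backward) {
  N <- length(forward); M <- length(backward)
  if (N == 0L && M == 0L) stopf("at least one component is required")
  if (abs(N - M) > 1L)
    stopf("|N - M| must be 0 or 1 (got N=%d, M=%d)", N, M)
  ok <- function(l) all(vapply(l, inherits, TRUE, "lognormal_component"))
  if (!ok(forward) || !ok(backward)) stopf("components must be lognormal_component objects")
  tf <- vapply(forward, `[[`, 0, "t0"); tb <- vapply(backward, `[[`, 0, "t0")
  sgn <- c(rep(1L, N), rep(-1L, M))[order(c(tf, tb))]
  if (any(diff(sgn) == 0L))
    stopf("merged component onsets must strictly alternate forward/backward")
  structure(list(forward = forward, backward = backward),
            class = "omega_lognormal_params")
}

#' Signed speed of an omega-lognormal oscillation
#'
#' @param t numeric vector of times (s).
#' @param p an [omega_lognormal_params()].
#' @return signed speed (mm/s) along the oscillation axis.
#' @export
omega_lognormal_speed <- function(t, p) {
  if (!inherits(p, "omega_lognormal_params")) stopf("p must be omega_lognormal_params")
  v <- numeric(length(t))
  for (c in p$forward) v <- v + c$D * eval_lognormal(t, c)
  for (c in p$backward) v <- v - c$D * eval_lognormal(t, c)
  v
}

#' Serialize / deserialize model parameter sets to JSON
#'
#' Field names are exactly `t0`, `D`, `mu`, `sigma`, `theta_s`, `theta_e`;
#' sigma- and omega-lognormal sets use lists of components.
#'
#' @param p a parameter set of any of the three model classes.
#' @return `params_to_json`: a JSON string; `params_from_json`: the
#'   parameter object.
#' @export
params_to_json <- function(p) {
  comp <- function(c) list(t0 = c$t0, D = c$D, mu = c$mu, sigma = c$sigma)
  x <- switch(class(p)[1],
    delta_lognormal_params = list(
      model = "delta", t0 = p$t0,
      agonist = comp(p$agonist), antagonist = comp(p$antagonist)),
    sigma_lognormal_params = list(
      model = "sigma",
      strokes = lapply(p$strokes, function(s)
        c(comp(s), list(theta_s = s$theta_s, theta_e = s$theta_e)))),
    omega_lognormal_params = list(
      model = "omega",
      forward = lapply(p$forward, comp),
      backward = lapply(p$backward, comp)),
    stopf("unsupported parameter class: %s", class(p)[1]))
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' @rdname params_to_json
#' @param json a JSON string produced by `params_to_json`.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  switch(x$model,
    delta = {
      a <- x$agonist; b <- x$antagonist
      delta_lognormal_params(x$t0, a$D, a$mu, a$sigma, b$D, b$mu, b$sigma,
                             strict = FALSE)
    },
    sigma = sigma_lognormal_params(lapply(x$strokes, function(s)
      sigma_stroke(s$t0, s$D, s$mu, s$sigma, s$theta_s, s$theta_e))),
    omega = omega_lognormal_params(
      lapply(x$forward, function(c) lognormal_component(c$t0, c$D, c$mu, c$sigma)),
      lapply(x$backward, function(c) lognormal_component(c$t0, c$D, c$mu, c$sigma))),
    stopf("unknown model kind '%s'", x$model))
}
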
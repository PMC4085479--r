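#' Sampling specification of the acquisition chain
#'
#' Emulates the digitizer: temporal sampling rate (200 Hz by default) and
#' spatial quantization step (0.01 mm, i.e. 100 lines per millimetre).
#'
#' @param rate samples per second (> 0).
#' @param quantum spatial quantization step (mm, >= 0; 0 disables rounding).
#' @param duration recording duration (s).
#' @return object of class `sampling_spec`.
#' @export
sampling_spec <- function(rate = 200, quantum = 0.01, duration = 2) {
  if (!is.finite(rate) || rate <= 0) stopf("rate must be > 0")
  if (!is.finite(quantum) || quantum < 0) stopf("quantum must be >= 0")
  if (!is.finite(duration) || duration <= 0) stopf("duration must be > 0")
  structure(list(rate = rate, quantum = quantum, duration = duration),
            class = "sampling_spec")
}

#' Construct a trial recording
#'
#' The canonical sampled-trace container: times (s), pen positions (mm)
#' and a per-sample pen-down flag, plus a metadata list (subject id, task
#' id, trial index, stimulus onset and kind, learning flag, validity
#' notes).  Time is trial-local, in seconds from recording start;
#' stimulus onset lives in the metadata and is never subtracted from the
#' samples, so fitted onset times remain comparable to reaction times.
#'
#' @param t,x,y,pen_down equal-length sample vectors.
#' @param meta metadata list.
#' @return object of class `trial_recording`.
#' @export
trial_recording <- function(t, x, y, pen_down = rep(TRUE, length(t)),
                            meta = list()) {
  n <- length(t)
  if (length(x) != n || length(y) != n || length(pen_down) != n)
    stopf("t, x, y, pen_down must have equal length")
  if (n >= 2L && any(diff(t) <= 0)) stopf("sample times must be strictly increasing")
  structure(list(t = t, x = x, y = y, pen_down = as.logical(pen_down),
                 meta = meta),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %d samples, %.3f s, task %s subject %s\n",
              length(x$t), diff(range(x$t)),
              x$meta$task_id %||% "?", x$meta$subject_id %||% "?"))
  invisible(x)
}

# Analytic velocity of any of the three parameter sets, resolved onto the
# plane. `direction` orients the 1-D delta/omega models.
model_velocity <- function(t, params, direction = 0) {
  if (inherits(params, "sigma_lognormal_params")) {
    sigma_lognormal_velocity(t, params)
  } else {
    v <- if (inherits(params, "delta_lognormal_params"))
      delta_lognormal_speed(t, params)
    else if (inherits(params, "omega_lognormal_params"))
      omega_lognormal_speed(t, params)
    else stopf("unsupported parameter class: %s", class(params)[1])
    list(vx = v * cos(direction), vy = v * sin(direction))
  }
}

# All lognormal components of a parameter set, as a flat list.
model_components <- function(params) {
  if (inherits(params, "delta_lognormal_params"))
    Filter(function(c) c$D > 0, list(params$agonist, params$antagonist))
  else if (inherits(params, "sigma_lognormal_params"))
    params$strokes
  else
    c(params$forward, params$backward)
}

# Fraction of commanded displacement mass delivered within `duration`;
# each component's mass beyond the recording is its lognormal tail.
delivered_mass_fraction <- function(params, duration) {
  comps <- model_components(params)
  D <- vapply(comps, `[[`, 0, "D")
  if (sum(D) <= 0) return(1)
  frac <- vapply(comps, function(c)
    plnorm(duration - c$t0, meanlog = c$mu, sdlog = c$sigma), 0)
  sum(D * frac) / sum(D)
}

#' Synthesize a sampled trial from model parameters
#'
#' The inverse of the acquisition chain: the analytic model velocity is
#' integrated to positions with the trapezoidal rule on an internal grid
#' at least 4x the output rate, decimated to the output rate, and the
#' positions are rounded to the digitizer's spatial quantization grid.
#' Quantization and sampling are applied last, emulating the tablet.
#'
#' If the sampled duration captures less than 99.9% of the commanded
#' path mass, the recording is flagged with `meta$truncated = TRUE`.
#'
#' @param params a delta-, sigma- or omega-lognormal parameter set.
#' @param spec a [sampling_spec()].
#' @param origin start position (mm, length-2).
#' @param direction movement axis angle (rad) for the 1-D models.
#' @param meta metadata list merged into the recording.
#' @param oversample internal grid factor (>= 4; the default 16 keeps
#'   the integration error well below the spatial quantization step).
#' @return a [trial_recording()].
#' @export
synthesize_trial <- function(params, spec = sampling_spec(),
                             origin = c(0, 0), direction = 0,
                             meta = list(), oversample = 16L) {
  if (!inherits(spec, "sampling_spec")) stopf("spec must be a sampling_spec")
  oversample <- max(4L, as.integer(oversample))
  dt <- 1 / (spec$rate * oversample)
  n_out <- floor(spec$duration * spec$rate) + 1L
  tt <- seq(0, by = dt, length.out = (n_out - 1L) * oversample + 1L)
  # before the first command onset every component is identically zero,
  # so the pen rests at the origin; integrate the active span only
  comps <- model_components(params)
  t_first <- if (length(comps)) min(vapply(comps, `[[`, 0, "t0")) else Inf
  from <- max(1L, findInterval(t_first, tt))
  xx <- rep(origin[1], length(tt)); yy <- rep(origin[2], length(tt))
  if (from < length(tt)) {
    idx <- from:length(tt)
    v <- model_velocity(tt[idx], params, direction)
    xx[idx] <- origin[1] + cumtrapz_int(tt[idx], v$vx)
    yy[idx] <- origin[2] + cumtrapz_int(tt[idx], v$vy)
  }
  keep <- seq(1L, length(tt), by = oversample)
  t_out <- tt[keep]
  x_out <- xx[keep]; y_out <- yy[keep]
  if (spec$quantum > 0) {
    x_out <- round(x_out / spec$quantum) * spec$quantum
    y_out <- round(y_out / spec$quantum) * spec$quantum
  }
  meta$truncated <- delivered_mass_fraction(params, spec$duration) < 0.999
  meta$sampling <- list(rate = spec$rate, quantum = spec$quantum)
  trial_recording(t_out, x_out, y_out, meta = meta)
}
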
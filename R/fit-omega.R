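# Segment a signed oscillation speed trace into same-sign lobes.
# Samples with |s| below `eps_frac` of the global maximum are treated as
# rest; consecutive same-sign runs separated only by rest are merged.
# Returns a list of (i1, i2, sign) with lobes in time order.
oscillation_lobes <- function(s, eps_frac = 0.02, min_area_frac = 0.02,
                              t = seq_along(s)) {
  eps <- eps_frac * max(abs(s))
  sg <- sign(s) * (abs(s) > eps)
  runs <- rle(sg)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  lobes <- list()
  for (k in seq_along(runs$values)) {
    if (runs$values[k] == 0) next
    cur <- list(i1 = starts[k], i2 = ends[k], sign = runs$values[k])
    nlast <- length(lobes)
    if (nlast > 0L && lobes[[nlast]]$sign == cur$sign) {
      lobes[[nlast]]$i2 <- cur$i2          # zero-touch split of one lobe
    } else {
      lobes[[nlast + 1L]] <- cur
    }
  }
  if (!length(lobes)) return(lobes)
  areas <- vapply(lobes, function(l)
    abs(trapz_int(t[l$i1:l$i2], s[l$i1:l$i2])), 0)
  lobes[areas >= min_area_frac * max(areas)]
}

#' Fit the omega-lognormal model to an oscillatory profile
#'
#' The planar velocity is projected onto the oscillation axis (by
#' default the first principal axis of the velocity samples); the signed
#' projection is segmented into alternating positive/negative lobes at
#' its zero crossings, each lobe is fitted with one sign-constrained
#' lognormal component as in [fit_sigma_lognormal()], and the
#' forward/backward count constraint `|N - M| <= 1` is enforced by
#' dropping the weakest surplus component.  A joint bounded
#' least-squares refinement is run for small component counts.
#'
#' @param sp a [compute_speed_profile()] result; if `vx`/`vy` are absent
#'   `sp$v` is taken as the already-projected signed speed.
#' @param axis optional unit vector (length 2) defining the oscillation
#'   axis.
#' @param refine_max joint refinement cap on component count.
#' @return a `fit_result` whose `params` is an
#'   [omega_lognormal_params()]; `fit$axis` records the axis used.
#' @export
fit_omega_lognormal <- function(sp, axis = NULL, refine_max = 12L) {
  if (!inherits(sp, "speed_profile")) stopf("sp must be a speed_profile")
  t <- sp$t
  if (!is.null(sp$vx) && !is.null(sp$vy)) {
    if (is.null(axis)) {
      pc <- prcomp(cbind(sp$vx, sp$vy), center = FALSE)
      axis <- pc$rotation[, 1]
    }
    axis <- axis / sqrt(sum(axis^2))
    s <- sp$vx * axis[1] + sp$vy * axis[2]
    # orient the axis so the first lobe is forward (positive)
    first_big <- which(abs(s) > 0.05 * max(abs(s)))[1]
    if (!is.na(first_big) && s[first_big] < 0) { s <- -s; axis <- -axis }
  } else {
    s <- sp$v
    axis <- c(1, 0)
  }
  lobes <- oscillation_lobes(s, t = t)
  if (length(lobes) < 2L)
    stopf("insufficient oscillation: fewer than 2 speed lobes found")
  comps <- lapply(lobes, function(l) {
    w <- abs(s)
    ipk <- l$i1 - 1L + which.max(w[l$i1:l$i2])
    b <- lobe_bounds(w, ipk)
    b[1] <- max(b[1], l$i1); b[2] <- min(b[2], l$i2)
    p4 <- fit_single_lognormal(t, w * (seq_along(w) >= b[1] &
                                         seq_along(w) <= b[2]), b[1], b[2])
    list(p = p4, sign = l$sign)
  })
  # time order, then enforce strict alternation: of any same-sign
  # neighbours keep the larger-amplitude one
  ord <- order(vapply(comps, function(c) c$p[1], 0))
  comps <- comps[ord]
  repeat {
    sg <- vapply(comps, `[[`, 0, "sign")
    dup <- which(diff(sg) == 0)
    if (!length(dup)) break
    i <- dup[1]
    drop_i <- if (comps[[i]]$p[2] < comps[[i + 1L]]$p[2]) i else i + 1L
    comps <- comps[-drop_i]
  }
  if (length(comps) < 2L)
    stopf("insufficient oscillation: fewer than 2 alternating lobes")
  omega_v <- function(m, sg) {
    v <- numeric(length(t))
    for (i in seq_len(nrow(m)))
      v <- v + sg[i] * m[i, 2] * dlnorm(pmax(t - m[i, 1], 0), m[i, 3], m[i, 4])
    v
  }
  pm <- do.call(rbind, lapply(comps, `[[`, "p"))
  sg <- vapply(comps, `[[`, 0, "sign")
  if (nrow(pm) <= refine_max) {
    flat0 <- as.vector(t(pm))
    K <- nrow(pm)
    lower <- rep(c(0, 1e-3, -4, 0.05), K)
    upper <- rep(c(max(t), Inf, 1, 1.5), K)
    objj <- function(p)
      sum((s - omega_v(matrix(p, ncol = 4, byrow = TRUE), sg))^2)
    st <- optim(flat0, objj, method = "L-BFGS-B", lower = lower, upper = upper,
                control = list(maxit = 200L, factr = 1e6,
                               parscale = rep(c(0.05, mean(pm[, 2]), 0.2, 0.1), K)))
    if (st$value <= objj(flat0)) {
      pm2 <- matrix(st$par, ncol = 4, byrow = TRUE)
      ord <- order(pm2[, 1]); pm2 <- pm2[ord, , drop = FALSE]; sg2 <- sg[ord]
      if (!any(diff(sg2) == 0)) { pm <- pm2; sg <- sg2 }  # keep alternation
    }
  }
  mk <- function(i) lognormal_component(pm[i, 1], pm[i, 2], pm[i, 3], pm[i, 4])
  params <- omega_lognormal_params(
    forward = lapply(which(sg > 0), mk),
    backward = lapply(which(sg < 0), mk))
  fit <- make_fit_result(params, t, s, omega_v(pm, sg),
                         n_iterations = nrow(pm), converged = TRUE)
  fit$axis <- axis
  fit
}
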
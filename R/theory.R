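# Effective front theory: the colony edge is described by its height
# h(t, x) and the local strain-1 fraction f(t, x), obeying
#
#   dh/dt = v0 + (v0/2) (dh/dx)^2 + Dh d2h/dx2 + alpha df/dx   [+ noise]
#   df/dt = Df d2f/dx2 - c(f) df/dx + v0 (dh/dx)(df/dx)        [+ noise]
#
# — a chiral extension of the KPZ equation coupled to a Burgers equation
# whose multiplicative noise (amplitude ~ sqrt(f(1-f))) encodes genetic
# drift.  alpha and beta are proportional to the chirality difference of
# the strains; f* is the composite chirality (see effective_f_star()).
#
# The local advection velocity of composition features is
#   c(f) = beta (1 - f* - f):
# a pure strain-1 (most left-handed) domain drifts along the front at
# -beta f*, a pure strain-2 domain at +beta (1 - f*).  This sign choice is
# fixed by the lattice model itself: sharp (shock-like) boundaries with a
# growing bulge form where f rises with x — the in-flow arrangement, with
# the left-handed strain on the right — while falling steps spread into
# rarefactions (dips), and flat-front boundaries of either type drift at
# v_par = beta (1/2 - f*), the mean of c over the step.

#' Effective-theory parameters
#'
#' @param v0 flat-front expansion speed (length/time), `> 0`.
#' @param Dh front smoothing coefficient (length^2/time), `> 0`.
#' @param alpha chiral shape coupling (length^2/time), `>= 0` under the
#'   strain-ordering convention.
#' @param Df fraction diffusivity (length^2/time), `> 0`.
#' @param beta chiral advection scale (length/time), `>= 0`.
#' @param f_star composite chirality (dimensionless).
#' @param sigma_h,sigma_f noise amplitudes (0 = noiseless).
#' @return Object of class `theory_params`.
#' @export
theory_params <- function(v0, Dh, alpha = 0, Df = Dh, beta = 0,
                          f_star = 0.5, sigma_h = 0, sigma_f = 0) {
  if (v0 <= 0 || Dh <= 0 || Df <= 0)
    stop("v0, Dh and Df must be positive")
  if (alpha < 0 || beta < 0)
    stop("alpha and beta must be non-negative (order the strains so the ",
         "first is the most left-handed)")
  if (sigma_h < 0 || sigma_f < 0) stop("noise amplitudes must be >= 0")
  structure(list(v0 = v0, Dh = Dh, alpha = alpha, Df = Df, beta = beta,
                 f_star = f_star, sigma_h = sigma_h, sigma_f = sigma_f),
            class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat("<theory_params> v0 =", x$v0, " Dh =", x$Dh, " alpha =", x$alpha,
      "\n  Df =", x$Df, " beta =", x$beta, " f* =", x$f_star,
      " sigma_h =", x$sigma_h, " sigma_f =", x$sigma_f, "\n")
  invisible(x)
}

#' Front fields h(x), f(x) on a periodic grid
#'
#' @param h front height profile.
#' @param f strain-1 fraction profile, in `[0, 1]`, same length as `h`.
#' @param dx grid spacing.
#' @param t time stamp.
#' @return Object of class `front_fields`.
#' @export
front_fields <- function(h, f, dx = 1, t = 0) {
  if (length(h) != length(f)) stop("h and f must have equal length")
  if (any(!is.finite(h))) stop("h must be finite")
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  structure(list(h = h, f = f, dx = dx, t = t), class = "front_fields")
}

#' Sharp-step initial condition for the front theory
#'
#' A periodic domain holding one rising and one falling step of `f`
#' (i.e. one boundary of each type), realised as hyperbolic-tangent
#' profiles of width `2 dx` to avoid grid-scale ringing, over a flat
#' front `h = 0`.  With strain 1 the more left-handed strain, the rising
#' step is the in-flow boundary.
#'
#' @param nx grid points.
#' @param dx grid spacing.
#' @param width step width (length units).
#' @param centers positions of the rising and falling steps; default
#'   1/4 and 3/4 of the domain.
#' @return A [front_fields()] object.
#' @export
step_front_fields <- function(nx, dx = 1, width = 2 * dx, centers = NULL) {
  L <- nx * dx
  x <- (seq_len(nx) - 1) * dx
  if (is.null(centers)) centers <- c(L / 4, 3 * L / 4)
  f <- 0.5 * (tanh((x - centers[1]) / width) -
                tanh((x - centers[2]) / width)) +
    0.5 * (tanh((x - centers[1] - L) / width) -
             tanh((x - centers[2] + L) / width)) + 1
  f <- pmin(1, pmax(0, f))
  front_fields(h = rep(0, nx), f = f, dx = dx)
}

#' Integrate the coupled front equations
#'
#' Finite-difference integration on a periodic grid: central differences
#' for the diffusion terms and the KPZ nonlinearity, first-order upwind
#' for the advection of `f` (upwind side chosen by the sign of the local
#' advection term `u = beta (f + f* - 1) + v0 dh/dx`, which is what
#' makes the shock-forming Burgers dynamics stable), Euler-Maruyama in
#' the Ito sense for the noise with multiplicative amplitude
#' `sigma_f sqrt(f(1-f))`; `f` is clipped to `[0, 1]` after every step.
#'
#' The time step must satisfy `dt <= 0.25 dx^2 / max(Dh, Df)` and
#' `dt <= 0.5 dx / max|u|`; violation raises an error rather than a
#' silent blow-up.
#'
#' @param fields a [front_fields()] object.
#' @param params a [theory_params()] object.
#' @param t_end integration time.
#' @param dt time step; defaults to the largest stable step (with a 20%
#'   safety margin on the advection bound).
#' @param record_every optionally record snapshots every so many time
#'   units.
#' @return The final [front_fields()] (with updated `t`); if
#'   `record_every` is set, attribute `"snapshots"` holds the recorded
#'   list.  Attribute `"clip_events"` counts clips of `f` into `[0, 1]`.
#' @export
integrate_front <- function(fields, params, t_end, dt = NULL,
                            record_every = NULL) {
  stopifnot(inherits(fields, "front_fields"),
            inherits(params, "theory_params"))
  h <- fields$h; f <- fields$f; dx <- fields$dx
  nx <- length(h)
  ip <- c(seq_len(nx)[-1], 1L)
  im <- c(nx, seq_len(nx)[-nx])
  v0 <- params$v0; Dh <- params$Dh; Df <- params$Df
  alpha <- params$alpha; beta <- params$beta; fs <- params$f_star
  diff_bound <- 0.25 * dx^2 / max(Dh, Df)
  # u f_x with u = -c(f) + v0 h_x  (advection velocity c = beta(1-f*-f))
  u_now <- function(h, f) beta * (f + fs - 1) + v0 * (h[ip] - h[im]) / (2 * dx)
  adv_bound <- function(u) 0.5 * dx / max(abs(u), 1e-12)
  if (is.null(dt)) dt <- min(diff_bound, 0.8 * adv_bound(u_now(h, f)))
  if (dt > diff_bound)
    stop("dt = ", signif(dt, 4), " violates the diffusive stability bound ",
         signif(diff_bound, 4))
  nsteps <- ceiling(t_end / dt)
  t <- fields$t
  clip_events <- 0L
  snapshots <- list()
  next_record <- if (is.null(record_every)) Inf else t + record_every
  noisy <- params$sigma_h > 0 || params$sigma_f > 0
  namp <- sqrt(dt / dx)
  for (s in seq_len(nsteps)) {
    hx <- (h[ip] - h[im]) / (2 * dx)
    hxx <- (h[ip] - 2 * h + h[im]) / dx^2
    fxx <- (f[ip] - 2 * f + f[im]) / dx^2
    fx_c <- (f[ip] - f[im]) / (2 * dx)
    u <- beta * (f + fs - 1) + v0 * hx
    if (max(abs(u)) * dt / dx > 1)
      stop("CFL violation at t = ", signif(t, 5), ": max |u| dt/dx = ",
           signif(max(abs(u)) * dt / dx, 4),
           " > 1; reduce dt or the advection couplings")
    fx_up <- ifelse(u > 0, (f[ip] - f) / dx, (f - f[im]) / dx)
    dh <- v0 + (v0 / 2) * hx^2 + Dh * hxx + alpha * fx_c
    df <- Df * fxx + u * fx_up
    if (noisy) {
      if (params$sigma_h > 0)
        dh <- dh + params$sigma_h * namp * stats::rnorm(nx) / dt
      if (params$sigma_f > 0)
        df <- df + params$sigma_f * sqrt(pmax(f * (1 - f), 0)) * namp *
          stats::rnorm(nx) / dt
    }
    h <- h + dt * dh
    f <- f + dt * df
    out <- f < 0 | f > 1
    if (any(out)) {
      clip_events <- clip_events + sum(out)
      f[f < 0] <- 0
      f[f > 1] <- 1
    }
    t <- t + dt
    if (t >= next_record) {
      snapshots[[length(snapshots) + 1]] <- front_fields(h, f, dx, t)
      next_record <- next_record + record_every
    }
  }
  out <- front_fields(h, f, dx, t)
  attr(out, "clip_events") <- clip_events
  if (!is.null(record_every)) attr(out, "snapshots") <- snapshots
  out
}

#' Triangular bulge profile at an in-flow boundary
#'
#' The noiseless front equations admit an exact long-time solution for
#' the excess height around a sharp in-flow boundary at `x_b`: a
#' triangle of slope magnitude `alpha/(2 Dh)` whose apex height
#' `v0 alpha^2 t / (8 Dh^2)` and half-width `v0 alpha t / (4 Dh)` grow
#' linearly in time.
#'
#' @param x positions.
#' @param t time (`> 0`).
#' @param params a [theory_params()].
#' @param x_b boundary position.
#' @return `h - v0 t` at the requested positions.
#' @export
bulge_profile <- function(x, t, params, x_b = 0) {
  stopifnot(inherits(params, "theory_params"))
  if (t <= 0) stop("t must be positive")
  with(params, {
    apex <- v0 * alpha^2 * t / (8 * Dh^2)
    pmax(0, apex - (alpha / (2 * Dh)) * abs(x - x_b))
  })
}

#' Equilibrium strain fraction
#'
#' At steady state the front is tiled by bulges and the relative
#' abundance of the strains is set by the ratio of the bulge slopes:
#'
#' \deqn{\bar f_{eq} = 0 \ (f^* \le 1/2 - \alpha v_0/(2 D_h \beta)); \quad
#'   1/2 + \frac{\beta D_h}{\alpha v_0}(f^* - 1/2) \ \text{inside}; \quad
#'   1 \ (f^* \ge 1/2 + \alpha v_0/(2 D_h \beta)).}
#'
#' The middle branch is the coexistence window; outside it one bulge
#' slope becomes horizontal and the less chiral strain is excluded.
#'
#' @param f_star composite chirality (vectorised).
#' @param params a [theory_params()] supplying `v0`, `Dh`, `alpha`,
#'   `beta`.
#' @return Equilibrium fraction(s) in `[0, 1]`.
#' @export
equilibrium_fraction <- function(f_star, params) {
  stopifnot(inherits(params, "theory_params"))
  v0 <- params$v0; Dh <- params$Dh
  alpha <- params$alpha; beta <- params$beta
  if (beta == 0) {
    if (alpha > 0) return(rep(0.5, length(f_star)))
    stop("degenerate parameters: alpha = beta = 0 gives no boundary ",
         "dynamics and no defined equilibrium fraction")
  }
  if (alpha == 0)   # zero-width coexistence window: a step at f* = 1/2
    return(ifelse(f_star < 0.5, 0, ifelse(f_star > 0.5, 1, 0.5)))
  slope <- beta * Dh / (alpha * v0)
  pmin(1, pmax(0, 0.5 + slope * (f_star - 0.5)))
}

#' Boundary drift velocity along a flat front
#'
#' Away from bulges, sector boundaries drift along the front with
#' velocity `v_par = beta (1/2 - f*)` — zero exactly for equal and
#' opposite chiralities, positive (towards larger x) when strain 1 is
#' the less chiral of an opposite-handed pair.
#'
#' @param f_star composite chirality.
#' @param beta chiral advection scale (`>= 0`).
#' @return `v_par`.
#' @export
boundary_drift_velocity <- function(f_star, beta) {
  if (any(beta < 0)) stop("beta must be >= 0")
  beta * (0.5 - f_star)
}

#' Growth velocity of a bulge apex
#'
#' The apex of a triangular bulge advances at
#' `v0 (1 + alpha^2 / (8 Dh^2))`, i.e. a mixture of strains with
#' opposite handedness expands faster than either strain alone.
#'
#' @param params a [theory_params()] with `alpha, Dh > 0`.
#' @return The apex velocity.
#' @export
apex_velocity <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  params$v0 + params$v0 * params$alpha^2 / (8 * params$Dh^2)
}
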
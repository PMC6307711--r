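# One time step of the lattice model is a deterministic update (logistic
# growth + direction-relative migration, computed synchronously from the
# time-t state) followed by two rounds of binomial sampling (demographic
# fluctuations, then genetic drift).  Three implementations of the
# deterministic part coexist and must agree element-wise:
#   * cpp_run()/cpp_deterministic_update() — the production path (src/),
#   * det_update_vectorized() — whole-matrix R, shift-based,
#   * det_update_reference() — a naive per-site double loop.
# All three group left/right and +x/-x contributions as commutative pairs,
# so reflecting x while swapping ml and mr is a bit-exact symmetry.

#' Expected logistic growth increment at a site
#'
#' `g * n_alpha * (1 - n_total/N) * dt`: growth is proportional to the
#' strain's own density and shuts off as the site fills up.
#'
#' @param n_alpha density of the focal strain at the site.
#' @param n_total total density (both strains).
#' @param params a [strain_params()].
#' @param N carrying capacity per site.
#' @param dt time step.
#' @return Expected density increment (same shape as the inputs).
#' @export
growth_increment <- function(n_alpha, n_total, params, N, dt = 1) {
  stopifnot(inherits(params, "strain_params"))
  if (any(n_alpha < 0) || any(n_total > N) || any(n_alpha > n_total))
    stop("invalid state: need 0 <= n_alpha <= n_total <= N")
  params$g * n_alpha * (1 - n_total / N) * dt
}

#' Expected migrant count along one direction
#'
#' The expected number of migrants of a strain from a source site towards
#' one of its four neighbours, given the total densities of the source,
#' the destination, and the three remaining neighbours of the source
#' labelled relative to the migration direction (left = 90 degrees
#' counterclockwise, right = clockwise, back = opposite):
#'
#' `n_src_alpha * (1 - n_dest/N) * (m0 + ms n_src/N + md n_dest/N +
#'   mb n_back/N + ml n_left/N + mr n_right/N)`
#'
#' The exclusion factor forbids migration into full sites, which freezes
#' the pattern in the saturated bulk.  Because the neighbour labels are
#' direction-relative, the four lattice directions are exactly equivalent.
#'
#' @param n_src_alpha focal-strain density at the source.
#' @param n_src,n_dest,n_left,n_back,n_right total densities.
#' @param params a [strain_params()].
#' @param N carrying capacity.
#' @return Expected migrants per unit time.
#' @examples
#' p <- strain_params(g = 0.03, ml = 0.045, mr = 0.005)
#' directional_flux(100, 100, 0, 100, 0, 0, p, N = 100)  # 4.5
#' @export
directional_flux <- function(n_src_alpha, n_src, n_dest, n_left, n_back,
                             n_right, params, N) {
  stopifnot(inherits(params, "strain_params"))
  dens <- c(n_src_alpha, n_src, n_dest, n_left, n_back, n_right)
  if (any(dens < 0) || any(dens > N))
    stop("invalid state: densities must lie in [0, N]")
  n_src_alpha * (1 - n_dest / N) *
    (params$m0 + params$ms * (n_src / N) + params$md * (n_dest / N) +
       params$mb * (n_back / N) +
       (params$ml * (n_left / N) + params$mr * (n_right / N)))
}

# --- shift helpers (width x height matrices; rows = x periodic, cols = y) ---
shift_xp <- function(A) A[c(seq_len(nrow(A))[-1], 1L), , drop = FALSE]
shift_xm <- function(A) A[c(nrow(A), seq_len(nrow(A) - 1L)), , drop = FALSE]
shift_yp <- function(A, pad) cbind(A[, -1L, drop = FALSE],
                                   matrix(pad, nrow(A), 1L))
shift_ym <- function(A, pad) cbind(matrix(pad, nrow(A), 1L),
                                   A[, -ncol(A), drop = FALSE])

# Out-fluxes of one strain in the four directions (matrices).
# bottom_pad is the total density assumed below row 1 (N for a linear
# front over saturated bulk, 0 for a radial colony).
flux_fields <- function(n_a, nt, params, N, bottom_pad) {
  H <- ncol(nt)
  f1 <- function(Dst, L, B, R)
    n_a * (1 - Dst / N) *
      (params$m0 + params$ms * (nt / N) + params$md * (Dst / N) +
         params$mb * (B / N) + (params$ml * (L / N) + params$mr * (R / N)))
  FE <- f1(shift_xp(nt), shift_yp(nt, 0), shift_xm(nt), shift_ym(nt, bottom_pad))
  FN <- f1(shift_yp(nt, 0), shift_xm(nt), shift_ym(nt, bottom_pad), shift_xp(nt))
  FW <- f1(shift_xm(nt), shift_ym(nt, bottom_pad), shift_xp(nt), shift_yp(nt, 0))
  FS <- f1(shift_ym(nt, bottom_pad), shift_xp(nt), shift_yp(nt, 0), shift_xm(nt))
  FN[, H] <- 0   # no migration off the lattice
  FS[, 1] <- 0
  list(E = FE, N = FN, W = FW, S = FS)
}

#' Net migration field for one strain
#'
#' The expected density change per site due to migration: the sum of the
#' four incoming fluxes minus the four outgoing ones (times `dt`).
#' Migration conserves cells, so the field sums to zero over the lattice.
#'
#' @param state a `lattice_state`.
#' @param strain which strain (1 or 2).
#' @param params the [strain_params()] of that strain.
#' @return A width x height matrix of expected density changes.
#' @export
migration_increment <- function(state, strain, params) {
  stopifnot(inherits(state, "lattice_state"), strain %in% c(1, 2))
  cfg <- state$config
  nt <- state$n1 + state$n2
  n_a <- if (strain == 1) state$n1 else state$n2
  bottom_pad <- if (identical(state$geometry, "linear")) cfg$N else 0
  Fx <- flux_fields(n_a, nt, params, cfg$N, bottom_pad)
  IN <- (shift_xp(Fx$W) + shift_xm(Fx$E)) +
        (shift_yp(Fx$S, 0) + shift_ym(Fx$N, 0))
  OUT <- (Fx$E + Fx$W) + (Fx$N + Fx$S)
  (IN - OUT) * cfg$dt
}

det_update_vectorized <- function(n1, n2, p1, p2, N, dt, bottom_pad) {
  nt <- n1 + n2
  rho_for <- function(n_a, p) {
    G <- p$g * n_a * (1 - nt / N)
    Fx <- flux_fields(n_a, nt, p, N, bottom_pad)
    IN <- (shift_xp(Fx$W) + shift_xm(Fx$E)) +
          (shift_yp(Fx$S, 0) + shift_ym(Fx$N, 0))
    OUT <- (Fx$E + Fx$W) + (Fx$N + Fx$S)
    n_a + (G + (IN - OUT)) * dt
  }
  rho1 <- rho_for(n1, p1)
  rho2 <- rho_for(n2, p2)
  clamped <- sum(rho1 < 0 | rho2 < 0)
  rho1[rho1 < 0] <- 0
  rho2[rho2 < 0] <- 0
  rt <- rho1 + rho2
  over <- rt > N
  clamped <- clamped + sum(over)
  if (any(over)) {
    sc <- N / rt[over]
    rho1[over] <- rho1[over] * sc
    rho2[over] <- rho2[over] * sc
  }
  list(rho1 = rho1, rho2 = rho2, clamp_events = clamped)
}

# Naive per-site double loop over the full lattice; the independent oracle.
# periodic_y = TRUE closes the lattice into a torus (used to check the
# 90-degree rotation equivariance of the direction-relative scheme).
det_update_reference <- function(n1, n2, p1, p2, N, dt, bottom_pad = N,
                                 periodic_y = FALSE) {
  W <- nrow(n1); H <- ncol(n1)
  nt <- n1 + n2
  tot <- function(i, j) {
    i <- ((i - 1) %% W) + 1
    if (periodic_y) j <- ((j - 1) %% H) + 1
    if (j < 1) return(bottom_pad)
    if (j > H) return(0)
    nt[i, j]
  }
  in_lattice_y <- function(j) periodic_y || (j >= 1 && j <= H)
  # neighbour offsets for migration direction d (E, N, W, S):
  # dest, left, back, right
  offs <- list(
    E = list(d = c(1, 0),  l = c(0, 1),  b = c(-1, 0), r = c(0, -1)),
    N = list(d = c(0, 1),  l = c(-1, 0), b = c(0, -1), r = c(1, 0)),
    W = list(d = c(-1, 0), l = c(0, -1), b = c(1, 0),  r = c(0, 1)),
    S = list(d = c(0, -1), l = c(1, 0),  b = c(0, 1),  r = c(-1, 0))
  )
  flux <- function(n_a, p, i, j, o) {
    if (!in_lattice_y(j)) return(0)
    ii <- ((i - 1) %% W) + 1
    jj <- if (periodic_y) ((j - 1) %% H) + 1 else j
    ns <- n_a[ii, jj]
    if (ns <= 0) return(0)
    dj <- j + o$d[2]
    if (!in_lattice_y(dj)) return(0)
    ntd <- tot(i + o$d[1], dj)
    excl <- 1 - ntd / N
    if (excl <= 0) return(0)
    ns * excl *
      (p$m0 + p$ms * (tot(i, j) / N) + p$md * (ntd / N) +
         p$mb * (tot(i + o$b[1], j + o$b[2]) / N) +
         (p$ml * (tot(i + o$l[1], j + o$l[2]) / N) +
            p$mr * (tot(i + o$r[1], j + o$r[2]) / N)))
  }
  rho_at <- function(n_a, p, i, j) {
    n <- n_a[i, j]
    G <- p$g * n * (1 - nt[i, j] / N)
    OUT <- (flux(n_a, p, i, j, offs$E) + flux(n_a, p, i, j, offs$W)) +
           (flux(n_a, p, i, j, offs$N) + flux(n_a, p, i, j, offs$S))
    IN <- (flux(n_a, p, i + 1, j, offs$W) + flux(n_a, p, i - 1, j, offs$E)) +
          (flux(n_a, p, i, j + 1, offs$S) + flux(n_a, p, i, j - 1, offs$N))
    n + (G + (IN - OUT)) * dt
  }
  rho1 <- matrix(0, W, H); rho2 <- matrix(0, W, H)
  clamped <- 0
  for (j in seq_len(H)) {
    for (i in seq_len(W)) {
      r1 <- rho_at(n1, p1, i, j)
      r2 <- rho_at(n2, p2, i, j)
      if (r1 < 0 || r2 < 0) {
        if (r1 < 0) r1 <- 0
        if (r2 < 0) r2 <- 0
        clamped <- clamped + 1
      }
      rt <- r1 + r2
      if (rt > N) {
        sc <- N / rt
        r1 <- r1 * sc; r2 <- r2 * sc
        clamped <- clamped + 1
      }
      rho1[i, j] <- r1; rho2[i, j] <- r2
    }
  }
  list(rho1 = rho1, rho2 = rho2, clamp_events = clamped)
}

#' Deterministic half of a time step
#'
#' Computes the auxiliary fields `rho1`, `rho2` — the expected occupancies
#' at the next time step — synchronously from the current state:
#' `rho = n + (G + M) dt` with growth `G` and net migration `M`.  The
#' fields are clamped to `[0, N]` (negative values to zero; the pair is
#' rescaled proportionally where the total exceeds `N`); clamping only
#' triggers for out-of-regime parameter choices and is counted in
#' `clamp_events`.
#'
#' @param state a `lattice_state`.
#' @param params1,params2 [strain_params()] for the two strains.
#' @param method `"fast"` (compiled, window only), `"vectorized"`
#'   (whole-lattice R) or `"reference"` (naive per-site double loop).
#'   The last two exist as oracles for the first.
#' @return A list with `rho1`, `rho2` and `clamp_events`.
#' @export
deterministic_update <- function(state, params1, params2,
                                 method = c("fast", "vectorized",
                                            "reference")) {
  method <- match.arg(method)
  cfg <- state$config
  bottom_pad <- if (identical(state$geometry, "linear")) cfg$N else 0
  if (method == "fast") {
    res <- cpp_deterministic_update(state$n1, state$n2,
                                    param_vec(params1), param_vec(params2),
                                    cfg$N, cfg$dt,
                                    state$ylo - 1L, state$yhi - 1L,
                                    bottom_pad == cfg$N)
    list(rho1 = res$rho1, rho2 = res$rho2, clamp_events = res$clamp_events)
  } else if (method == "vectorized") {
    det_update_vectorized(state$n1, state$n2, params1, params2,
                          cfg$N, cfg$dt, bottom_pad)
  } else {
    det_update_reference(state$n1, state$n2, params1, params2,
                         cfg$N, cfg$dt, bottom_pad)
  }
}

#' Demographic sampling round
#'
#' Draws the total occupancy of each site at the next time step from a
#' binomial law with `N` trials and success probability
#' `(rho1 + rho2)/N`, so the expectation matches the deterministic
#' dynamics, fluctuations scale as `sqrt(n)` for `n << N`, and the
#' occupancy can never exceed `N`.
#'
#' @param rho1,rho2 auxiliary fields from [deterministic_update()].
#' @param N carrying capacity.
#' @return An integer matrix of total occupancies.
#' @export
demographic_sampling <- function(rho1, rho2, N) {
  p <- (rho1 + rho2) / N
  if (any(p < 0) || any(p > 1 + 1e-12))
    stop("internal error: binomial probability outside [0, 1]; ",
         "clamping failed upstream")
  p[p > 1] <- 1
  matrix(rbinom(length(p), N, p), nrow(rho1), ncol(rho1))
}

#' Genetic drift sampling round
#'
#' Splits the freshly drawn total occupancy between the strains: strain 1
#' receives a binomial draw with `n_new` trials and success probability
#' `rho1/(rho1 + rho2)`; strain 2 gets the rest.  The expected fraction is
#' unchanged (drift is unbiased) and `f = 0`, `f = 1` are absorbing.
#'
#' @param n_new total occupancies from [demographic_sampling()].
#' @param rho1,rho2 auxiliary fields.
#' @return A list of integer matrices `n1`, `n2`.
#' @export
drift_sampling <- function(n_new, rho1, rho2) {
  rt <- rho1 + rho2
  q <- ifelse(rt > 0, rho1 / rt, 0)
  n1 <- matrix(rbinom(length(n_new), as.vector(n_new), as.vector(q)),
               nrow(n_new), ncol(n_new))
  n1[rt <= 0] <- 0L
  list(n1 = n1, n2 = n_new - n1)
}

#' Advance a lattice state by whole time steps
#'
#' Applies the composed update (deterministic + two binomial rounds)
#' inside the active window and advances the window with the front.  This
#' is the low-level stepper; [run_expansion()] adds recording, stop
#' handling and metadata.
#'
#' @param state a `lattice_state`.
#' @param params1,params2 [strain_params()] of the strains.
#' @param steps number of time steps.
#' @param freeze_saturated skip resampling of sites that sit, with all
#'   four neighbours, at carrying capacity (used for radial colonies,
#'   where a row window cannot follow the front; such sites have zero
#'   growth and migration, so this freezes the bulk).
#' @return The updated `lattice_state`, with attributes `front` (deepest
#'   occupied row), `hit_top` and `clamp_events`.
#' @export
lattice_step <- function(state, params1, params2, steps = 1,
                         freeze_saturated = !identical(state$geometry,
                                                       "linear")) {
  cfg <- state$config
  linear <- identical(state$geometry, "linear")
  res <- cpp_run(state$n1, state$n2,
                 param_vec(params1), param_vec(params2),
                 cfg$N, cfg$dt, as.integer(steps),
                 state$ylo - 1L, state$yhi - 1L,
                 linear, cfg$window_behind, cfg$window_ahead,
                 linear, freeze_saturated)
  state$n1 <- res$n1
  state$n2 <- res$n2
  state$t <- state$t + res$steps * cfg$dt
  state$ylo <- res$ylo + 1L
  state$yhi <- res$yhi + 1L
  attr(state, "front") <- res$front + 1L
  attr(state, "hit_top") <- res$hit_top
  attr(state, "clamp_events") <- res$clamp_events
  state
}
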
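#' Continuum coefficients of the lattice model
#'
#' In the deterministic limit the lattice dynamics obey a reaction-diffusion
#' equation whose flux contains a density-dependent diffusivity `D(n)`, a
#' straight (gradient-aligned) advection strength `S(n)` and a chiral
#' advection strength `A(n)` that changes sign under mirror reflection:
#'
#' \deqn{D(n) = [m_0 + (n/N)(m_s+m_d+m_l+m_b+m_r)](1-n/N)\,\Delta x^2/\Delta t}
#' \deqn{S(n) = [2(m_b-m_d)(1-n/N) + (m_0+m_s+m_d+m_l+m_b+m_r)]\,\Delta x^2/\Delta t}
#' \deqn{A(n) = 2(m_l-m_r)(1-n/N)\,\Delta x^2/\Delta t}
#'
#' `A` depends on the coefficients only through `ml - mr` while `D` depends
#' on `ml + mr`, so chirality and motility are independently tunable.
#' All three vanish at `n = N` when `m0 = 0`, which freezes the pattern in
#' the saturated colony bulk.
#'
#' @param params a [strain_params()] object.
#' @param n density (cells/site) at which to evaluate; may be a vector.
#' @param N carrying capacity per site.
#' @param dx,dt lattice spacing and time step.
#' @return A data frame with columns `n`, `D`, `S`, `A`.
#' @examples
#' p <- strain_params(g = 0.03, ml = 0.045, mr = 0.005)
#' continuum_coefficients(p, n = 0, N = 100)  # A = 0.08 at the leading edge
#' @export
continuum_coefficients <- function(params, n, N, dx = 1, dt = 1) {
  stopifnot(inherits(params, "strain_params"), N >= 1)
  if (any(n < 0 | n > N)) stop("density n must lie in [0, N]")
  u <- n / N
  msum <- params$ms + params$md + params$ml + params$mb + params$mr
  fac <- dx^2 / dt
  data.frame(
    n = n,
    D = (params$m0 + u * msum) * (1 - u) * fac,
    S = (2 * (params$mb - params$md) * (1 - u) + (params$m0 + msum)) * fac,
    A = 2 * (params$ml - params$mr) * (1 - u) * fac
  )
}

#' Composite chirality parameter f*
#'
#' For two strains with chiralities `chi1` and `chi2` (see [chirality()]),
#' the effective front theory depends on their relative chirality through
#' `f* = chi1 / (chi1 - chi2)`, with the convention that strain 1 is the
#' most left-handed (least right-handed) of the two, so that the theory's
#' couplings are positive.  If the arguments violate the convention they
#' are swapped internally and the swap is reported.
#'
#' Interpretation: `f* = 1/2` means equal but opposite chiralities;
#' `f* = 1` a left-handed vs a non-chiral strain; `f* = 0` a non-chiral vs
#' a right-handed strain; `f*` outside `[0, 1]` means the strains share
#' the same handedness.
#'
#' @param chi1,chi2 signed chirality measures, or [strain_params()] objects.
#' @return A list with elements `f_star`, `swapped`, `chi1`, `chi2`
#'   (ordered so `chi1 > chi2`).
#' @examples
#' effective_f_star(0.08, -0.08)$f_star  # 1/2
#' effective_f_star(0.08, 0)$f_star      # 1
#' effective_f_star(0, -0.08)$f_star     # 0
#' @export
effective_f_star <- function(chi1, chi2) {
  if (inherits(chi1, "strain_params")) chi1 <- chirality(chi1)
  if (inherits(chi2, "strain_params")) chi2 <- chirality(chi2)
  if (chi1 == chi2)
    stop("strains have equal chirality (chi1 == chi2): ",
         "f* is undefined and no composite boundary dynamics exist")
  swapped <- chi1 < chi2
  if (swapped) { tmp <- chi1; chi1 <- chi2; chi2 <- tmp }
  list(f_star = chi1 / (chi1 - chi2), swapped = swapped,
       chi1 = chi1, chi2 = chi2)
}

#' Empirical estimates of the effective-theory ratios
#'
#' The front theory's couplings cannot be computed a priori from the
#' lattice parameters; they are estimated from simulation output the same
#' way one would estimate them from experimental colony profiles:
#'
#' * `alpha/Dh` from the fitted slope(s) of a bulge at an in-flow
#'   boundary — for a symmetric bulge (`f* = 1/2`) the magnitude of each
#'   slope is `alpha/(2 Dh)`, so `alpha/Dh = 2 |slope|`;
#' * `beta/v0` from the measured drift velocity `v_par` of boundaries on
#'   flat front segments, using `v_par = beta (1/2 - f*)`.
#'
#' The ratio of the two, `(beta/v0) / (alpha/Dh) = beta Dh / (alpha v0)`,
#' is the predicted slope of the equilibrium fraction versus `f*` in the
#' coexistence window (see [equilibrium_fraction()]).
#'
#' @param bulge_slopes fitted bulge slope(s); magnitudes are averaged.
#' @param slope_se optional standard error(s) of the slopes.
#' @param v_par measured boundary drift velocity on flat front segments.
#' @param v_par_se optional standard error of `v_par`.
#' @param v0 measured flat-front expansion velocity.
#' @param f_star composite chirality of the pair (see [effective_f_star()]).
#' @return A list with `alpha_over_Dh`, `beta_over_v0`, their standard
#'   errors (`NA` when not derivable), and `coexistence_slope`.
#' @examples
#' est <- estimate_theory_ratios(bulge_slopes = 0.040, v_par = 0.017,
#'                               v0 = 0.25, f_star = 0.75)
#' est$alpha_over_Dh  # 0.08
#' @export
estimate_theory_ratios <- function(bulge_slopes = NULL, slope_se = NULL,
                                   v_par = NULL, v_par_se = NULL,
                                   v0 = NULL, f_star = NULL) {
  out <- list(alpha_over_Dh = NA_real_, alpha_over_Dh_se = NA_real_,
              beta_over_v0 = NA_real_, beta_over_v0_se = NA_real_,
              coexistence_slope = NA_real_)
  if (!is.null(bulge_slopes)) {
    out$alpha_over_Dh <- 2 * mean(abs(bulge_slopes))
    if (!is.null(slope_se))
      out$alpha_over_Dh_se <- 2 * sqrt(mean(slope_se^2) / length(slope_se))
  }
  if (!is.null(v_par)) {
    if (is.null(v0) || is.null(f_star))
      stop("estimating beta/v0 from v_par requires v0 and f_star")
    if (f_star == 0.5) {
      warning("f* = 1/2: boundary drift vanishes by symmetry and beta/v0 ",
              "is indeterminate from v_par; use the symmetric bulge-slope ",
              "estimator instead")
    } else {
      out$beta_over_v0 <- v_par / (v0 * (0.5 - f_star))
      if (!is.null(v_par_se))
        out$beta_over_v0_se <- abs(v_par_se / (v0 * (0.5 - f_star)))
    }
  }
  if (is.finite(out$alpha_over_Dh) && is.finite(out$beta_over_v0) &&
      out$alpha_over_Dh > 0)
    out$coexistence_slope <- out$beta_over_v0 / out$alpha_over_Dh
  out
}
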
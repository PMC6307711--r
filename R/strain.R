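#' Per-strain growth and migration parameters
#'
#' A strain is described by a per-capita growth rate `g` and six
#' dimensionless migration coefficients.  Migration between neighbouring
#' lattice sites is density dependent, and the coefficients are assigned
#' *relative to the direction of the migration*: `m0` is independent of the
#' neighbourhood, `ms` multiplies the density at the source site, `md` at
#' the destination, `ml` at the site 90 degrees counterclockwise ("left")
#' of the migration direction, `mb` behind the source, and `mr` clockwise
#' ("right").  The asymmetry `ml - mr` makes a strain chiral (positive =
#' left-handed) without changing its motility, which depends on `ml + mr`.
#'
#' The expected number of migrants leaving a site in one time step cannot
#' exceed the occupancy of that site, which bounds the coefficient sum:
#' `m0 + ms + md + ml + mb + mr <= 1` is required at construction.
#'
#' @param g per-capita growth rate (1/time step), `>= 0`.
#' @param m0,ms,md,ml,mb,mr migration coefficients, all `>= 0`.
#' @return An object of class `strain_params`.
#' @examples
#' left  <- strain_params(g = 0.1, ml = 0.09, mr = 0.01)
#' right <- strain_params(g = 0.1, ml = 0.01, mr = 0.09)
#' chirality(left)   #  0.08
#' chirality(right)  # -0.08
#' @export
strain_params <- function(g, m0 = 0, ms = 0, md = 0, ml = 0, mb = 0, mr = 0) {
  vals <- c(g = g, m0 = m0, ms = ms, md = md, ml = ml, mb = mb, mr = mr)
  if (length(vals) != 7L || any(!is.finite(vals)))
    stop("all strain parameters must be finite scalars")
  if (any(vals < 0))
    stop("strain parameters must be non-negative; got ",
         paste(names(vals)[vals < 0], collapse = ", "), " < 0")
  msum <- m0 + ms + md + ml + mb + mr
  if (msum > 1)
    stop("migration coefficients sum to ", signif(msum, 4),
         " > 1; a site would emit more migrants than it holds")
  structure(as.list(vals), class = "strain_params")
}

#' @export
print.strain_params <- function(x, ...) {
  cat("<strain_params>  g =", x$g, "\n")
  cat("  m0 =", x$m0, " ms =", x$ms, " md =", x$md,
      " ml =", x$ml, " mb =", x$mb, " mr =", x$mr, "\n")
  cat("  chirality (ml - mr):", x$ml - x$mr,
      if (x$ml > x$mr) "(left-handed)"
      else if (x$ml < x$mr) "(right-handed)" else "(non-chiral)", "\n")
  invisible(x)
}

# parameter vector in the order the C++ kernel expects
param_vec <- function(p) {
  stopifnot(inherits(p, "strain_params"))
  c(p$g, p$m0, p$ms, p$md, p$ml, p$mb, p$mr)
}

#' Signed chirality of a strain
#'
#' The handedness measure `ml - mr`: positive for a left-handed strain,
#' negative for a right-handed one, zero for a non-chiral strain.  It is
#' invariant under any change of the coefficients that keeps `ml - mr`
#' fixed, so chirality can be varied independently of motility
#' (`ml + mr`).
#'
#' @param params a [strain_params()] object.
#' @return A signed scalar.
#' @export
chirality <- function(params) {
  stopifnot(inherits(params, "strain_params"))
  params$ml - params$mr
}
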
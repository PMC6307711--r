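# Shared parameter sets and small utilities for the suite.

# equal-and-opposite pair (f* = 1/2)
lh_strain <- function(g = 0.1) strain_params(g = g, ml = 0.09, mr = 0.01)
rh_strain <- function(g = 0.1) strain_params(g = g, ml = 0.01, mr = 0.09)

# a generic "all coefficients nonzero" pair for symmetry tests
full_strain_a <- function()
  strain_params(g = 0.1, m0 = 0.01, ms = 0.02, md = 0.03, ml = 0.09,
                mb = 0.02, mr = 0.01)
full_strain_b <- function()
  strain_params(g = 0.12, ml = 0.01, mr = 0.09, mb = 0.05)

swap_lr <- function(p)
  strain_params(g = p$g, m0 = p$m0, ms = p$ms, md = p$md,
                ml = p$mr, mb = p$mb, mr = p$ml)

reflect_x <- function(M) M[nrow(M):1, , drop = FALSE]

rot90 <- function(A) t(A)[, nrow(A):1]

# opposite-handed pair with chirality difference dchi at composite f*
fstar_pair <- function(f_star, dchi = 0.1, msum = 0.1, g = 0.1, m0 = 0) {
  chi1 <- f_star * dchi
  chi2 <- chi1 - dchi
  list(strain_params(g = g, m0 = m0, ml = (msum + chi1) / 2,
                     mr = (msum - chi1) / 2),
       strain_params(g = g, m0 = m0, ml = (msum + chi2) / 2,
                     mr = (msum - chi2) / 2))
}

tail_mean <- function(history, col = "fbar", frac = 0.4) {
  n <- nrow(history)
  mean(history[[col]][history$t >= (1 - frac) * history$t[n]])
}
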
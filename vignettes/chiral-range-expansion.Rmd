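---
title: "Chiral range expansions: model, effective theory, and measurement choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chiral range expansions: model, effective theory, and measurement choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Many cellular aggregates — microbial colonies, biofilm edges, solid
tumours — grow almost exclusively at their rim, and the cells at the rim
can move with a *chiral* bias: their displacement makes a consistent
non-zero angle with the local density gradient, so lineages curl
clockwise or counterclockwise as the aggregate expands.  `chirex`
simulates two such strains competing at a growing front, measures the
resulting spatial patterns, and compares them with an effective
interface theory.  This vignette records the model, the meaning and
default of every tunable parameter, and the numerical and measurement
choices that are not forced by the science, so that results can be
interpreted (and distrusted) correctly.

## The lattice model

The habitat is a rectangular grid (x periodic, the colony grows towards
larger y) whose sites hold at most `N` cells — each site is a deme, and
`N` sets the strength of demographic noise and genetic drift.  A time
step has a deterministic and a stochastic half.

**Deterministic half.** For each strain an auxiliary field
`rho = n + (G + M) dt` collects the expected occupancy at the next
step, computed synchronously from the current state.  Growth is
logistic, `G = g n (1 - n_tot/N)`, and shuts off in the saturated bulk.
Migration moves cells between nearest neighbours with the expected flux

```
flux(src -> dest) = n_src * (1 - n_dest/N) *
    (m0 + ms n_src/N + md n_dest/N + ml n_left/N + mb n_back/N + mr n_right/N)
```

where *left*, *back*, *right* are labelled **relative to the migration
direction** (left = 90° counterclockwise).  This direction-relative rule
keeps the four lattice directions exactly equivalent — rotating a
configuration by 90° rotates the update — while the asymmetry
`ml - mr` breaks the left–right mirror symmetry: it is the strain's
chirality.  Because motility depends on `ml + mr` but chirality on
`ml - mr`, the two can be tuned independently; this is the model's
central experimental control, impossible to achieve cleanly in living
strains.  The exclusion factor `(1 - n_dest/N)` forbids immigration
into full sites, so the interior pattern freezes, as in real colonies
where growth is confined to the edge.

**Stochastic half.** Two rounds of binomial sampling: the total
occupancy of each site is drawn as `Binomial(N, (rho1 + rho2)/N)`
(demographic fluctuations; the mean matches the deterministic dynamics
and the total can never exceed `N`), then strain 1's share is drawn as
`Binomial(n_new, rho1/(rho1 + rho2))` (genetic drift; unbiased, with
`f = 0` and `f = 1` absorbing).

**Clamping.** At extreme parameter combinations the deterministic half
can transiently leave `[0, N]`; `rho` is clamped at zero and the pair
rescaled proportionally where the total exceeds `N`, and every such
event is counted and reported as a warning, because it signals
out-of-regime parameters rather than normal operation.  None of the
scenarios shipped with the package trigger it.

**Active window.** Only rows near the front are updated.  For linear
fronts the window spans 30 rows behind to 30 rows ahead of the deepest
occupied row (no published window depth exists, so this is a package
choice: 30 rows is several times the front width of every shipped
parameter set, so growth and migration vanish at both window edges).
For radial colonies a row window cannot follow the front, so bulk
freezing uses the equivalent saturation rule: a site surrounded by
saturated sites has zero growth and zero flux, and is exempted from
resampling.  Migration across the top/bottom lattice edge is forbidden
outright, which is what makes cell number conservation exact rather
than approximate.

**Randomness.** All draws go through R's RNG in a fixed order (x
fastest, then y, demographic before drift), so a run is reproducible
bit-for-bit from `set.seed()`; scenario runs record their seed in the
metadata.

## From lattice to continuum

Expanding the migration rule to lowest order in gradients gives a
reaction–diffusion description whose flux carries a density-dependent
diffusivity `D(n)`, a gradient-aligned advection `S(n)`, and a chiral
advection `A(n) = 2 (ml - mr)(1 - n/N) dx^2/dt` — the only term that
changes sign under mirror reflection (`continuum_coefficients()`).
`A > 0` means left-handed here; in a radial colony this handedness
twists sector boundaries counterclockwise.

For two strains the effective composite parameters are the chiralities
`chi = ml - mr` and `f* = chi1/(chi1 - chi2)` (`effective_f_star()`),
with strains ordered so that strain 1 is the most left-handed.
`f*` in `(0, 1)` means opposite handedness; `f* = 1/2` equal and
opposite; `f*` outside `[0, 1]` the same handedness.

## The effective front theory

Since growth is confined to the rim, the dynamics reduce to two fields
on a line: the front height `h(t, x)` and the strain-1 fraction
`f(t, x)`:

* height: `dh/dt = v0 + (v0/2)(dh/dx)^2 + Dh d2h/dx2 + alpha df/dx`
  (+ additive noise) — a KPZ-type growth law plus a *chiral* coupling:
  composition gradients tilt the front;
* fraction: `df/dt = Df d2f/dx2 - c(f) df/dx + v0 (dh/dx)(df/dx)`
  (+ multiplicative noise with amplitude proportional to
  `sqrt(f(1-f))`, so monomorphic fronts stay monomorphic) — a Burgers
  equation whose advection velocity `c(f) = beta (1 - f* - f)`
  transports composition features along the front.

A genuinely open design point sits in the advection term: symmetry
arguments fix its form only up to an overall sign convention, and the
two readings predict opposite phenomenology.  We fixed it empirically
against the lattice model: in lattice runs with `f* = 1/2`, sharp
boundaries with a growing bulge form where
`f` *rises* with x (the in-flow arrangement — biases pointing towards
each other, left-handed strain on the right), and with `f* = 1` the
boundaries drift towards negative x.  `c(f) = beta (1 - f* - f)`
reproduces both: rising steps are Burgers shocks (self-sharpening,
which is why sector boundaries stay sharp without any drift), falling
steps are rarefactions (dips that deepen only logarithmically), and
flat-front boundaries of either type drift at
`v_par = beta (1/2 - f*)`.

Closed forms implemented alongside the integrator:

* `bulge_profile()` — the long-time triangular bulge: slope magnitude
  `alpha/(2 Dh)`, apex height `v0 alpha^2 t/(8 Dh^2)`, half-width
  `v0 alpha t/(4 Dh)`;
* `apex_velocity()` — `v0 (1 + alpha^2/(8 Dh^2))`: an opposite-handed
  mixture outruns either strain alone;
* `equilibrium_fraction()` — the steady state once bulges tile the
  front: `f_eq = 1/2 + (beta Dh/(alpha v0)) (f* - 1/2)` inside the
  coexistence window `|f* - 1/2| < alpha v0/(2 Dh beta)`, exclusion
  (0 or 1) outside;
* `boundary_drift_velocity()` — `beta (1/2 - f*)`.

`alpha` and `beta` cannot be computed a priori from the lattice
coefficients here; like an experimentalist, `estimate_theory_ratios()`
recovers `alpha/Dh` from fitted bulge slopes and `beta/v0` from
measured boundary drift.

## Numerics of the integrator

`integrate_front()` uses central differences for both diffusion terms
and the KPZ nonlinearity, and first-order upwind differencing for the
advection of `f`, with the upwind side chosen per grid point from the
sign of the local advection term — the standard stabilisation for
shock-forming Burgers dynamics.  The time step must satisfy
`dt <= 0.25 dx^2/max(Dh, Df)` and `dt <= 0.5 dx/max|u|`; the
integrator errors out rather than integrating an unstable scheme, and
re-checks the advection bound every step because `|dh/dx|` grows with
the bulges.  Noise uses Euler–Maruyama in the Ito convention with `f`
clipped to `[0, 1]` afterwards (clips are counted); the noise
amplitudes are free parameters with default 0, since no published
values exist.  Sharp initial steps are realised as tanh profiles of
width `2 dx` to avoid grid-scale ringing.

Two numerical regime warnings, found while validating against the
closed forms and worth knowing about:

* the triangular-bulge solution assumes a *sharp* boundary.  In the
  noiseless PDE the shock at an in-flow boundary stays sharp only while
  its self-sharpening rate `beta/2` comfortably exceeds the defocusing
  tilt `v0 alpha/(2 Dh)` of the bulge it creates; outside that regime
  the realised slopes fall measurably below `alpha/(2 Dh)`.  (On the
  lattice, genetic drift keeps boundaries sharp instead.)
* the triangle is a long-time asymptote; its edges carry rounding of
  width `~ 2 Dh/(v0 slope)`, so slope fits should use an interior
  window (the tests fit 15–55% of the half-width and run to times
  where the half-width is several times the rounding).

## Observables: operational definitions

The source material never defines its measurements operationally, so
these are package choices, stated here once:

* **front height** `h(x)`: the largest row where total occupancy
  reaches `N/2`, linearly interpolated between the bracketing rows (a
  flat saturated front at row k reads k + 1/2);
* **front fraction** `f(x)`: strain-1 share of all cells in a band of
  10 rows behind `h(x)`; columns with an empty band are flagged, not
  imputed;
* **boundaries**: crossings of 1/2 of the fraction profile after a
  5-column circular moving average (suppresses single-site drift
  noise); a rising crossing is in-flow when strain 1 is the more
  left-handed.  Tracking across snapshots is nearest-neighbour with a
  periodic wrap and a configurable matching radius;
* **heterozygosity** comes in two flavours: column-band
  `H = mean(2 f(x)(1 - f(x)))` from the profile, and per-site
  `H = mean(2 f_site (1 - f_site))` over occupied sites
  (`site_heterozygosity()`).  The per-site version is the one used for
  the segregation/intermixing phase diagram, because it vanishes under
  segregation no matter how finely sectors interleave; the band version
  would not.  The same per-site quantity summed per row gives the
  boundary width measure (`boundary_width()`);
* **spiral fits**: boundary angles are read from the frozen pattern in
  radial steps of one site, unwrapped by continuity (the angular
  matching tolerance shrinks as 1/r since a fixed lateral displacement
  subtends a shrinking angle), and each boundary's initial angle is
  subtracted before averaging.  Sectors die by coarsening, so the fit
  range extends only as far as a minimum number of boundaries (default
  2) survives — fitting dying boundaries would bias the twist towards
  whatever killed them.  `theta = c0 + c1 ln r` is then an ordinary
  least-squares fit; `c1 > 0` is counterclockwise.

## What the scenarios emulate, and what they do not

The scenario registry (`chirex_scenarios()`) carries the published
parameter sets of the competition experiments this model was built
around: sectoring radial colonies (`radial_sectors`), takeover of a
non-chiral resident (`chiral_invasion`), 50:50 coexistence of
equal-and-opposite strains (`symmetric_coexistence`), growth-penalty
scans (`growth_penalty_*`), bulge formation (`bulge`), the equilibrium
fraction versus `f*` (`fstar_scan`), and the segregation/intermixing
transition (`mixing_N`, `mixing_chirality`).  Each ships at its
original size (`scaled = FALSE`) and at a desk scale with linear
dimensions reduced roughly 3–5x, which the tests and the acceptance
script use; stochastic summaries at desk scale carry proportionally
wider error bars, and the test tolerances say so explicitly.

Problem sizes used by the automated checks (package choices, stated
for reproducibility): coexistence runs 200x1000 at N = 100;
growth-penalty scans 100x800 (g = 0.01 branch) and 100x1200 at
N = 200; the equilibrium-fraction scan 300x5000 at N = 200 with paired
starts at 0.3/0.7 of the ten steady-state points; radial colonies
300x300 from radius 15; mixing scans 250x1200.  The
equilibrium-fraction scan deserves a caution flag: near the mixing
transition `f_bar` wanders with a long correlation time, and runs an
order of magnitude shorter than these visibly underestimate the slope
of `f_eq(f*)` — they are still in the transient.

The generator emulates demographic noise, drift, chiral migration and
frozen-pattern formation.  It does **not** emulate mechanical cell–cell
interactions, cell shape or adhesion, nutrient fields, 3D structure,
or off-lattice motion; the 7% growth-penalty threshold, for instance,
is a property of this reaction–diffusion caricature, not a biological
constant.  Passing tests therefore certify the implementation and its
internal theory, not quantitative predictions for any particular
organism.

## Known limitations

* The proportionality between (`alpha`, `beta`) and the lattice
  parameters is treated as empirical; only the ratios `alpha/Dh` and
  `beta/v0` are recovered, by fitting.
* The noisy effective equations are integrated but their
  universality-class behaviour is out of scope, as is any critical
  analysis of the intermixing transition.
* At strong asymmetry (`f*` near the coexistence edges) the
  equilibrium fraction deviates from linearity; the linear fit is only
  meaningful well inside the window.
* The spiral fit assumes boundaries survive the fitted radius range;
  heavily coarsened colonies (small N, weak chirality) may refuse the
  fit rather than return a biased one.
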
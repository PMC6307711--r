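Package: chirex
Title: Chiral Range Expansions in Compact Cellular Aggregates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic lattice (stepping-stone) simulations of two strains
    with tunable chiral motility competing at the growing edge of a compact
    cellular aggregate such as a microbial colony. Growth is logistic and
    migration is density dependent with coefficients assigned relative to the
    direction of motion, so a strain can be made left- or right-handed without
    changing its motility. Demographic fluctuations and genetic drift enter
    through two rounds of binomial resampling. The package also provides the
    matching continuum coefficients, an effective front theory (a chiral
    Kardar-Parisi-Zhang equation coupled to a noisy Burgers equation) with a
    finite-difference integrator and its closed-form predictions (triangular
    bulges at sector boundaries, equilibrium strain fractions, boundary drift
    velocities), and measurement utilities: front profiles, heterozygosity,
    expansion velocities, sector-boundary tracking, logarithmic-spiral fits,
    and bulge-slope estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
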
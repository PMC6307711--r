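# Named simulation scenarios with published parameter sets, plus a
# parameter-scan driver and deterministic fixture generators for tests.

#' Scenario registry
#'
#' Each scenario bundles the geometry, lattice size, strain parameters
#' and initial condition of one published competition experiment, at two
#' scales: `full` (the original lattice) and `scaled` (a desk-scale
#' variant with the linear dimensions reduced, for quick exploration —
#' stochastic outcomes carry correspondingly wider error bars).
#'
#' Available scenarios:
#' * `radial_sectors` — radial colony of two equally chiral strains;
#'   sector boundaries twist as logarithmic spirals.
#' * `chiral_invasion` — a localized chiral patch invades and displaces
#'   a non-chiral resident of equal growth rate and motility.
#' * `symmetric_coexistence` — equal-and-opposite chiralities from
#'   well-mixed initial conditions; the fraction converges to 1/2.
#' * `growth_penalty_same_hand` — chiral vs faster-growing non-chiral
#'   strain, scanned over the growth-rate difference `dg` (percent).
#' * `growth_penalty_opposite` — opposite handedness with a growth-rate
#'   difference.
#' * `bulge` — weakly chiral opposite pair started from two domains;
#'   used to measure bulge shapes.
#' * `fstar_scan` — opposite-handed pair at fixed chirality difference
#'   `dchi`, parameterised by the composite chirality `f_star`.
#' * `mixing_N` — opposite pair at fixed chirality; deme size `N` tunes
#'   genetic drift across the segregation/intermixing transition.
#' * `mixing_chirality` — fixed `N`; common chirality magnitude `chi`
#'   tunes the same transition.
#' * `velocity_check` — single strains of equal motility and varying
#'   chirality (expansion velocity must not depend on chirality).
#'
#' @return Named list of scenario objects (class `chirex_scenario`).
#' @export
chirex_scenarios <- function() {
  sc <- list(
    radial_sectors = list(
      geometry = "radial", f0 = 0.5,
      g = 0.03, N = 100,
      strain1 = c(ml = 0.045, mr = 0.005),
      strain2 = c(ml = 0.045, mr = 0.005),
      full = list(width = 700, height = 700, radius = 30),
      scaled = list(width = 300, height = 300, radius = 15)
    ),
    chiral_invasion = list(
      geometry = "linear", mode = "single_patch", f0 = 0.1,
      g = 0.1, N = 200,
      strain1 = c(ml = 0.09, mr = 0.01),     # the chiral invader
      strain2 = c(ml = 0.05, mr = 0.05),     # non-chiral resident
      full = list(width = 600, height = 3300),
      scaled = list(width = 200, height = 1000)
    ),
    symmetric_coexistence = list(
      geometry = "linear", mode = "well_mixed", f0 = 0.5,
      g = 0.1, N = 200,
      strain1 = c(ml = 0.09, mr = 0.01),
      strain2 = c(ml = 0.01, mr = 0.09),
      full = list(width = 600, height = 3000),
      scaled = list(width = 200, height = 1000, N = 100)
    ),
    growth_penalty_same_hand = list(
      geometry = "linear", mode = "well_mixed", f0 = 0.5,
      g = 0.01, N = 200, dg = 0,
      strain1 = c(ml = 0.10, mr = 0.00),
      strain2 = c(ml = 0.05, mr = 0.05),
      full = list(width = 1000, height = 3600),
      scaled = list(width = 150, height = 1200)
    ),
    growth_penalty_opposite = list(
      geometry = "linear", mode = "well_mixed", f0 = 0.5,
      g = 0.1, N = 200, dg = 0,
      strain1 = c(ml = 0.09, mr = 0.01),
      strain2 = c(ml = 0.01, mr = 0.09),
      full = list(width = 500, height = 3000),
      scaled = list(width = 150, height = 1200)
    ),
    bulge = list(
      geometry = "linear", mode = "two_domains", f0 = 0.5,
      g = 0.1, N = 200,
      strain1 = c(ml = 0.009, mr = 0.001),
      strain2 = c(ml = 0.001, mr = 0.009),
      full = list(width = 2400, height = 2100),
      scaled = list(width = 400, height = 700)
    ),
    fstar_scan = list(
      geometry = "linear", mode = "well_mixed", f0 = 0.5,
      g = 0.1, N = 200, m0 = 0.01, msum = 0.1, dchi = 0.1, f_star = 0.5,
      full = list(width = 300, height = 3000),
      scaled = list(width = 300, height = 1500)
    ),
    mixing_N = list(
      geometry = "linear", mode = "well_mixed", f0 = 0.5,
      g = 0.1, N = 40,
      strain1 = c(ml = 0.075, mr = 0.025),
      strain2 = c(ml = 0.025, mr = 0.075),
      full = list(width = 1000, height = 8000),
      scaled = list(width = 250, height = 1500)
    ),
    mixing_chirality = list(
      geometry = "linear", mode = "well_mixed", f0 = 0.5,
      g = 0.1, N = 200, msum = 0.1, chi = 0.05,
      full = list(width = 1000, height = 8000),
      scaled = list(width = 250, height = 1500)
    ),
    velocity_check = list(
      geometry = "linear", mode = "well_mixed", f0 = 1,
      g = 0.1, N = 200, msum = 0.1, chi = 0.08,
      full = list(width = 200, height = 1000),
      scaled = list(width = 200, height = 800)
    )
  )
  lapply(names(sc), function(nm) {
    s <- sc[[nm]]; s$name <- nm
    class(s) <- "chirex_scenario"
    s
  }) -> out
  names(out) <- names(sc)
  out
}

# strains for scenarios parameterised by (f_star, dchi, msum) or (chi, msum)
scenario_strains <- function(s) {
  m0 <- if (is.null(s$m0)) 0 else s$m0
  g2 <- s$g * (1 + (if (is.null(s$dg)) 0 else s$dg) / 100)
  if (!is.null(s$f_star)) {
    chi1 <- s$f_star * s$dchi
    chi2 <- chi1 - s$dchi
    list(
      strain_params(g = s$g, m0 = m0, ml = (s$msum + chi1) / 2,
                    mr = (s$msum - chi1) / 2),
      strain_params(g = g2, m0 = m0, ml = (s$msum + chi2) / 2,
                    mr = (s$msum - chi2) / 2)
    )
  } else if (!is.null(s$chi)) {
    list(
      strain_params(g = s$g, m0 = m0, ml = (s$msum + s$chi) / 2,
                    mr = (s$msum - s$chi) / 2),
      strain_params(g = g2, m0 = m0, ml = (s$msum - s$chi) / 2,
                    mr = (s$msum + s$chi) / 2)
    )
  } else {
    list(
      strain_params(g = s$g, m0 = m0, ml = s$strain1[["ml"]],
                    mr = s$strain1[["mr"]]),
      strain_params(g = g2, m0 = m0, ml = s$strain2[["ml"]],
                    mr = s$strain2[["mr"]])
    )
  }
}

#' Run a named scenario
#'
#' Builds the lattice and strain parameters of a registered scenario
#' (optionally at desk scale and with field overrides), runs it to
#' completion with [run_expansion()], and optionally writes the snapshot
#' and metadata to a directory.
#'
#' @param scenario a scenario name (see [chirex_scenarios()]) or a
#'   `chirex_scenario` object.
#' @param seed RNG seed (recorded in the metadata).
#' @param scaled use the desk-scale lattice (default) or the full one.
#' @param overrides named list of scenario fields to replace, e.g.
#'   `list(f0 = 0.25, dg = 3, height = 2000)`; size fields (`width`,
#'   `height`, `radius`, `N`) apply to the chosen scale.
#' @param max_steps,record_every passed to [run_expansion()].
#' @param out_dir optional output directory for snapshot + metadata.
#' @return The `chirex_run`, with the resolved scenario in `$scenario`.
#' @export
run_scenario <- function(scenario, seed = NULL, scaled = TRUE,
                         overrides = list(), max_steps = 100000,
                         record_every = 200, out_dir = NULL) {
  if (is.character(scenario)) {
    reg <- chirex_scenarios()
    if (!scenario %in% names(reg))
      stop("unknown scenario '", scenario, "'; see chirex_scenarios()")
    scenario <- reg[[scenario]]
  }
  stopifnot(inherits(scenario, "chirex_scenario"))
  size <- if (scaled) scenario$scaled else scenario$full
  s <- modifyList(scenario, size)
  if (length(overrides)) s <- modifyList(s, overrides)
  if (!is.null(seed)) set.seed(seed)
  strains <- scenario_strains(s)
  cfg <- lattice_config(s$width, s$height, s$N)
  st <- if (identical(s$geometry, "radial")) {
    init_circular_colony(cfg, radius = s$radius, f0 = s$f0)
  } else {
    init_linear_front(cfg, f0 = s$f0, mode = s$mode)
  }
  run <- run_expansion(st, strains[[1]], strains[[2]],
                       max_steps = max_steps, record_every = record_every)
  run$scenario <- s
  run$seed <- seed
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_snapshot(run$state, file.path(out_dir, "snapshot"))
    write_run_metadata(run, file.path(out_dir, "run.json"))
    write.table(run$history, file.path(out_dir, "history.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  run
}

#' Scan a scenario over one parameter
#'
#' Repeats a scenario across a value grid and replicate seeds and
#' summarises each run's endpoint: final global fraction, site
#' heterozygosity, extinction flags, and the steady-state check of
#' [steady_state()].
#'
#' @param scenario name or `chirex_scenario`.
#' @param param scenario field to vary (e.g. `"dg"`, `"f_star"`, `"N"`,
#'   `"chi"`, `"f0"`).
#' @param values numeric grid.
#' @param replicates runs per value (`>= 1`).
#' @param seed base seed; each run's seed is derived from the base seed,
#'   the replicate index and the parameter value (not its position), so
#'   scan summaries are invariant under permutation of the value grid.
#' @param overrides additional fixed overrides applied to every run.
#' @param ... passed on to [run_scenario()].
#' @return Data frame with one row per (value, replicate).
#' @export
scan_scenario <- function(scenario, param, values, replicates = 1,
                          seed = 1, overrides = list(), ...) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.numeric(values) || !length(values))
    stop("values must be a non-empty numeric grid")
  rows <- list()
  for (vi in seq_along(values)) {
    for (r in seq_len(replicates)) {
      ov <- modifyList(overrides, stats::setNames(list(values[vi]), param))
      run_seed <- (seed + 1009L * r +
                     abs(round(values[vi] * 1e4))) %% 2147483647L
      run <- run_scenario(scenario, seed = run_seed,
                          overrides = ov, ...)
      ss <- steady_state(run$history)
      n <- nrow(run$history)
      rows[[length(rows) + 1]] <- data.frame(
        value = values[vi], replicate = r,
        fbar = run$history$fbar[n],
        fbar_tail = ss$fbar_end,
        H_site = run$history$H_site[n],
        extinct1 = run$history$fbar[n] <= 0,
        extinct2 = run$history$fbar[n] >= 1,
        converged = ss$converged,
        t_end = run$history$t[n],
        stop = run$stop_reason)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- param
  out
}

#' Deterministic test fixtures
#'
#' Small, self-describing inputs used by the test-suite and handy for
#' experimentation:
#' * `tiny_lattice` — a random occupancy state (default 10 x 10) with
#'   `n1 + n2 <= N` everywhere;
#' * `step_front` — sharp-step front fields (see [step_front_fields()]);
#' * `spiral_track` — an exact Bernoulli spiral `(r, theta)` track;
#' * `triangle_bulge` — an exact triangular bulge profile.
#'
#' @param kind fixture type.
#' @param seed RNG seed (fixtures are deterministic given the seed).
#' @param width,height,N lattice fixture dimensions.
#' @param nx grid points for `step_front`.
#' @param c0,c1,r_range spiral parameters.
#' @param params a [theory_params()] for `triangle_bulge`.
#' @param t bulge age.
#' @return The fixture object.
#' @export
make_fixture <- function(kind = c("tiny_lattice", "step_front",
                                  "spiral_track", "triangle_bulge"),
                         seed = 1, width = 10, height = 10, N = 30,
                         nx = 256, c0 = 0, c1 = 0.3, r_range = c(10, 100),
                         params = NULL, t = 1000) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    tiny_lattice = {
      cfg <- lattice_config(width, height, N)
      tot <- matrix(sample(0:N, width * height, replace = TRUE),
                    width, height)
      n1 <- matrix(rbinom(width * height, tot, 0.5), width, height)
      new_lattice_state(n1, tot - n1, cfg, ylo = 1L, yhi = height)
    },
    step_front = step_front_fields(nx),
    spiral_track = {
      r <- seq(r_range[1], r_range[2], length.out = 200)
      data.frame(r = r, theta = c0 + c1 * log(r))
    },
    triangle_bulge = {
      if (is.null(params))
        params <- theory_params(v0 = 0.4, Dh = 1, alpha = 0.08, Df = 1,
                                beta = 0.08)
      x <- seq(-nx / 2, nx / 2)
      list(x = x, h = bulge_profile(x, t, params, x_b = 0),
           params = params, t = t)
    })
}
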
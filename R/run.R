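#' Run a range expansion and record front observables
#'
#' Advances the lattice in chunks of `record_every` steps, recording at
#' each checkpoint the mean front height, the spatially averaged strain-1
#' fraction, the front heterozygosity (column band), and the per-site
#' heterozygosity of the active region.  A linear run stops when the
#' front approaches the top of the lattice or after `max_steps`; a radial
#' run additionally stops when the colony nears the lattice edge.
#'
#' @param state a `lattice_state` from [init_linear_front()] or
#'   [init_circular_colony()].
#' @param params1,params2 [strain_params()] of the two strains.
#' @param max_steps hard cap on time steps.
#' @param record_every checkpoint cadence in steps.
#' @param band_depth band for [front_profile()].
#' @param edge_margin (radial only) stop when cells get this close to the
#'   lattice boundary.
#' @return An object of class `chirex_run`: list with the final `state`,
#'   a `history` data frame (`t`, `front`, `fbar`, `H`, `H_site`),
#'   `stop_reason` (`"hit_top"`, `"max_steps"`, `"edge"`), and
#'   `clamp_events`.
#' @examples
#' \donttest{
#' set.seed(1)
#' cfg <- lattice_config(100, 300, N = 100)
#' st <- init_linear_front(cfg, f0 = 0.5)
#' left <- strain_params(g = 0.1, ml = 0.09, mr = 0.01)
#' right <- strain_params(g = 0.1, ml = 0.01, mr = 0.09)
#' run <- run_expansion(st, left, right, max_steps = 2000)
#' run$history[nrow(run$history), ]
#' }
#' @export
run_expansion <- function(state, params1, params2, max_steps = 50000,
                          record_every = 200, band_depth = 10,
                          edge_margin = 5) {
  linear <- identical(state$geometry, "linear")
  hist <- list()
  clamp <- 0
  stop_reason <- "max_steps"
  steps_left <- max_steps
  record <- function(st) {
    pr <- front_profile(st, band_depth)
    list(t = st$t, front = mean(pr$h, na.rm = TRUE),
         fbar = global_fraction(pr), H = heterozygosity(pr),
         H_site = site_heterozygosity(st))
  }
  hist[[1]] <- record(state)
  while (steps_left > 0) {
    chunk <- min(record_every, steps_left)
    state <- lattice_step(state, params1, params2, steps = chunk)
    clamp <- clamp + attr(state, "clamp_events")
    steps_left <- steps_left - chunk
    hist[[length(hist) + 1]] <- record(state)
    if (isTRUE(attr(state, "hit_top"))) { stop_reason <- "hit_top"; break }
    if (!linear) {
      nt <- state$n1 + state$n2
      W <- state$config$width; H <- state$config$height
      m <- edge_margin
      if (any(nt[c(seq_len(m), W - seq_len(m) + 1), ] > 0) ||
          any(nt[, c(seq_len(m), H - seq_len(m) + 1)] > 0)) {
        stop_reason <- "edge"; break
      }
    }
  }
  history <- do.call(rbind, lapply(hist, as.data.frame))
  if (clamp > 0)
    warning(clamp, " clamping events during the run: the deterministic ",
            "update left [0, N] — parameters are out of regime")
  structure(list(state = state, history = history,
                 stop_reason = stop_reason, clamp_events = clamp,
                 params1 = params1, params2 = params2),
            class = "chirex_run")
}

#' @export
print.chirex_run <- function(x, ...) {
  n <- nrow(x$history)
  cat("<chirex_run> ", x$state$config$width, "x", x$state$config$height,
      " lattice, N = ", x$state$config$N, "\n", sep = "")
  cat("  steps:", x$state$t, " stop:", x$stop_reason, "\n")
  cat("  final f-bar:", signif(x$history$fbar[n], 4),
      "  front H:", signif(x$history$H[n], 4),
      "  site H:", signif(x$history$H_site[n], 4), "\n")
  invisible(x)
}

#' @export
plot.chirex_run <- function(x, what = c("pattern", "history"), ...) {
  what <- match.arg(what)
  if (what == "pattern") {
    plot(x$state, ...)
  } else {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::plot(x$history$t, x$history$fbar, type = "l", ylim = c(0, 1),
                   xlab = "t", ylab = "f-bar", ...)
    graphics::abline(h = 0.5, lty = 3)
    graphics::plot(x$history$t, x$history$H_site, type = "l",
                   xlab = "t", ylab = "site heterozygosity")
  }
  invisible(x)
}

#' Steady-state check on a fraction trajectory
#'
#' Declares a trajectory converged when the least-squares slope of
#' `fbar` over the trailing `tail_frac` of the samples is below `tol`
#' per step, and the run is at least `min_samples` checkpoints long.
#'
#' @param history a `chirex_run` history data frame.
#' @param tail_frac trailing fraction of samples used.
#' @param tol slope tolerance (per time step).
#' @param min_samples minimum number of checkpoints.
#' @return List with `converged`, `slope`, `fbar_end` (mean of the
#'   trailing window).
#' @export
steady_state <- function(history, tail_frac = 0.2, tol = 1e-5,
                         min_samples = 10) {
  n <- nrow(history)
  if (n < min_samples)
    return(list(converged = FALSE, slope = NA_real_,
                fbar_end = history$fbar[n]))
  k <- max(3, ceiling(tail_frac * n))
  tailh <- history[seq(n - k + 1, n), ]
  fit <- lm(fbar ~ t, data = tailh)
  slope <- unname(coef(fit)[2])
  list(converged = is.finite(slope) && abs(slope) < tol,
       slope = slope, fbar_end = mean(tailh$fbar))
}
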
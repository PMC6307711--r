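# Measurements extracted from lattice states: front profiles, global
# fraction, heterozygosity, expansion velocity, sector boundaries (linear
# and radial), spiral fits, boundary width, bulge-slope fits.

#' Front height and strain fraction per column
#'
#' The front height `h(x)` of a column is the largest row where the total
#' occupancy reaches half the carrying capacity, linearly interpolated
#' between the bracketing rows (a flat saturated front at row `k` gives
#' `h = k + 1/2`).  The strain fraction `f(x)` is the strain-1 share of
#' all cells in a band of `band_depth` rows behind the front — the
#' region the effective front variables describe.  Columns with no
#' occupied band are returned as `NA` and flagged.
#'
#' @param state a `lattice_state`.
#' @param band_depth rows behind the front over which `f` is averaged.
#' @return An object of class `front_profile`: list with `x`, `h`, `f`,
#'   `empty` (logical flag per column), `t`, `band_depth`, `N`.
#' @export
front_profile <- function(state, band_depth = 10) {
  cfg <- state$config
  W <- cfg$width; H <- cfg$height; N <- cfg$N
  nt <- state$n1 + state$n2
  half <- N / 2
  h <- rep(NA_real_, W)
  f <- rep(NA_real_, W)
  for (x in seq_len(W)) {
    rows <- which(nt[x, ] >= half)
    if (!length(rows)) next
    k <- max(rows)
    v1 <- nt[x, k]
    v2 <- if (k < H) nt[x, k + 1] else 0
    h[x] <- k + (v1 - half) / (v1 - v2)
    lo <- max(1L, k - band_depth + 1L)
    s1 <- sum(state$n1[x, lo:k])
    st <- s1 + sum(state$n2[x, lo:k])
    if (st > 0) f[x] <- s1 / st
  }
  structure(list(x = seq_len(W), h = h, f = f,
                 empty = is.na(h) | is.na(f),
                 t = state$t, band_depth = band_depth, N = N),
            class = "front_profile")
}

#' @export
print.front_profile <- function(x, ...) {
  cat("<front_profile> t =", x$t, " columns:", length(x$x),
      " (", sum(x$empty), "empty )\n")
  cat("  mean h:", signif(mean(x$h, na.rm = TRUE), 5),
      "  f-bar:", signif(global_fraction(x), 4),
      "  H:", signif(heterozygosity(x), 4), "\n")
  invisible(x)
}

#' @export
plot.front_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$x, x$h, type = "l", xlab = "x", ylab = "front height h(x)", ...)
  graphics::plot(x$x, x$f, type = "l", ylim = c(0, 1), xlab = "x",
                 ylab = "strain-1 fraction f(x)")
  invisible(x)
}

#' Spatially averaged strain-1 fraction
#' @param profile a [front_profile()].
#' @return Mean of `f(x)` over valid columns, in `[0, 1]`.
#' @export
global_fraction <- function(profile) {
  mean(profile$f, na.rm = TRUE)
}

#' Front heterozygosity
#'
#' `H = <2 f (1 - f)>` over valid columns: zero when every column is
#' monomorphic, `1/2` at perfect 50:50 mixing.  Measures local strain
#' intermixing at the front.
#'
#' @param profile a [front_profile()].
#' @return `H` in `[0, 1/2]`.
#' @export
heterozygosity <- function(profile) {
  mean(2 * profile$f * (1 - profile$f), na.rm = TRUE)
}

#' Per-site heterozygosity of a lattice region
#'
#' The mean over occupied sites of `2 f (1 - f)` with `f = n1/(n1 + n2)`
#' site by site, computed within a row window (defaults to the active
#' window).  This is the intermixing measure used for the
#' segregation/intermixing phase diagram: it vanishes when every site is
#' monomorphic no matter how finely sectors interleave.
#'
#' @param state a `lattice_state`.
#' @param rows row interval `c(lo, hi)`; default the active window.
#' @return Mean per-site heterozygosity in `[0, 1/2]`.
#' @export
site_heterozygosity <- function(state, rows = NULL) {
  if (is.null(rows)) rows <- c(state$ylo, state$yhi)
  jj <- seq(max(1, rows[1]), min(state$config$height, rows[2]))
  n1 <- state$n1[, jj, drop = FALSE]
  nt <- n1 + state$n2[, jj, drop = FALSE]
  occ <- nt > 0
  if (!any(occ)) return(NA_real_)
  fr <- n1[occ] / nt[occ]
  mean(2 * fr * (1 - fr))
}

#' Expansion velocity from a front-height time series
#'
#' Least-squares slope of mean front height against time after discarding
#' an initial transient.
#'
#' @param t,h time points and mean front heights.
#' @param fit_window optional `c(t_min, t_max)` to restrict the fit.
#' @param discard_frac fraction of the earliest samples dropped as
#'   transient when `fit_window` is not given.
#' @return A list with `v0`, `se`, and the underlying `fit`.
#' @export
expansion_velocity <- function(t, h, fit_window = NULL, discard_frac = 0.2) {
  keep <- if (is.null(fit_window)) {
    t >= stats::quantile(t, discard_frac)
  } else {
    t >= fit_window[1] & t <= fit_window[2]
  }
  if (sum(keep) < 3) stop("too few samples in the fit window")
  fit <- lm(h[keep] ~ t[keep])
  list(v0 = unname(coef(fit)[2]),
       se = unname(summary(fit)$coefficients[2, 2]),
       fit = fit)
}

# circular moving average of width k (k odd)
smooth_circular <- function(v, k) {
  if (k <= 1) return(v)
  half <- (k - 1) %/% 2
  n <- length(v)
  ext <- c(tail(v, half), v, head(v, half))
  as.numeric(stats::filter(ext, rep(1 / k, k), sides = 2))[half + seq_len(n)]
}

#' Sector boundaries along a front profile
#'
#' Boundary positions are the `f = 1/2` crossings of the smoothed
#' fraction profile (sub-column linear interpolation, periodic in x).
#' Each is labelled by the local strain arrangement: with strain 1 the
#' more left-handed strain, a rising crossing (strain 1 to the right) is
#' an in-flow boundary — the chiral biases point towards each other — and
#' a falling crossing is out-flow.  Under periodic x the two types
#' alternate, so their counts are equal.
#'
#' @param profile a [front_profile()].
#' @param chi1,chi2 chiralities of strains 1 and 2 (scalars or
#'   [strain_params()]); used only for the labels.
#' @param smooth_k width (columns) of the circular moving average applied
#'   before crossing detection.
#' @return A data frame with columns `x` and `type`
#'   (`"in_flow"`/`"out_flow"`); zero rows when `f` never crosses 1/2.
#' @export
extract_boundaries <- function(profile, chi1, chi2, smooth_k = 5) {
  if (inherits(chi1, "strain_params")) chi1 <- chirality(chi1)
  if (inherits(chi2, "strain_params")) chi2 <- chirality(chi2)
  f <- profile$f
  f[is.na(f)] <- 0.5    # empty columns are uninformative
  fs <- smooth_circular(f, smooth_k)
  n <- length(fs)
  s <- fs - 0.5
  nxt <- c(seq_len(n)[-1], 1L)
  cross <- which(s * s[nxt] < 0 | (s == 0 & s[nxt] != 0))
  if (!length(cross))
    return(data.frame(x = numeric(0), type = character(0)))
  xs <- numeric(length(cross)); rising <- logical(length(cross))
  for (k in seq_along(cross)) {
    i <- cross[k]; j <- nxt[i]
    frac <- if (s[i] == s[j]) 0.5 else s[i] / (s[i] - s[j])
    xs[k] <- profile$x[i] + frac        # may wrap past n
    rising[k] <- s[j] > s[i]
  }
  xs[xs > n] <- xs[xs > n] - n
  in_flow_is_rising <- chi1 > chi2
  type <- ifelse(rising == in_flow_is_rising, "in_flow", "out_flow")
  data.frame(x = xs, type = type, stringsAsFactors = FALSE)
}

#' Track sector boundaries through time
#'
#' Matches boundary positions of consecutive snapshots by nearest
#' neighbour (periodic in x, same type only) and accumulates unwrapped
#' trajectories.  Boundaries that fail to match within `match_radius`
#' terminate their track (sector extinction) or start a new one (birth).
#'
#' @param boundaries list of data frames from [extract_boundaries()].
#' @param times time stamps, one per snapshot.
#' @param width lattice width (for periodic wrapping).
#' @param match_radius maximum per-step displacement.
#' @return A list of tracks, each a data frame `t`, `x` (unwrapped),
#'   `type`; class `boundary_tracks`.
#' @export
track_boundaries <- function(boundaries, times, width, match_radius = 10) {
  stopifnot(length(boundaries) == length(times))
  open <- list()   # each: list(t=, x=, xw= wrapped last pos, type=)
  closed <- list()
  for (k in seq_along(boundaries)) {
    b <- boundaries[[k]]
    used <- rep(FALSE, nrow(b))
    still <- logical(length(open))
    for (o in seq_along(open)) {
      tr <- open[[o]]
      cand <- which(!used & b$type == tr$type)
      if (length(cand)) {
        d <- b$x[cand] - tr$xw
        d <- d - width * round(d / width)
        best <- which.min(abs(d))
        if (abs(d[best]) <= match_radius) {
          i <- cand[best]
          used[i] <- TRUE
          tr$t <- c(tr$t, times[k])
          tr$x <- c(tr$x, tail(tr$x, 1) + d[best])
          tr$xw <- b$x[i]
          open[[o]] <- tr
          still[o] <- TRUE
        }
      }
    }
    closed <- c(closed, open[!still])
    open <- open[still]
    for (i in which(!used)) {
      open <- c(open, list(list(t = times[k], x = b$x[i], xw = b$x[i],
                                type = b$type[i])))
    }
  }
  closed <- c(closed, open)
  tracks <- lapply(closed, function(tr)
    data.frame(t = tr$t, x = tr$x, type = tr$type, stringsAsFactors = FALSE))
  structure(tracks, class = "boundary_tracks")
}

#' Drift velocity of a boundary track
#' @param track one element of a [track_boundaries()] result.
#' @return List with `v` (slope of x vs t), `se`, `fit`.
#' @export
boundary_track_velocity <- function(track) {
  if (nrow(track) < 3) stop("track too short for a velocity fit")
  fit <- lm(x ~ t, data = track)
  list(v = unname(coef(fit)[2]),
       se = unname(summary(fit)$coefficients[2, 2]), fit = fit)
}

#' Logarithmic-spiral fit to a boundary track
#'
#' Sector boundaries of a radially growing chiral colony are Bernoulli
#' (logarithmic) spirals: the polar angle grows linearly with `ln r`.
#' This fits `theta = c0 + c1 ln(r)` by least squares; `c1 > 0` means a
#' counterclockwise twist (left-handed strains in this package's
#' convention).  Accepts any generic `(r, theta)` track, e.g. digitised
#' experimental boundaries.
#'
#' @param r radii (positive, same length as `theta`).
#' @param theta continuity-unwrapped polar angles (radians).
#' @return Object of class `spiral_fit` with `c0`, `c1`, `r_squared`,
#'   `se`, `n`, and the `lm` fit.
#' @export
spiral_fit <- function(r, theta) {
  stopifnot(length(r) == length(theta), all(r > 0))
  fit <- lm(theta ~ log(r))
  co <- coef(fit)
  structure(list(c0 = unname(co[1]), c1 = unname(co[2]),
                 r_squared = summary(fit)$r.squared,
                 se = unname(summary(fit)$coefficients[2, 2]),
                 n = length(r), fit = fit),
            class = "spiral_fit")
}

#' @export
print.spiral_fit <- function(x, ...) {
  cat("<spiral_fit> theta = c0 + c1 ln r\n")
  cat("  c1 =", signif(x$c1, 4), "+/-", signif(x$se, 3),
      "  c0 =", signif(x$c0, 4), "  R^2 =", signif(x$r_squared, 4),
      "  n =", x$n, "\n")
  invisible(x)
}

#' @export
coef.spiral_fit <- function(object, ...) c(c0 = object$c0, c1 = object$c1)

#' Sector-boundary angles of a radial colony and their spiral fit
#'
#' Walks outward through the frozen pattern of a circular colony in
#' radial steps of one site, locates the strain boundaries on each ring
#' (crossings of the angularly smoothed site fraction through 1/2),
#' matches them ring-to-ring by angular continuity, keeps the boundaries
#' that survive the whole fitted radius range, subtracts each boundary's
#' initial angle, and averages.  The averaged `theta(r)` is then fitted
#' as a logarithmic spiral with [spiral_fit()].
#'
#' @param state a `lattice_state` from a radial run (or several via
#'   `more_states` to pool boundaries across replicates).
#' @param center colony centre; defaults to the one stored by
#'   [init_circular_colony()].
#' @param r_range radius interval to analyse; defaults to from just
#'   outside the inoculum to just inside the final colony radius.
#' @param smooth_k angular smoothing window (ring cells).
#' @param min_boundaries refuse to fit with fewer surviving boundaries.
#' @param more_states optional list of further states whose boundaries
#'   are pooled before averaging.
#' @return A `spiral_fit` object with extra fields `theta_mean` (averaged
#'   relative angle per radius), `r`, and `n_boundaries`.
#' @export
radial_boundary_angles <- function(state, center = NULL, r_range = NULL,
                                   smooth_k = 5, min_boundaries = 2,
                                   more_states = NULL) {
  states <- c(list(state), if (is.null(more_states)) list() else more_states)
  all_tracks <- list()
  for (st in states) {
    ctr <- if (is.null(center)) st$center else center
    if (is.null(ctr)) stop("no colony centre available")
    rr <- r_range
    if (is.null(rr)) {
      nt <- st$n1 + st$n2
      occ <- which(nt > 0, arr.ind = TRUE)
      rad <- sqrt((occ[, 1] - ctr[1])^2 + (occ[, 2] - ctr[2])^2)
      r0 <- if (!is.null(st$radius0)) st$radius0 + 5 else 10
      # stay inside the fully occupied disk
      rmax <- floor(stats::quantile(rad, 0.995)) - 5
      rr <- c(r0, rmax)
    }
    if (rr[2] - rr[1] < 10) stop("radius range too narrow for a spiral fit")
    all_tracks <- c(all_tracks, ring_boundary_tracks(st, ctr, rr, smooth_k))
  }
  # fitted range: from the inner radius out to the largest radius still
  # covered by at least min_boundaries tracks (sectors go extinct by
  # coarsening, so few boundaries span the whole colony)
  r_lo <- min(sapply(all_tracks, function(tr) min(tr$r)))
  from_start <- Filter(function(tr) min(tr$r) <= r_lo + 1, all_tracks)
  if (length(from_start) < min_boundaries)
    stop("only ", length(from_start), " boundaries near the inner radius (",
         min_boundaries, " required); fit refused")
  r_his <- sort(sapply(from_start, function(tr) max(tr$r)),
                decreasing = TRUE)
  r_hi <- r_his[min_boundaries]
  if (r_hi - r_lo < 10)
    stop("fewer than ", min_boundaries, " boundaries survive a usable ",
         "radius range; fit refused")
  radii <- seq(ceiling(r_lo), floor(r_hi))
  full <- Filter(function(tr) min(tr$r) <= radii[1] &&
                   max(tr$r) >= tail(radii, 1), from_start)
  rel <- sapply(full, function(tr) {
    th <- tr$theta[match(radii, tr$r)]
    th - th[1]
  })
  theta_mean <- rowMeans(rel)
  out <- spiral_fit(radii, theta_mean)
  out$theta_mean <- theta_mean
  out$r <- radii
  out$n_boundaries <- length(full)
  out
}

# boundary tracks (r, theta) through the frozen pattern of one colony
ring_boundary_tracks <- function(state, center, r_range, smooth_k) {
  n1 <- state$n1; nt <- n1 + state$n2
  W <- nrow(nt); H <- ncol(nt)
  xs <- matrix(seq_len(W), W, H) - center[1]
  ys <- matrix(seq_len(H), W, H, byrow = TRUE) - center[2]
  rad <- sqrt(xs^2 + ys^2)
  ang <- atan2(ys, xs)
  rings <- seq(r_range[1], r_range[2])
  bucket <- round(rad)
  tracks <- list()
  for (r in rings) {
    sel <- which(bucket == r & nt > 0)
    if (length(sel) < 8) next
    o <- order(ang[sel])
    th <- ang[sel][o]
    fr <- (n1[sel] / nt[sel])[o]
    fs <- smooth_circular(fr, smooth_k)
    s <- fs - 0.5
    m <- length(s)
    nxt <- c(seq_len(m)[-1], 1L)
    cross <- which(s * s[nxt] < 0)
    if (!length(cross)) next
    bth <- numeric(length(cross))
    for (k in seq_along(cross)) {
      i <- cross[k]; j <- nxt[i]
      dth <- th[j] - th[i]
      if (dth < 0) dth <- dth + 2 * pi
      frac <- s[i] / (s[i] - s[j])
      bth[k] <- th[i] + frac * dth
    }
    bth <- ((bth + pi) %% (2 * pi)) - pi
    # continue existing tracks by angular proximity
    used <- rep(FALSE, length(bth))
    for (o2 in seq_along(tracks)) {
      tr <- tracks[[o2]]
      if (tail(tr$r, 1) != r - 1) next
      d <- bth - tail(tr$theta_w, 1)
      d <- d - 2 * pi * round(d / (2 * pi))
      best <- which.min(abs(d) + ifelse(used, 1e6, 0))
      if (length(best) && !used[best] &&
          abs(d[best]) <= (0.25 + 8 / r)) {
        used[best] <- TRUE
        tr$r <- c(tr$r, r)
        tr$theta <- c(tr$theta, tail(tr$theta, 1) + d[best])
        tr$theta_w <- c(tr$theta_w, bth[best])
        tracks[[o2]] <- tr
      }
    }
    for (i in which(!used))
      tracks <- c(tracks, list(list(r = r, theta = bth[i], theta_w = bth[i])))
  }
  lapply(tracks, function(tr) list(r = tr$r, theta = tr$theta))
}

#' Boundary width as summed local heterozygosity
#'
#' For each row in `y_window`, sums `2 f (1 - f)` with `f = n1/(n1 + n2)`
#' over all occupied sites of the row, then averages over the rows.  For
#' a deterministic sharp boundary this is of order one site; it grows
#' with the deme size `N` (weaker genetic drift) and is insensitive to a
#' common chirality of the two strains.
#'
#' @param state a `lattice_state`.
#' @param y_window row interval `c(lo, hi)` over which to average.
#' @return A list with `width` (the average) and `per_row`.
#' @export
boundary_width <- function(state, y_window) {
  jj <- seq(max(1, y_window[1]), min(state$config$height, y_window[2]))
  per_row <- vapply(jj, function(j) {
    n1 <- state$n1[, j]; nt <- n1 + state$n2[, j]
    occ <- nt > 0
    if (!any(occ)) return(NA_real_)
    fr <- n1[occ] / nt[occ]
    sum(2 * fr * (1 - fr))
  }, numeric(1))
  list(width = mean(per_row, na.rm = TRUE), per_row = per_row, rows = jj)
}

#' Fit the two slopes of a bulge
#'
#' Straight-line fits to the front height on each side of a boundary,
#' over a window that excludes the rounded apex.  For strains with equal
#' and opposite chirality the two slope magnitudes agree; for `f* != 1/2`
#' the steeper slope is on the side that leads the bulge's forward
#' motion.
#'
#' @param profile a [front_profile()] (or any list with `x` and `h`).
#' @param x_b boundary (apex) position.
#' @param window distances from `x_b` used on each side,
#'   `c(exclude, extent)`.
#' @return List with `slope_left`, `slope_right`, their `se`, and the
#'   fits.
#' @export
fit_bulge_slopes <- function(profile, x_b, window = c(3, 30)) {
  W <- length(profile$x)
  d <- profile$x - x_b
  d <- d - W * round(d / W)          # signed periodic distance
  side_fit <- function(sel) {
    if (sum(sel) < 3) stop("bulge-slope window holds fewer than 3 columns")
    fit <- lm(profile$h[sel] ~ d[sel])
    list(slope = unname(coef(fit)[2]),
         se = unname(summary(fit)$coefficients[2, 2]), fit = fit)
  }
  left <- side_fit(d <= -window[1] & d >= -window[2] & !is.na(profile$h))
  right <- side_fit(d >= window[1] & d <= window[2] & !is.na(profile$h))
  list(slope_left = left$slope, se_left = left$se,
       slope_right = right$slope, se_right = right$se,
       fit_left = left$fit, fit_right = right$fit)
}
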
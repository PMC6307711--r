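#' Lattice geometry and bookkeeping
#'
#' The habitat is a rectangular grid of `width` x `height` sites, periodic
#' in x.  Each site holds at most `N` cells.  The colony grows towards
#' larger y; only an active window of rows around the front is updated
#' each step (`window_behind` rows behind the deepest occupied row and
#' `window_ahead` rows ahead of it), the saturated bulk behind it stays
#' frozen, exactly as in a real colony where growth is confined to the
#' edge.
#'
#' @param width,height site counts (both `>= 3`).
#' @param N carrying capacity per site (cells), `>= 1`.
#' @param dx,dy,dt lattice spacings and time step (the model is normally
#'   run with all three equal to 1; they are carried symbolically).
#' @param window_behind,window_ahead active-window depth in rows.
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(width, height, N, dx = 1, dy = 1, dt = 1,
                           window_behind = 30, window_ahead = 30) {
  if (width < 3 || height < 3) stop("width and height must be >= 3")
  if (N < 1) stop("carrying capacity N must be >= 1")
  if (dx != dy) stop("dx and dy must be equal")
  structure(list(width = as.integer(width), height = as.integer(height),
                 N = as.integer(N), dx = dx, dy = dy, dt = dt,
                 window_behind = as.integer(window_behind),
                 window_ahead = as.integer(window_ahead)),
            class = "lattice_config")
}

new_lattice_state <- function(n1, n2, config, t = 0, ylo = 1L, yhi = NULL,
                              geometry = c("linear", "radial")) {
  geometry <- match.arg(geometry)
  if (is.null(yhi)) yhi <- config$height
  structure(list(n1 = n1, n2 = n2, t = t,
                 ylo = as.integer(ylo), yhi = as.integer(yhi),
                 geometry = geometry, config = config),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  nt <- x$n1 + x$n2
  occ <- which(colSums(nt) > 0)
  cat("<lattice_state> ", x$config$width, "x", x$config$height,
      " sites, N = ", x$config$N, ", t = ", x$t, "\n", sep = "")
  cat("  geometry:", x$geometry,
      " active window rows:", x$ylo, "-", x$yhi, "\n")
  if (length(occ)) {
    cat("  occupied rows:", min(occ), "-", max(occ),
        "  cells:", sum(nt),
        "  strain-1 fraction:", signif(sum(x$n1) / sum(nt), 4), "\n")
  } else cat("  empty lattice\n")
  invisible(x)
}

#' Plot the strain pattern of a lattice state
#'
#' Renders the occupancy fields with the usual two-colour convention:
#' strain 1 green, strain 2 red, mixtures blended, empty sites black.
#'
#' @param x a `lattice_state`.
#' @param ... passed to [graphics::rasterImage()]-backed plotting.
#' @export
plot.lattice_state <- function(x, ...) {
  img <- snapshot_raster(x)
  op <- graphics::par(mar = c(2, 2, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0, x$config$width), ylim = c(0, x$config$height),
                 xlab = "x", ylab = "y", asp = 1, ...)
  graphics::rasterImage(img, 0, 0, x$config$width, x$config$height,
                        interpolate = FALSE)
  invisible(x)
}

# RGB raster (height x width, top row first) from a state
snapshot_raster <- function(state) {
  N <- state$config$N
  g <- t(state$n1 / N)[state$config$height:1, , drop = FALSE]
  r <- t(state$n2 / N)[state$config$height:1, , drop = FALSE]
  arr <- array(0, c(nrow(g), ncol(g), 3))
  arr[, , 1] <- r
  arr[, , 2] <- g
  arr
}

#' Initialise a flat linear front
#'
#' Fills the bottom `filled_rows` rows to carrying capacity and splits
#' them between the strains:
#'
#' * `well_mixed` — at every occupied site the strain-1 count is a
#'   binomial draw with success probability `f0` (each site is a deme of
#'   `N` cells);
#' * `two_domains` — strain 1 occupies a contiguous x-interval of
#'   fractional width `f0`; under periodic x this creates exactly one
#'   boundary of each type (in-flow and out-flow);
#' * `single_patch` — a localized strain-1 interval of `patch_width`
#'   columns (a mutant/immigrant patch) inside strain 2.
#'
#' @param config a [lattice_config()].
#' @param f0 initial strain-1 fraction in `[0, 1]`.
#' @param mode initial arrangement, see above.
#' @param filled_rows number of occupied bottom rows.
#' @param patch_width,patch_center geometry of the `single_patch` mode
#'   (columns; centre defaults to the lattice middle).
#' @return A `lattice_state`.
#' @export
init_linear_front <- function(config, f0,
                              mode = c("well_mixed", "two_domains",
                                       "single_patch"),
                              filled_rows = 10, patch_width = NULL,
                              patch_center = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "lattice_config"))
  if (f0 < 0 || f0 > 1) stop("f0 must lie in [0, 1]")
  W <- config$width; H <- config$height; N <- config$N
  if (filled_rows < 1 || filled_rows + config$window_ahead >= H)
    stop("filled_rows leaves no room for the front to grow")
  n1 <- matrix(0L, W, H); n2 <- matrix(0L, W, H)
  rows <- seq_len(filled_rows)
  if (mode == "well_mixed") {
    draws <- matrix(rbinom(W * filled_rows, N, f0), W, filled_rows)
    n1[, rows] <- draws
    n2[, rows] <- N - draws
  } else if (mode == "two_domains") {
    k <- round(f0 * W)
    if (k > 0) n1[seq_len(k), rows] <- N
    if (k < W) n2[seq(k + 1, W), rows] <- N
  } else {
    pw <- if (is.null(patch_width)) max(1, round(f0 * W)) else patch_width
    if (pw > W) stop("patch_width exceeds the lattice width")
    ctr <- if (is.null(patch_center)) ceiling(W / 2) else patch_center
    idx <- ((ctr - ceiling(pw / 2) + seq_len(pw) - 1) %% W) + 1
    n2[, rows] <- N
    n1[idx, rows] <- N
    n2[idx, rows] <- 0L
  }
  ylo <- max(1L, filled_rows - config$window_behind)
  yhi <- min(H, filled_rows + config$window_ahead)
  new_lattice_state(n1, n2, config, t = 0, ylo = ylo, yhi = yhi,
                    geometry = "linear")
}

#' Initialise a circular colony
#'
#' Places a well-mixed disk of cells at carrying capacity in the middle of
#' the lattice, as in a radial expansion started from a droplet inoculum.
#'
#' @param config a [lattice_config()].
#' @param radius disk radius in sites; the disk (plus growing room) must
#'   fit the lattice.
#' @param f0 initial strain-1 fraction; per-site binomial splitting.
#' @param center disk centre `c(x, y)`; defaults to the lattice centre.
#' @return A `lattice_state` with radial geometry (the whole lattice is
#'   active; the saturated interior is frozen by the update rule itself).
#' @export
init_circular_colony <- function(config, radius, f0, center = NULL) {
  stopifnot(inherits(config, "lattice_config"))
  if (f0 < 0 || f0 > 1) stop("f0 must lie in [0, 1]")
  W <- config$width; H <- config$height; N <- config$N
  if (is.null(center)) center <- c((W + 1) / 2, (H + 1) / 2)
  if (radius < 1 ||
      center[1] - radius < 1 || center[1] + radius > W ||
      center[2] - radius < 1 || center[2] + radius > H)
    stop("circle does not fit the lattice")
  xs <- matrix(seq_len(W), W, H)
  ys <- matrix(seq_len(H), W, H, byrow = TRUE)
  inside <- (xs - center[1])^2 + (ys - center[2])^2 <= radius^2
  n1 <- matrix(0L, W, H); n2 <- matrix(0L, W, H)
  k <- sum(inside)
  draws <- rbinom(k, N, f0)
  n1[inside] <- draws
  n2[inside] <- N - draws
  st <- new_lattice_state(n1, n2, config, t = 0, ylo = 1L, yhi = H,
                          geometry = "radial")
  st$center <- center
  st$radius0 <- radius
  st
}
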
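# Snapshot and metadata output.  Snapshots are plain text: one TSV
# integer matrix per strain (x in rows, y in columns), so they diff and
# version cleanly; an optional PNG render uses the usual colour code
# (strain 1 green, strain 2 red, mixture blended, background black).

#' Write a lattice snapshot
#'
#' @param state a `lattice_state`.
#' @param prefix output path prefix; writes `<prefix>_n1.tsv`,
#'   `<prefix>_n2.tsv` and (if `png = TRUE` and the png package is
#'   available) `<prefix>.png`.
#' @param png also write the rendered raster.
#' @return The paths written, invisibly.
#' @export
write_snapshot <- function(state, prefix, png = FALSE) {
  p1 <- paste0(prefix, "_n1.tsv")
  p2 <- paste0(prefix, "_n2.tsv")
  write.table(state$n1, p1, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  write.table(state$n2, p2, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  paths <- c(p1, p2)
  if (png) {
    if (!requireNamespace("png", quietly = TRUE)) {
      warning("package 'png' not available; skipping raster output")
    } else {
      p3 <- paste0(prefix, ".png")
      png::writePNG(snapshot_raster(state), p3)
      paths <- c(paths, p3)
    }
  }
  invisible(paths)
}

#' Read a lattice snapshot written by [write_snapshot()]
#'
#' @param prefix the path prefix used when writing.
#' @param config a [lattice_config()] describing the lattice; if `NULL`
#'   a config with `N = max(n1 + n2)` is synthesised.
#' @param geometry `"linear"` or `"radial"`.
#' @return A `lattice_state`.
#' @export
read_snapshot <- function(prefix, config = NULL,
                          geometry = c("linear", "radial")) {
  geometry <- match.arg(geometry)
  n1 <- as.matrix(read.table(paste0(prefix, "_n1.tsv"), sep = "\t"))
  n2 <- as.matrix(read.table(paste0(prefix, "_n2.tsv"), sep = "\t"))
  dimnames(n1) <- NULL; dimnames(n2) <- NULL
  storage.mode(n1) <- "integer"; storage.mode(n2) <- "integer"
  if (is.null(config))
    config <- lattice_config(nrow(n1), ncol(n1), max(n1 + n2))
  new_lattice_state(n1, n2, config, ylo = 1L, yhi = ncol(n1),
                    geometry = geometry)
}

#' Write run metadata as JSON
#'
#' Records the full parameter set, seed, package version and stop reason
#' of a run so it can be reproduced exactly.
#'
#' @param run a `chirex_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(run, path) {
  meta <- list(
    package = "chirex",
    version = as.character(utils::packageVersion("chirex")),
    config = unclass(run$state$config),
    params1 = unclass(run$params1),
    params2 = unclass(run$params2),
    geometry = run$state$geometry,
    seed = run$seed,
    t_end = run$state$t,
    stop_reason = run$stop_reason,
    clamp_events = run$clamp_events,
    scenario = if (!is.null(run$scenario)) run$scenario$name else NULL
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
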
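#' Monte Carlo flux estimate at the detector disk
#'
#' Runs the particle-tracing estimator: photons are launched from the source,
#' their ultrasonic phase frozen per path, and they alternate between
#' non-linear ray tracing through the sculpted index field and volume events
#' (weight-based absorption, Henyey-Greenstein scattering). At every volume
#' event a next-event split is traced towards the detector disk and combined
#' with the phase-function continuation through the balance heuristic, so
#' the estimator remains unbiased while converging orders of magnitude
#' faster in optically thick media. Results are bit-reproducible for a given
#' (seed, n_photons): each photon owns a counter-based RNG substream, so the
#' estimate does not depend on scheduling.
#'
#' @param sc A [scene()].
#' @param n_photons Number of photon paths (> 0).
#' @param seed Integer seed for the counter-based substreams.
#' @param nee Use next-event estimation splits (default TRUE).
#' @param step_ds Leapfrog step (m); default is one twentieth of the
#'   ultrasonic wavelength.
#' @param kill_radius Lateral radius beyond which photons count as lost
#'   (default ten times the waveguide core radius).
#' @param max_events Maximum volume events per path; paths beyond it are
#'   terminated into a diagnostics bucket, never silently dropped.
#' @param order_max Highest scattering order tallied separately; higher
#'   orders accumulate in an overflow bin.
#' @param fresnel_mode Boundary handling: \code{"deterministic"} weighting
#'   (default) or \code{"stochastic"} branching.
#' @return A \code{flux_estimate}: total flux and standard error per detector
#'   radius, per-scattering-order decomposition (which sums exactly to the
#'   total), diagnostics buckets, and the run metadata.
#' @examples
#' sc <- scene(acoustic_profile(delta_n = 0, freq_hz = 1e6),
#'             medium_optics(0, length_m = 0.03),
#'             beam_source(100e-6, 100), detector_spec(100e-6))
#' estimate_flux(sc, n_photons = 1000, seed = 1)
#' @export
estimate_flux <- function(sc, n_photons, seed, nee = TRUE, step_ds = NULL,
                          kill_radius = NULL, max_events = 1e4,
                          order_max = 10,
                          fresnel_mode = c("deterministic", "stochastic")) {
  stopifnot(inherits(sc, "scene"), n_photons > 0)
  ctrl <- default_controls(sc, step_ds, kill_radius, max_events, order_max,
                           nee = nee, fresnel_mode = match.arg(fresnel_mode))
  t0 <- proc.time()[["elapsed"]]
  raw <- cpp_trace(scene_to_cpp(sc), as.integer(n_photons), as.numeric(seed),
                   ctrl)
  elapsed <- proc.time()[["elapsed"]] - t0
  build_flux_estimate(raw, sc, n_photons, seed, ctrl, elapsed)
}

build_flux_estimate <- function(raw, sc, n_photons, seed, ctrl, elapsed) {
  n <- n_photons
  radii <- sc$detector$radius_m
  # total = sum of per-photon contributions c_i; Var(total) ~ n * var(c)
  se_of <- function(s, sq) {
    v <- (sq - s^2 / n) * n / (n - 1)
    v[v < 0] <- 0
    sqrt(v)
  }
  total <- raw$sum_total
  se <- se_of(total, raw$sumsq_total)
  om <- ctrl$order_max
  ord_names <- c(as.character(0:om), paste0(">", om))
  by_order <- raw$sum_order
  by_order_se <- se_of(raw$sum_order, raw$sumsq_order)
  dimnames(by_order) <- dimnames(by_order_se) <-
    list(radius = signif(radii, 8), order = ord_names)
  structure(list(mean_flux = stats::setNames(total, signif(radii, 8)),
                 std_error = stats::setNames(se, signif(radii, 8)),
                 flux_by_order = by_order,
                 flux_by_order_se = by_order_se,
                 radii_m = radii,
                 buckets = raw$buckets,
                 launched = raw$launched,
                 n_photons = n,
                 seed = seed,
                 controls = ctrl,
                 elapsed_s = elapsed),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat("<flux_estimate>\n")
  for (i in seq_along(x$mean_flux))
    cat(sprintf("  r = %s um: flux %.6g +/- %.3g a.u.\n",
                format(1e6 * x$radii_m[i]), x$mean_flux[i], x$std_error[i]))
  cat(sprintf("  %d photons (seed %s), %.2f s; launched %g a.u.\n",
              x$n_photons, format(x$seed), x$elapsed_s, x$launched))
  ords <- x$flux_by_order[length(x$radii_m), ]
  nz <- ords[ords > 0]
  if (length(nz))
    cat("  by order (largest radius): ",
        paste(sprintf("N%s=%.3g", names(nz), nz), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Trace individual photon paths with full contribution records
#'
#' Runs the same estimator as [estimate_flux()] for a small number of photons
#' and returns every detector contribution (direct plane crossings and
#' next-event splits) with its scattering order, weight and landing point,
#' plus the diagnostics buckets. Intended for path-level inspection and
#' testing, not production estimates.
#'
#' @inheritParams estimate_flux
#' @return List with \code{contributions} (data frame: photon, type
#'   \code{"direct"}/\code{"nee"}, order, weight, landing x/y) and
#'   \code{buckets}.
#' @export
trace_photon <- function(sc, n_photons = 1, seed = 1, nee = TRUE,
                         step_ds = NULL, kill_radius = NULL,
                         max_events = 1e4, order_max = 10) {
  stopifnot(inherits(sc, "scene"))
  ctrl <- default_controls(sc, step_ds, kill_radius, max_events, order_max)
  ctrl$nee <- isTRUE(nee)
  ctrl$record <- TRUE
  raw <- cpp_trace(scene_to_cpp(sc), as.integer(n_photons), as.numeric(seed),
                   ctrl)
  contribs <- as.data.frame(raw$records)
  if (nrow(contribs))
    contribs$type <- c("direct", "nee")[contribs$type + 1]
  list(contributions = contribs, buckets = raw$buckets,
       launched = raw$launched)
}

#' Render the irradiance image at the target plane
#'
#' Tallies every detector-plane crossing onto a regular grid and converts to
#' irradiance (a.u./m^2). The pixel sum times the pixel area equals the
#' plane-crossing flux tally. Optionally restricted to paths of a single
#' scattering order, which is how per-order confinement is visualized.
#'
#' @inheritParams estimate_flux
#' @param grid List \code{list(nx, ny, pitch_m)}; defaults to the scene
#'   detector's image spec, else 101 x 101 pixels spanning four core radii.
#' @param order \code{NULL} for all orders, or a single scattering order N.
#' @return Matrix of class \code{irradiance_image} (a.u./m^2) with attributes
#'   \code{pitch_m}, \code{extent_m}, \code{flux_estimate}.
#' @export
render_irradiance <- function(sc, n_photons, seed, grid = NULL, order = NULL,
                              nee = TRUE, step_ds = NULL, kill_radius = NULL,
                              max_events = 1e4, order_max = 10) {
  stopifnot(inherits(sc, "scene"))
  if (is.null(grid)) grid <- sc$detector$image
  if (is.null(grid)) {
    half <- 4 * first_zero_radius(sc$profile)
    grid <- list(nx = 101L, ny = 101L, pitch_m = 2 * half / 101)
  }
  ctrl <- default_controls(sc, step_ds, kill_radius, max_events, order_max)
  ctrl$nee <- isTRUE(nee)
  ctrl$image <- TRUE
  ctrl$nx <- as.integer(grid$nx)
  ctrl$ny <- as.integer(grid$ny)
  ctrl$pitch <- grid$pitch_m
  ctrl$image_order <- if (is.null(order)) -1L else as.integer(order)
  t0 <- proc.time()[["elapsed"]]
  raw <- cpp_trace(scene_to_cpp(sc), as.integer(n_photons), as.numeric(seed),
                   ctrl)
  elapsed <- proc.time()[["elapsed"]] - t0
  px_area <- grid$pitch_m^2
  img <- raw$image / px_area
  structure(img,
            class = c("irradiance_image", "matrix"),
            pitch_m = grid$pitch_m,
            extent_m = c(grid$nx, grid$ny) * grid$pitch_m,
            order = if (is.null(order)) NA_integer_ else as.integer(order),
            flux_estimate = build_flux_estimate(raw, sc, n_photons, seed,
                                                ctrl, elapsed))
}

#' @export
print.irradiance_image <- function(x, ...) {
  cat(sprintf("<irradiance_image> %d x %d px, pitch %g um, peak %.4g a.u./m^2\n",
              nrow(x), ncol(x), 1e6 * attr(x, "pitch_m"), max(x)))
  invisible(x)
}

#' Write an irradiance image as a flat binary matrix with a text sidecar
#'
#' The matrix is stored as little-endian doubles in column-major order; the
#' sidecar \code{<path>.meta} records grid dimensions, pitch, extent, units
#' and the run seed, so the image is self-describing.
#'
#' @param image An \code{irradiance_image}.
#' @param path Output path for the binary matrix.
#' @export
write_irradiance <- function(image, path) {
  stopifnot(inherits(image, "irradiance_image"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(unclass(image)), con, size = 8, endian = "little")
  fe <- attr(image, "flux_estimate")
  meta <- c(
    sprintf("nx = %d", nrow(image)),
    sprintf("ny = %d", ncol(image)),
    sprintf("pitch_m = %.12g", attr(image, "pitch_m")),
    sprintf("extent_m = %.12g %.12g", attr(image, "extent_m")[1],
            attr(image, "extent_m")[2]),
    "units = a.u. per m^2",
    "storage = float64 little-endian column-major",
    sprintf("order = %s", attr(image, "order")),
    sprintf("seed = %s", format(fe$seed)),
    sprintf("n_photons = %d", fe$n_photons))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
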
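#' Light source specifications
#'
#' \code{beam_source} describes a collimated beam of the given diameter
#' entering the slab along +z at normal incidence (uniform intensity across
#' the disk). \code{lens_source} describes an ideal external thin lens:
#' aberration-free and non-absorptive, all rays aimed at the on-axis focus at
#' \code{focus_depth_m} inside the medium.
#'
#' @param diameter_m Beam/aperture diameter in meters.
#' @param flux_au Total source flux in arbitrary units (default 7.5e4).
#' @param focus_depth_m Focus depth of the lens in meters.
#' @return A source specification list.
#' @export
beam_source <- function(diameter_m = 500e-6, flux_au = 7.5e4) {
  stopifnot(diameter_m > 0, flux_au > 0)
  list(type = "collimated", diameter_m = diameter_m, flux_au = flux_au,
       focus_depth_m = 0)
}

#' @rdname beam_source
#' @export
lens_source <- function(focus_depth_m, diameter_m = 500e-6, flux_au = 7.5e4) {
  stopifnot(focus_depth_m > 0, diameter_m > 0, flux_au > 0)
  list(type = "lens", diameter_m = diameter_m, flux_au = flux_au,
       focus_depth_m = focus_depth_m)
}

#' Detector specification
#'
#' A disk detector (closed: r <= radius) on the target plane, by default the
#' slab exit face z = L. Several concentric radii may be tallied in a single
#' run; the largest one drives the next-event proposal cone. An optional
#' image grid collects irradiance at the same plane.
#'
#' @param radius_m Disk radius (m), scalar or ascending vector.
#' @param depth_m Target plane depth; \code{NULL} (default) means the exit
#'   face.
#' @param image \code{NULL} or a list \code{list(nx, ny, pitch_m)} describing
#'   the irradiance grid (centered on the axis).
#' @export
detector_spec <- function(radius_m, depth_m = NULL, image = NULL) {
  radius_m <- sort(as.numeric(radius_m))
  stopifnot(length(radius_m) >= 1L, all(radius_m > 0))
  if (!is.null(image))
    stopifnot(is.list(image), all(c("nx", "ny", "pitch_m") %in% names(image)))
  list(radius_m = radius_m, depth_m = depth_m, image = image)
}

#' Temporal handling of the ultrasonic phase
#'
#' The ultrasonic period (~1 us) is many orders of magnitude slower than
#' light transit, so each path sees a frozen refractive index; the temporal
#' average is taken over paths. Modes: \code{"uniform"} samples the phase
#' time uniformly over one period (default); \code{"fixed"} freezes it at
#' \code{t_fixed_s}; \code{"duty"} samples uniformly inside a window of
#' \code{duty_fraction} of the period centered (by default) at peak
#' modulation \code{t = 1/(4 f)}, mirroring a laser gated in sync with the
#' ultrasound; \code{"peak"} freezes it at peak modulation \code{t = 1/(4 f)}
#' for every path, the quasi-static limit of the gated mode and the regime in
#' which the focal condition is defined (frequency-amplitude maps use it).
#'
#' @param mode One of \code{"uniform"}, \code{"fixed"}, \code{"duty"},
#'   \code{"peak"}.
#' @param t_fixed_s Frozen phase time for \code{"fixed"} (s).
#' @param duty_fraction Window width as a fraction of the period.
#' @param duty_center_t Window center (s); \code{NULL} = peak modulation.
#' @export
time_spec <- function(mode = c("uniform", "fixed", "duty", "peak"),
                      t_fixed_s = 0,
                      duty_fraction = 0.1, duty_center_t = NULL) {
  mode <- match.arg(mode)
  stopifnot(duty_fraction > 0, duty_fraction <= 1)
  list(mode = mode, t_fixed_s = t_fixed_s, duty_fraction = duty_fraction,
       duty_center_t = duty_center_t)
}

#' Assemble a simulation scene
#'
#' Combines the sculpted index profile, the optical properties of the slab,
#' the light source, the detector and the temporal mode into one validated
#' object consumed by [estimate_flux()], [trace_photon()] and
#' [render_irradiance()].
#'
#' @param profile [acoustic_profile()].
#' @param optics [medium_optics()].
#' @param source [beam_source()] or [lens_source()].
#' @param detector [detector_spec()].
#' @param time_mode [time_spec()]; default uniform phase sampling.
#' @return An object of class \code{scene}.
#' @export
scene <- function(profile, optics, source, detector,
                  time_mode = time_spec()) {
  stopifnot(inherits(profile, "acoustic_profile"),
            inherits(optics, "medium_optics"),
            is.list(source), is.list(detector), is.list(time_mode))
  depth <- detector$depth_m
  if (is.null(depth)) depth <- optics$L
  if (abs(depth - optics$L) > 1e-12)
    stop("detector plane must coincide with the slab exit face", call. = FALSE)
  if (source$type == "lens" && source$focus_depth_m > optics$L + 1e-12)
    warning("lens focus lies beyond the slab exit face")
  structure(list(profile = profile, optics = optics, source = source,
                 detector = detector, time_mode = time_mode),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene>\n")
  cat(sprintf("  source: %s, diameter %g um, flux %g a.u.\n",
              x$source$type, 1e6 * x$source$diameter_m, x$source$flux_au))
  cat(sprintf("  detector disk: r = %s um at z = L\n",
              paste(signif(1e6 * x$detector$radius_m, 4), collapse = "/")))
  cat(sprintf("  phase mode: %s\n", x$time_mode$mode))
  print(x$profile)
  print(x$optics)
  invisible(x)
}

# Internal: flatten a scene + controls for the compiled core.
scene_to_cpp <- function(sc) {
  tm <- sc$time_mode
  t_fixed <- tm$t_fixed_s
  if (tm$mode == "peak") t_fixed <- 1 / (4 * sc$profile$freq_hz)
  mode_i <- switch(tm$mode, uniform = 0L, fixed = 1L, peak = 1L, duty = 2L)
  t_cent <- tm$duty_center_t
  if (is.null(t_cent)) t_cent <- 1 / (4 * sc$profile$freq_hz)
  list(n0 = sc$profile$n0, delta_n = sc$profile$delta_n,
       freq_hz = sc$profile$freq_hz, k_r = sc$profile$k_r,
       sigma_t = sc$optics$sigma_t, albedo = sc$optics$albedo,
       g = sc$optics$g, L = sc$optics$L, n_ext = sc$optics$n_external,
       source_type = if (sc$source$type == "lens") 1L else 0L,
       beam_radius = sc$source$diameter_m / 2,
       focus_depth = max(sc$source$focus_depth_m, sc$optics$L),
       flux = sc$source$flux_au,
       time_mode = mode_i, t_fixed = t_fixed,
       duty_fraction = tm$duty_fraction, duty_center_t = t_cent,
       det_radii = sc$detector$radius_m)
}

# Internal: default run controls derived from the scene.
default_controls <- function(sc, step_ds = NULL, kill_radius = NULL,
                             max_events = 1e4, order_max = 10, nee = TRUE,
                             fresnel_mode = c("deterministic", "stochastic")) {
  fresnel_mode <- match.arg(fresnel_mode)
  lambda_us <- sc$profile$v_us_m_s / sc$profile$freq_hz
  if (is.null(step_ds)) step_ds <- lambda_us / 20
  if (is.null(kill_radius)) kill_radius <- 10 * first_zero_radius(sc$profile)
  stopifnot(step_ds > 0, kill_radius > 0, max_events >= 1, order_max >= 1)
  list(step_ds = step_ds, kill_radius = kill_radius,
       max_events = as.integer(max_events), order_max = as.integer(order_max),
       nee = isTRUE(nee),
       fresnel_mode = if (fresnel_mode == "stochastic") 1L else 0L,
       image = FALSE, nx = 1L, ny = 1L, pitch = 1, image_order = -1L,
       record = FALSE, weight_min = 1e-4, rr_survive = 0.1)
}
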
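#' Photon state for non-linear ray tracing
#'
#' Holds the Hamiltonian phase-space coordinates of a light path: position
#' \code{x} (m) and reduced velocity \code{v = n(x) omega}, where \code{omega}
#' is the unit propagation direction. The ultrasonic phase is frozen per path
#' (light and ultrasound dynamics differ by several orders of magnitude).
#'
#' @param position 3-vector position in meters.
#' @param direction Unit 3-vector propagation direction.
#' @param profile [acoustic_profile()] used to set |v| = n(x).
#' @param weight Statistical weight (a.u. of flux).
#' @param scatter_count Number of volume scattering events so far.
#' @param phase_time Frozen ultrasonic phase time (s).
#' @return An object of class \code{photon_state}.
#' @export
photon_state <- function(position, direction, profile, weight = 1,
                         scatter_count = 0L, phase_time = 0) {
  stopifnot(length(position) == 3L, length(direction) == 3L,
            inherits(profile, "acoustic_profile"), weight >= 0)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9)
    stop("direction must be unit length", call. = FALSE)
  n_here <- refractive_index(position, phase_time, profile)
  structure(list(position = as.numeric(position),
                 velocity = n_here * as.numeric(direction),
                 weight = weight, scatter_count = as.integer(scatter_count),
                 phase_time = phase_time, alive = TRUE),
            class = "photon_state")
}

#' @export
print.photon_state <- function(x, ...) {
  cat("<photon_state>\n")
  cat(sprintf("  position  [um]: %s\n", paste(signif(1e6 * x$position, 6), collapse = ", ")))
  cat(sprintf("  velocity      : %s\n", paste(signif(x$velocity, 6), collapse = ", ")))
  cat(sprintf("  weight %g, scatters %d, phase t = %g s, %s\n",
              x$weight, x$scatter_count, x$phase_time,
              if (x$alive) "alive" else "terminated"))
  invisible(x)
}

#' Propagate a photon through the modulated medium (leapfrog)
#'
#' Integrates Hamilton's equations for rays,
#' \deqn{dv/ds = \nabla n(x), \qquad dx/ds = v / n(x),}
#' with a second-order symplectic kick-drift-kick leapfrog in arc length.
#' The integrator preserves \eqn{|v| = n(x)} up to bounded drift; the default
#' step (set by callers) is one twentieth of the ultrasonic wavelength.
#'
#' @param state A [photon_state()].
#' @param arc_length Arc length to travel (m, >= 0).
#' @param profile [acoustic_profile()].
#' @param step_ds Integration step in meters (> 0).
#' @param return_path If TRUE, attach the sampled trajectory (matrix of
#'   positions) as attribute \code{"path"}.
#' @return The advanced \code{photon_state}.
#' @export
leapfrog_propagate <- function(state, arc_length, profile, step_ds,
                               return_path = FALSE) {
  stopifnot(inherits(state, "photon_state"),
            inherits(profile, "acoustic_profile"))
  if (!state$alive) stop("photon state is not alive", call. = FALSE)
  if (!is.numeric(arc_length) || arc_length < 0)
    stop("arc_length must be >= 0", call. = FALSE)
  if (!is.numeric(step_ds) || step_ds <= 0)
    stop("step_ds must be positive", call. = FALSE)
  A <- profile$delta_n * sin(2 * pi * profile$freq_hz * state$phase_time)
  res <- cpp_leapfrog(state$position, state$velocity, arc_length, step_ds,
                      profile$n0, A, profile$k_r, return_path)
  if (any(!is.finite(res$position)) || any(!is.finite(res$velocity))) {
    err <- simpleError("numeric failure during leapfrog propagation")
    err$last_state <- state
    stop(err)
  }
  state$position <- res$position
  state$velocity <- res$velocity
  if (return_path) attr(state, "path") <- res$path
  state
}

#' Unpolarized Fresnel power transmittance
#'
#' Average of the s- and p-polarized transmittances for a planar interface
#' from index \code{n1} into \code{n2}. Total internal reflection gives 0.
#'
#' @param n1,n2 Refractive indices on the incidence and transmission side.
#' @param cos_incident Cosine of the incidence angle, in [0, 1].
#' @return Transmittance in [0, 1]; vectorized over its arguments.
#' @examples
#' fresnel_transmittance(1, 1.3333, 1)  # ~0.97959 at normal incidence
#' @export
fresnel_transmittance <- function(n1, n2, cos_incident) {
  if (any(cos_incident < 0 | cos_incident > 1))
    stop("cos_incident must lie in [0, 1]", call. = FALSE)
  cpp_fresnel_t(n1, n2, cos_incident)
}

#' Interact a photon with a slab face
#'
#' Applies Fresnel reflection/refraction at an entry or exit plane of the
#' slab. In the default deterministic mode the weight is multiplied by the
#' transmittance and the refracted ray continues (the reflected branch is
#' dropped, a documented variance-reduction approximation); in stochastic
#' mode the ray refracts with probability T and otherwise reflects
#' specularly, with unchanged weight. The interface transmittance uses the
#' unperturbed background index \code{n_internal} (the ultrasonic modulation
#' is at most a few percent of it).
#'
#' @param state A [photon_state()] positioned on a slab face.
#' @param geometry List with \code{L} (slab length, m), \code{n_internal} and
#'   \code{n_external}.
#' @param u Uniform variate for the stochastic mode (ignored otherwise).
#' @param mode \code{"deterministic"} (default) or \code{"stochastic"}.
#' @return The updated \code{photon_state}; in deterministic TIR the weight
#'   drops to 0 and the state is terminated.
#' @export
boundary_interact <- function(state, geometry, u = NULL,
                              mode = c("deterministic", "stochastic")) {
  stopifnot(inherits(state, "photon_state"))
  mode <- match.arg(mode)
  L <- geometry$L
  z <- state$position[3]
  on_entry <- abs(z) < 1e-9 * max(L, 1)
  on_exit <- abs(z - L) < 1e-9 * max(L, 1)
  if (!on_entry && !on_exit)
    stop("photon is not on a slab face", call. = FALSE)
  v <- state$velocity
  nv <- sqrt(sum(v^2))
  omega <- v / nv
  outward <- if (on_exit) c(0, 0, 1) else c(0, 0, -1)
  ci <- sum(omega * outward)
  if (ci <= 0)
    stop("photon on a face but travelling inward; no interaction", call. = FALSE)
  n1 <- geometry$n_internal
  n2 <- geometry$n_external
  if (n1 == n2) return(state)
  Tt <- fresnel_transmittance(n1, n2, ci)
  refract <- function() {
    # vector Snell refraction about the outward normal
    sin2 <- (n1 / n2)^2 * (1 - ci^2)
    ct <- sqrt(1 - sin2)
    tangent <- omega - ci * outward
    new_dir <- (n1 / n2) * tangent + ct * outward
    new_dir / sqrt(sum(new_dir^2))
  }
  if (mode == "deterministic") {
    state$weight <- state$weight * Tt
    if (Tt == 0) {
      state$alive <- FALSE
    } else {
      state$velocity <- n2 * refract()
    }
  } else {
    if (is.null(u)) u <- runif(1)
    if (u < Tt) {
      state$velocity <- n2 * refract()
    } else {
      omega_r <- omega - 2 * ci * outward
      state$velocity <- n1 * omega_r
    }
  }
  state
}

#' Ray fan of an ideal external thin lens
#'
#' Builds the launch states of an aberration-free, non-absorptive thin lens:
#' rays start across the beam aperture on the entry plane (z = 0), each
#' directed at the on-axis focus at depth \code{focus_depth} inside the
#' medium, with total weight equal to \code{flux}. Used as the
#' external-focusing reference arm (the waveguide is switched off,
#' \code{delta_n = 0}, when simulating it).
#'
#' @param focus_depth Focus depth in meters (> 0).
#' @param beam_diameter Aperture diameter at the entry plane (m).
#' @param flux Total launched flux (a.u.).
#' @param n_rays Number of rays (> 0).
#' @param profile [acoustic_profile()] providing the medium index for the
#'   velocity normalization (use \code{delta_n = 0} for the ideal-lens arm).
#' @return List of [photon_state()] objects; aperture positions are sampled
#'   uniformly over the disk using the current R random stream.
#' @export
lens_ray_fan <- function(focus_depth, beam_diameter, flux, n_rays, profile) {
  if (!is.numeric(focus_depth) || focus_depth <= 0)
    stop("focus_depth must be positive", call. = FALSE)
  if (!is.numeric(n_rays) || n_rays <= 0)
    stop("n_rays must be positive", call. = FALSE)
  n_rays <- as.integer(n_rays)
  r <- (beam_diameter / 2) * sqrt(runif(n_rays))
  th <- 2 * pi * runif(n_rays)
  w <- flux / n_rays
  lapply(seq_len(n_rays), function(i) {
    pos <- c(r[i] * cos(th[i]), r[i] * sin(th[i]), 0)
    dir <- c(-pos[1], -pos[2], focus_depth)
    dir <- dir / sqrt(sum(dir^2))
    photon_state(pos, dir, profile, weight = w)
  })
}
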
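#' Ultrasonically sculpted refractive index profile
#'
#' Describes the refractive index field sculpted in a medium by a cylindrical
#' ultrasonic standing wave,
#' \deqn{n(r, t) = n_0 + \Delta n \, J_0(k_r r) \sin(2 \pi f t),}
#' where \eqn{r} is the distance from the waveguide axis (the beam propagation
#' axis, z), \eqn{J_0} the zeroth-order Bessel function of the first kind and
#' \eqn{k_r = 2 \pi f / V_{us}} the radial component of the ultrasonic
#' wavevector. The profile is azimuth-independent; the phase convention is
#' that \code{t = 0} gives zero modulation and \code{t = 1/(4 f)} peak
#' modulation.
#'
#' @param n0 Background refractive index of the medium (> 1).
#' @param delta_n Refractive index contrast \eqn{\Delta n} (>= 0); proportional
#'   to the ultrasonic pressure amplitude. \code{delta_n = 0} reduces the
#'   field to the constant \code{n0}.
#' @param freq_hz Ultrasonic frequency in Hz (> 0).
#' @param v_us_m_s Speed of sound in the medium in m/s (default 1500, typical
#'   for water and soft tissue).
#' @return An object of class \code{acoustic_profile} with the derived radial
#'   wavevector component \code{k_r} (rad/m).
#' @examples
#' prof <- acoustic_profile(delta_n = 1e-3, freq_hz = 1e6)
#' refractive_index(c(0, 0, 0), phase_time = 1 / (4 * prof$freq_hz), prof)
#' @export
acoustic_profile <- function(n0 = 1.3333, delta_n = 0, freq_hz,
                             v_us_m_s = 1500) {
  stopifnot(is.numeric(n0), length(n0) == 1L, is.finite(n0),
            is.numeric(delta_n), length(delta_n) == 1L, is.finite(delta_n),
            is.numeric(freq_hz), length(freq_hz) == 1L, is.finite(freq_hz),
            is.numeric(v_us_m_s), length(v_us_m_s) == 1L, is.finite(v_us_m_s))
  if (n0 <= 1) stop("background index n0 must exceed 1", call. = FALSE)
  if (delta_n < 0) stop("delta_n must be non-negative", call. = FALSE)
  if (freq_hz <= 0) stop("freq_hz must be positive", call. = FALSE)
  if (v_us_m_s <= 0) stop("v_us_m_s must be positive", call. = FALSE)
  structure(list(n0 = n0, delta_n = delta_n, freq_hz = freq_hz,
                 v_us_m_s = v_us_m_s,
                 k_r = 2 * pi * freq_hz / v_us_m_s),
            class = "acoustic_profile")
}

#' @export
print.acoustic_profile <- function(x, ...) {
  cat("<acoustic_profile>\n")
  cat(sprintf("  n0 = %.4f, delta_n = %g\n", x$n0, x$delta_n))
  cat(sprintf("  f = %g MHz, V_us = %g m/s, k_r = %g rad/m\n",
              x$freq_hz / 1e6, x$v_us_m_s, x$k_r))
  cat(sprintf("  core radius (first J0 zero) = %g um\n",
              1e6 * first_zero_radius(x)))
  invisible(x)
}

as_position_matrix <- function(position) {
  if (is.matrix(position)) {
    if (ncol(position) != 3L) stop("position matrix needs 3 columns", call. = FALSE)
    pos <- position
  } else {
    if (length(position) != 3L) stop("position must be a 3-vector", call. = FALSE)
    pos <- matrix(position, nrow = 1L)
  }
  if (!all(is.finite(pos))) stop("position must be finite", call. = FALSE)
  pos
}

#' Evaluate the sculpted refractive index field
#'
#' @param position A 3-vector (m) or an n x 3 matrix of positions. The
#'   waveguide axis is the z axis.
#' @param phase_time Time within the ultrasonic cycle (s).
#' @param profile An [acoustic_profile()].
#' @return Refractive index value(s), dimensionless.
#' @export
refractive_index <- function(position, phase_time, profile) {
  stopifnot(inherits(profile, "acoustic_profile"), is.finite(phase_time))
  pos <- as_position_matrix(position)
  r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  if (profile$delta_n == 0) return(rep(profile$n0, nrow(pos)))
  profile$n0 + profile$delta_n * besselJ(profile$k_r * r, 0) *
    sin(2 * pi * profile$freq_hz * phase_time)
}

#' Spatial gradient of the sculpted refractive index field
#'
#' The radial derivative is
#' \eqn{\partial n / \partial r = k_r \Delta n J_0'(k_r r) \sin(2\pi f t)}
#' with \eqn{J_0' = -J_1}; the gradient points radially (zero axial and
#' azimuthal components).
#'
#' @inheritParams refractive_index
#' @return A 3-vector (or n x 3 matrix) in 1/m.
#' @export
refractive_index_gradient <- function(position, phase_time, profile) {
  stopifnot(inherits(profile, "acoustic_profile"), is.finite(phase_time))
  pos <- as_position_matrix(position)
  out <- matrix(0, nrow(pos), 3L)
  if (profile$delta_n > 0) {
    r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
    ok <- r > 0
    if (any(ok)) {
      dndr <- -profile$k_r * profile$delta_n *
        besselJ(profile$k_r * r[ok], 1) *
        sin(2 * pi * profile$freq_hz * phase_time)
      out[ok, 1] <- dndr * pos[ok, 1] / r[ok]
      out[ok, 2] <- dndr * pos[ok, 2] / r[ok]
    }
  }
  if (!is.matrix(position)) out <- drop(out)
  out
}

#' Waveguide core radius (first zero of J0)
#'
#' Radius of the central high-index lobe, \eqn{j_{0,1} / k_r} with
#' \eqn{j_{0,1} \approx 2.40483}. Ten times this radius is the default lateral
#' kill radius of the transport geometry.
#'
#' @inheritParams refractive_index
#' @export
first_zero_radius <- function(profile) {
  stopifnot(inherits(profile, "acoustic_profile"))
  J0_FIRST_ROOT / profile$k_r
}

#' Paraxial quarter pitch of the waveguide
#'
#' Under the parabolic approximation \eqn{J_0(k_r r) \approx 1 - (k_r r)^2/4}
#' (at peak modulation) a collimated paraxial ray first crosses the axis at
#' \deqn{z_{q} = \frac{\pi}{2 k_r} \sqrt{2 (n_0 + \Delta n) / \Delta n},}
#' the quarter pitch of the equivalent parabolic gradient-index guide. The
#' k-th on-axis focus sits at \eqn{(2k - 1) z_q}.
#'
#' @inheritParams refractive_index
#' @export
paraxial_quarter_pitch <- function(profile) {
  stopifnot(inherits(profile, "acoustic_profile"))
  if (profile$delta_n <= 0) return(Inf)
  (pi / (2 * profile$k_r)) *
    sqrt(2 * (profile$n0 + profile$delta_n) / profile$delta_n)
}
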
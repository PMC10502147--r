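#' Optical properties of the turbid slab
#'
#' Bundles the radiative-transfer parameters of the medium: extinction
#' coefficient \eqn{\sigma_t}, single-scattering albedo \eqn{a} (probability
#' that a volume interaction scatters rather than absorbs), Henyey-Greenstein
#' anisotropy \eqn{g}, and slab length \eqn{L} along the beam axis. The
#' ultrasound is assumed to modulate only the refractive index, not
#' \eqn{\sigma_t}, \eqn{a} or \eqn{g}.
#'
#' @param sigma_t_per_m Extinction coefficient in 1/m (>= 0; 0 means a
#'   transparent medium with no volume events).
#' @param albedo Single-scattering albedo in [0, 1].
#' @param g Henyey-Greenstein anisotropy factor, |g| < 1.
#' @param length_m Slab geometric length along z in meters (> 0).
#' @param n_external Refractive index outside both slab faces (default 1,
#'   air; set to the medium index for index-matched/tank-immersed scenarios).
#' @return An object of class \code{medium_optics}.
#' @examples
#' opt <- medium_optics(166.7, albedo = 0.99, g = 0.9, length_m = 0.03)
#' optical_depth(opt)          # about 5 mean free paths
#' optical_depth(opt, "TMFP")  # 0.5 transport mean free paths
#' @export
medium_optics <- function(sigma_t_per_m = 0, albedo = 0.99, g = 0.9,
                          length_m, n_external = 1) {
  stopifnot(is.numeric(sigma_t_per_m), length(sigma_t_per_m) == 1L,
            is.numeric(albedo), length(albedo) == 1L,
            is.numeric(g), length(g) == 1L,
            is.numeric(length_m), length(length_m) == 1L,
            is.numeric(n_external), length(n_external) == 1L)
  if (sigma_t_per_m < 0) stop("sigma_t_per_m must be >= 0", call. = FALSE)
  if (albedo < 0 || albedo > 1) stop("albedo must lie in [0, 1]", call. = FALSE)
  if (abs(g) >= 1) stop("anisotropy g must satisfy |g| < 1", call. = FALSE)
  if (length_m <= 0) stop("length_m must be positive", call. = FALSE)
  if (n_external < 1) stop("n_external must be >= 1", call. = FALSE)
  structure(list(sigma_t = sigma_t_per_m, albedo = albedo, g = g,
                 L = length_m, n_external = n_external),
            class = "medium_optics")
}

#' @export
print.medium_optics <- function(x, ...) {
  cat("<medium_optics>\n")
  cat(sprintf("  sigma_t = %g /m, albedo = %g, g = %g\n",
              x$sigma_t, x$albedo, x$g))
  cat(sprintf("  L = %g mm (%.3g MFP, %.3g TMFP), n_external = %g\n",
              1e3 * x$L, optical_depth(x), optical_depth(x, "TMFP"),
              x$n_external))
  invisible(x)
}

#' Mean free path and transport mean free path
#'
#' \code{mean_free_path} returns \eqn{1/\sigma_t}, the average distance
#' between volume events; \code{transport_mean_free_path} returns
#' \eqn{1/(\sigma_t (1 - g))}, the direction-randomization length.
#'
#' @param optics A [medium_optics()].
#' @return Length in meters (Inf for a transparent medium).
#' @export
mean_free_path <- function(optics) {
  stopifnot(inherits(optics, "medium_optics"))
  if (optics$sigma_t == 0) return(Inf)
  1 / optics$sigma_t
}

#' @rdname mean_free_path
#' @export
transport_mean_free_path <- function(optics) {
  stopifnot(inherits(optics, "medium_optics"))
  if (optics$sigma_t == 0) return(Inf)
  1 / (optics$sigma_t * (1 - optics$g))
}

#' Optical depth of the slab
#'
#' Slab length expressed in scattering length units: \code{L / MFP} or
#' \code{L / TMFP}. A transparent medium (\code{sigma_t = 0}) has depth 0.
#'
#' @param optics A [medium_optics()].
#' @param units Either \code{"MFP"} (default) or \code{"TMFP"}.
#' @export
optical_depth <- function(optics, units = c("MFP", "TMFP")) {
  stopifnot(inherits(optics, "medium_optics"))
  units <- match.arg(units)
  if (optics$sigma_t == 0) return(0)
  lref <- if (units == "MFP") mean_free_path(optics) else
    transport_mean_free_path(optics)
  optics$L / lref
}

#' Sample an exponential free path
#'
#' Inverse-CDF sampling of the distance to the next volume event,
#' \eqn{s = -\ln(1 - u) / \sigma_t}. For a transparent medium the sentinel
#' \code{Inf} is returned (the ray crosses the slab ballistically).
#'
#' @param sigma_t Extinction coefficient in 1/m.
#' @param u Uniform(0,1) variate(s), in [0, 1).
#' @return Free path length(s) in meters.
#' @export
sample_free_path <- function(sigma_t, u) {
  stopifnot(is.numeric(sigma_t), length(sigma_t) == 1L, sigma_t >= 0)
  if (any(!is.finite(u)) || any(u < 0) || any(u >= 1))
    stop("u must lie in [0, 1)", call. = FALSE)
  if (sigma_t == 0) return(rep(Inf, length(u)))
  -log(1 - u) / sigma_t
}

#' Henyey-Greenstein phase function
#'
#' Density over solid angle of the scattering deflection,
#' \deqn{f_s(\cos\theta) = \frac{1 - g^2}{4\pi (1 + g^2 - 2 g
#' \cos\theta)^{3/2}},}
#' normalized so that its integral over the unit sphere is 1; the mean cosine
#' of the deflection equals \eqn{g}.
#'
#' @param g Anisotropy factor, |g| < 1.
#' @param cos_theta Cosine(s) of the deflection angle.
#' @return Density value(s) in 1/sr.
#' @export
hg_pdf <- function(g, cos_theta) {
  stopifnot(abs(g) < 1)
  denom <- 1 + g^2 - 2 * g * cos_theta
  (1 - g^2) / (4 * pi * denom^1.5)
}

#' Sample a Henyey-Greenstein scattering direction
#'
#' Deterministically maps two uniform variates to an outgoing unit direction
#' whose deflection cosine from \code{incoming} follows the
#' Henyey-Greenstein density. The local frame is built with a branch-free
#' orthonormal basis so results are reproducible across platforms.
#'
#' @param g Anisotropy factor, |g| < 1.
#' @param incoming Unit 3-vector of the incoming direction.
#' @param u1,u2 Uniform(0,1) variates.
#' @return A unit 3-vector.
#' @export
hg_sample_direction <- function(g, incoming, u1, u2) {
  stopifnot(abs(g) < 1, length(incoming) == 3L)
  nrm <- sqrt(sum(incoming^2))
  if (abs(nrm - 1) > 1e-9)
    stop("incoming direction must be unit length", call. = FALSE)
  cpp_hg_direction(g, incoming, u1, u2)
}
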
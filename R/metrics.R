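#' Turbid-versus-transparent throughput comparison
#'
#' Pairs the flux reaching the target disk in the turbid medium, \eqn{F_s(r)},
#' with the flux in the transparent reference \eqn{F_t(r)} (same source,
#' same ultrasound settings, refractive index of water, no scattering or
#' absorption), for one focusing method.
#'
#' @param F_s Flux in the turbid medium (a.u., >= 0).
#' @param F_t Flux in the transparent reference (a.u., > 0 for losses).
#' @param r Target disk radius (m).
#' @param method \code{"waveguide"} or \code{"lens"}.
#' @export
throughput_comparison <- function(F_s, F_t, r, method = c("waveguide", "lens")) {
  method <- match.arg(method)
  stopifnot(F_s >= 0, F_t >= 0, r > 0)
  structure(list(F_s = F_s, F_t = F_t, r = r, method = method),
            class = "throughput_comparison")
}

#' Insertion loss of a focusing method in a turbid medium
#'
#' \deqn{\mathrm{insertion\_loss}(r) = -10 \log_{10}(F_s(r) / F_t(r)),}
#' positive when scattering loses light; \code{+Inf} when no light reaches
#' the target in the turbid medium.
#'
#' @param comp A [throughput_comparison()].
#' @return Loss in dB.
#' @export
insertion_loss <- function(comp) {
  stopifnot(inherits(comp, "throughput_comparison"))
  if (comp$F_t <= 0) stop("transparent reference flux must be positive",
                          call. = FALSE)
  if (comp$F_s == 0) return(Inf)
  -10 * log10(comp$F_s / comp$F_t)
}

#' Insertion gain and relative throughput enhancement
#'
#' The insertion gain of a virtual optical waveguide over an external lens is
#' the difference of their insertion losses (dB); the relative throughput
#' enhancement is the percentage improvement of the waveguide's
#' turbid-to-transparent flux ratio over the lens's. The two satisfy
#' \code{gain = 10 log10(1 + enhancement/100)}.
#'
#' @param lens_loss,us_loss Insertion losses in dB.
#' @return Gain in dB.
#' @export
insertion_gain <- function(lens_loss, us_loss) lens_loss - us_loss

#' @rdname insertion_gain
#' @param us,lens [throughput_comparison()] objects at the same target radius.
#' @return Enhancement in percent.
#' @export
enhancement <- function(us, lens) {
  stopifnot(inherits(us, "throughput_comparison"),
            inherits(lens, "throughput_comparison"))
  if (abs(us$r - lens$r) > 1e-12 * max(us$r, lens$r))
    stop("comparisons must use the same target radius", call. = FALSE)
  ratio_us <- us$F_s / us$F_t
  ratio_lens <- lens$F_s / lens$F_t
  (ratio_us - ratio_lens) / ratio_lens * 100
}

#' Mechanical index and the diagnostic safety limit
#'
#' \deqn{\mathrm{MI} = P_r / \sqrt{f},} with the derated peak rarefaction
#' pressure \eqn{P_r} in MPa and the frequency \eqn{f} in MHz. Diagnostic
#' ultrasound requires MI <= 1.9 (FDA limit).
#'
#' @param P_r_mpa Derated peak rarefaction pressure in MPa (>= 0).
#' @param f_mhz Ultrasonic frequency in MHz (> 0).
#' @param limit MI limit (default 1.9).
#' @export
mechanical_index <- function(P_r_mpa, f_mhz) {
  if (any(f_mhz <= 0)) stop("frequency must be positive", call. = FALSE)
  if (any(P_r_mpa < 0)) stop("pressure must be >= 0", call. = FALSE)
  P_r_mpa / sqrt(f_mhz)
}

#' @rdname mechanical_index
#' @export
max_safe_pressure <- function(f_mhz, limit = 1.9) {
  if (any(f_mhz <= 0)) stop("frequency must be positive", call. = FALSE)
  limit * sqrt(f_mhz)
}

#' @rdname mechanical_index
#' @export
is_safe <- function(P_r_mpa, f_mhz, limit = 1.9) {
  mechanical_index(P_r_mpa, f_mhz) <= limit
}

#' Ultrasound safety model
#'
#' Holds the mechanical-index limit and, optionally, the linear coupling
#' between pressure and refractive index contrast (\code{coupling_per_mpa},
#' delta-n per MPa). No default coupling is asserted: the pressure-to-index
#' conversion depends on the medium and must be supplied explicitly wherever
#' a safety boundary is drawn in (f, delta_n) space.
#'
#' @param P_r_mpa Operating derated peak rarefaction pressure (MPa, >= 0).
#' @param f_mhz Operating frequency (MHz).
#' @param limit MI limit (default 1.9).
#' @param coupling_per_mpa Optional delta-n per MPa (> 0).
#' @export
safety_model <- function(P_r_mpa = 0, f_mhz = 1, limit = 1.9,
                         coupling_per_mpa = NULL) {
  stopifnot(P_r_mpa >= 0, limit > 0)
  if (!is.null(coupling_per_mpa)) stopifnot(coupling_per_mpa > 0)
  structure(list(P_r_mpa = P_r_mpa, f_mhz = f_mhz, limit = limit,
                 coupling_per_mpa = coupling_per_mpa),
            class = "safety_model")
}

#' Frequency-amplitude sweep grid
#'
#' Container for a matrix of flux estimates over a frequency x amplitude
#' grid, the substrate from which focal loci are extracted.
#'
#' @param f_hz Ascending vector of ultrasonic frequencies (Hz).
#' @param delta_n Ascending vector of index contrasts.
#' @param flux Matrix \code{length(f_hz)} x \code{length(delta_n)} of fluxes.
#' @param se Matching matrix of standard errors (optional).
#' @export
sweep_grid <- function(f_hz, delta_n, flux, se = NULL) {
  f_hz <- as.numeric(f_hz); delta_n <- as.numeric(delta_n)
  stopifnot(!is.unsorted(f_hz, strictly = TRUE),
            !is.unsorted(delta_n, strictly = TRUE),
            is.matrix(flux),
            nrow(flux) == length(f_hz), ncol(flux) == length(delta_n))
  if (any(flux < 0)) stop("fluxes must be non-negative", call. = FALSE)
  if (!is.null(se)) stopifnot(all(dim(se) == dim(flux)))
  structure(list(f_hz = f_hz, delta_n = delta_n, flux = flux, se = se),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("<sweep_grid> %d frequencies x %d amplitudes, flux %.3g..%.3g\n",
              length(x$f_hz), length(x$delta_n), min(x$flux), max(x$flux)))
  invisible(x)
}

#' Extract focal loci from a frequency-amplitude sweep
#'
#' Focal loci are the approximately hyperbolic curves of (f, delta_n) pairs
#' that bring the beam to an on-axis focus exactly at the target plane; the
#' k-th-order locus corresponds to the k-th intermediate focus. Ridge points
#' are local maxima of flux along the delta_n axis at fixed f (with
#' quadratic sub-cell refinement in log delta_n), chained across neighboring
#' frequencies by proximity, and loci are ordered by increasing
#' \code{delta_n * f} (order 1 = lowest). Extraction is invariant to uniform
#' rescaling of the flux matrix.
#'
#' @param grid A [sweep_grid()].
#' @param min_points Minimum chained points for a locus to be reported.
#' @return List of class \code{focal_loci}; each element is a data frame
#'   \code{(f_hz, delta_n, flux)} with attribute \code{order}. An empty list
#'   (with a warning) when the grid is flat.
#' @export
find_focal_loci <- function(grid, min_points = 2L) {
  stopifnot(inherits(grid, "sweep_grid"))
  nf <- length(grid$f_hz); nd <- length(grid$delta_n)
  rel <- diff(range(grid$flux))
  if (rel <= 1e-12 * max(abs(grid$flux), 1e-300)) {
    warning("flat sweep grid: no focal loci found")
    return(structure(list(), class = "focal_loci"))
  }
  ldn <- log(grid$delta_n)
  step <- median(diff(ldn))
  # per-frequency ridge points
  peaks <- vector("list", nf)
  for (i in seq_len(nf)) {
    y <- grid$flux[i, ]
    idx <- which(diff(sign(diff(y))) < 0) + 1L  # strict interior local maxima
    pts <- lapply(idx, function(j) {
      denom <- y[j - 1] - 2 * y[j] + y[j + 1]
      off <- if (denom < 0) 0.5 * (y[j - 1] - y[j + 1]) / denom else 0
      off <- max(-0.5, min(0.5, off))
      list(ldn = ldn[j] + off * step, flux = y[j])
    })
    peaks[[i]] <- pts
  }
  # chain ridge points across frequencies in log(delta_n * f): loci are
  # near-hyperbolic, so that coordinate is locally constant along a locus
  loci <- list()   # each: list(rows = list(...), last_ldnf, last_i)
  tol <- 1.5 * abs(step)
  for (i in seq_len(nf)) {
    lf <- log(grid$f_hz[i])
    for (p in peaks[[i]]) {
      best <- 0; bestd <- Inf
      for (k in seq_along(loci)) {
        if (loci[[k]]$last_i >= i) next  # one point per frequency per locus
        if (i - loci[[k]]$last_i > 2) next
        d <- abs((p$ldn + lf) - loci[[k]]$last_ldnf)
        if (d < bestd) { bestd <- d; best <- k }
      }
      if (best > 0 && bestd <= tol) {
        loci[[best]]$rows <- c(loci[[best]]$rows,
                               list(c(grid$f_hz[i], exp(p$ldn), p$flux)))
        loci[[best]]$last_ldnf <- p$ldn + lf
        loci[[best]]$last_i <- i
      } else {
        loci[[length(loci) + 1L]] <- list(
          rows = list(c(grid$f_hz[i], exp(p$ldn), p$flux)),
          last_ldnf = p$ldn + lf, last_i = i)
      }
    }
  }
  out <- lapply(loci, function(lc) {
    m <- do.call(rbind, lc$rows)
    df <- data.frame(f_hz = m[, 1], delta_n = m[, 2], flux = m[, 3])
    df[order(df$f_hz), , drop = FALSE]
  })
  out <- out[vapply(out, nrow, 1L) >= min_points]
  if (!length(out)) {
    warning("no chained focal loci found")
    return(structure(list(), class = "focal_loci"))
  }
  key <- vapply(out, function(df) median(df$delta_n * df$f_hz), 0)
  out <- out[order(key)]
  for (k in seq_along(out)) attr(out[[k]], "order") <- k
  structure(out, class = "focal_loci")
}

#' @export
print.focal_loci <- function(x, ...) {
  cat(sprintf("<focal_loci> %d loci\n", length(x)))
  for (k in seq_along(x)) {
    df <- x[[k]]
    cat(sprintf("  order %d: %d points, f %.3g..%.3g MHz, delta_n %.3g..%.3g\n",
                attr(df, "order"), nrow(df), min(df$f_hz) / 1e6,
                max(df$f_hz) / 1e6, min(df$delta_n), max(df$delta_n)))
  }
  invisible(x)
}

#' Safety-constrained configuration per focal locus
#'
#' Within each focal locus, throughput improves towards lower frequency /
#' higher amplitude, so only the configuration with the largest index
#' contrast that still satisfies the mechanical-index limit needs simulating.
#' The safety boundary in (f, delta_n) space is
#' \code{delta_n <= coupling * limit * sqrt(f_MHz)}; its intersection with
#' each locus is found by linear interpolation along the locus. Loci lying
#' wholly in the unsafe region are dropped; with an unbounded limit each
#' locus contributes its maximum-amplitude point.
#'
#' @param loci A \code{focal_loci} list.
#' @param safety A [safety_model()].
#' @param coupling Linear delta-n per MPa coupling; defaults to the model's
#'   \code{coupling_per_mpa}. Required (no physical default exists).
#' @return Data frame \code{(order, f_hz, delta_n)} of candidate
#'   configurations, one per locus that intersects the safe region.
#' @export
select_safe_configs <- function(loci, safety, coupling = NULL) {
  stopifnot(inherits(loci, "focal_loci"), inherits(safety, "safety_model"))
  if (is.null(coupling)) coupling <- safety$coupling_per_mpa
  if (is.null(coupling))
    stop("a delta_n-per-MPa coupling coefficient must be supplied: the ",
         "pressure-to-index conversion is medium-specific and has no ",
         "universal default", call. = FALSE)
  rows <- list()
  for (df in loci) {
    ord <- attr(df, "order")
    bound <- coupling * safety$limit * sqrt(df$f_hz / 1e6)
    excess <- df$delta_n - bound   # > 0 means unsafe
    if (all(excess > 0)) next      # locus wholly unsafe
    if (all(excess <= 0) || !is.finite(safety$limit)) {
      j <- which.max(df$delta_n)
      rows[[length(rows) + 1L]] <- data.frame(order = ord, f_hz = df$f_hz[j],
                                              delta_n = df$delta_n[j])
      next
    }
    # locus delta_n falls with f while the bound rises: unique crossing
    i2 <- which(excess <= 0)[1]
    if (i2 == 1L) {
      rows[[length(rows) + 1L]] <- data.frame(order = ord, f_hz = df$f_hz[1],
                                              delta_n = df$delta_n[1])
      next
    }
    i1 <- i2 - 1L
    w <- excess[i1] / (excess[i1] - excess[i2])
    rows[[length(rows) + 1L]] <- data.frame(
      order = ord,
      f_hz = df$f_hz[i1] + w * (df$f_hz[i2] - df$f_hz[i1]),
      delta_n = df$delta_n[i1] + w * (df$delta_n[i2] - df$delta_n[i1]))
  }
  if (!length(rows)) return(data.frame(order = integer(), f_hz = numeric(),
                                       delta_n = numeric()))
  do.call(rbind, rows)
}

#' Index contrast satisfying the focal condition at the exit plane
#'
#' Solves for the delta_n that places the k-th on-axis focus of a collimated
#' paraxial ray exactly at depth L, at peak ultrasonic modulation. The ray is
#' traced through the full Bessel profile with the leapfrog integrator and
#' the k-th axial crossing depth is driven to L by root bracketing around the
#' parabolic-approximation seed.
#'
#' @param freq_hz Ultrasonic frequency (Hz).
#' @param L Target depth = slab length (m).
#' @param order Focus order k (>= 1).
#' @param n0 Background index.
#' @param v_us_m_s Sound speed (m/s).
#' @param launch_frac Launch radius as a fraction of the core radius
#'   (paraxial regime; default 0.02).
#' @return The focal delta_n.
#' @export
focal_delta_n <- function(freq_hz, L, order = 1L, n0 = 1.3333,
                          v_us_m_s = 1500, launch_frac = 0.02) {
  stopifnot(freq_hz > 0, L > 0, order >= 1)
  kr <- 2 * pi * freq_hz / v_us_m_s
  r0 <- launch_frac * J0_FIRST_ROOT / kr
  ds <- (v_us_m_s / freq_hz) / 40
  # parabolic-profile seed: (2k-1) * quarter pitch = L
  seed_dn <- 2 * n0 * ((2 * order - 1) * pi / (2 * L * kr))^2
  zk <- function(dn) {
    cr <- cpp_axial_crossings(r0, n0, dn, kr, ds, 6 * L, as.integer(order))
    if (length(cr) < order) return(NA_real_)
    cr[order]
  }
  fobj <- function(dn) {
    z <- zk(dn)
    if (is.na(z)) return(2 * L)  # too weak: focus beyond reach
    z - L
  }
  lo <- seed_dn / 4; hi <- seed_dn * 4
  flo <- fobj(lo); fhi <- fobj(hi)
  tries <- 0
  while (flo * fhi > 0 && tries < 8) {
    lo <- lo / 2; hi <- hi * 2
    flo <- fobj(lo); fhi <- fobj(hi)
    tries <- tries + 1
  }
  if (flo * fhi > 0)
    stop("could not bracket the focal condition; check parameters",
         call. = FALSE)
  uniroot(fobj, c(lo, hi), tol = seed_dn * 1e-6)$root
}

#' Focus order of a frequency-contrast configuration
#'
#' Counts the on-axis foci a collimated paraxial ray passes through inside a
#' slab of length L at peak modulation: a configuration on the k-th focal
#' locus has exactly k crossings, the last one at the exit plane. This is
#' the locus-order index used to compare configurations across optical
#' depths; it agrees with ordering by \code{delta_n * f}.
#'
#' @param freq_hz Ultrasonic frequency (Hz).
#' @param delta_n Index contrast.
#' @param L Slab length (m).
#' @param n0 Background index.
#' @param v_us_m_s Sound speed (m/s).
#' @param order_max Count foci up to this order.
#' @return Integer count of axial crossings within the slab (0 when the
#'   first focus lies beyond the exit plane).
#' @export
focal_order_of <- function(freq_hz, delta_n, L, n0 = 1.3333,
                           v_us_m_s = 1500, order_max = 20L) {
  stopifnot(freq_hz > 0, delta_n >= 0, L > 0)
  if (delta_n == 0) return(0L)
  kr <- 2 * pi * freq_hz / v_us_m_s
  r0 <- 0.02 * J0_FIRST_ROOT / kr
  ds <- min((v_us_m_s / freq_hz) / 40, L / 400)
  length(cpp_axial_crossings(r0, n0, delta_n, kr, ds, L, as.integer(order_max)))
}
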
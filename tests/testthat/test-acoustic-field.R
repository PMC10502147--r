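test_that("index field matches the Bessel standing-wave profile", {
  prof <- acoustic_profile(n0 = 1.3333, delta_n = 2e-3, freq_hz = 1e6)
  t_peak <- 1 / (4 * prof$freq_hz)

  # on axis at peak modulation: J0(0) = 1
  expect_equal(refractive_index(c(0, 0, 0), t_peak, prof),
               prof$n0 + prof$delta_n)
  # unmodulated medium
  prof0 <- acoustic_profile(delta_n = 0, freq_hz = 1e6)
  expect_equal(refractive_index(c(1e-3, 2e-4, 5), 0.37e-6, prof0), prof0$n0)
  # zero-modulation phase
  expect_equal(refractive_index(c(3e-4, 0, 0), 0, prof), prof$n0)

  # first root of J0 located by an independent root finder on the series
  j0_series <- function(x) {
    k <- 0:19
    sum((-1)^k / (factorial(k)^2) * (x / 2)^(2 * k))
  }
  root <- uniroot(j0_series, c(2, 3), tol = 1e-12)$root
  r <- root / prof$k_r
  expect_lt(abs(refractive_index(c(r, 0, 0), t_peak, prof) - prof$n0), 1e-6)

  # azimuth independence
  r0 <- 3e-4
  phis <- 2 * pi * unit_grid(8)
  vals <- refractive_index(cbind(r0 * cos(phis), r0 * sin(phis), 0),
                           t_peak, prof)
  expect_equal(max(vals) - min(vals), 0)

  expect_error(refractive_index(c(NaN, 0, 0), 0, prof), "finite")
  expect_error(acoustic_profile(n0 = 0.9, freq_hz = 1e6), "n0")
  expect_error(acoustic_profile(delta_n = -1e-3, freq_hz = 1e6), "delta_n")
})

test_that("gradient is radial and consistent with the field", {
  prof <- acoustic_profile(n0 = 1.3333, delta_n = 5e-3, freq_hz = 0.7e6)
  t_peak <- 1 / (4 * prof$freq_hz)
  # zero on the axis and at the zero-modulation phase
  expect_equal(refractive_index_gradient(c(0, 0, 0.01), t_peak, prof),
               c(0, 0, 0))
  expect_equal(refractive_index_gradient(c(2e-4, 1e-4, 0), 0, prof),
               c(0, 0, 0))

  # finite-difference oracle over random positions and phases
  set.seed(42)
  n <- 1000
  r <- runif(n, 0.05, 1.4) * first_zero_radius(prof)  # J1 > 0 here
  phi <- runif(n, 0, 2 * pi)
  tt <- runif(n, 0.05, 0.45) / prof$freq_hz  # keep sin well away from 0
  h <- 1e-9
  worst <- 0
  for (i in seq_len(n)) {
    p <- c(r[i] * cos(phi[i]), r[i] * sin(phi[i]), 0.003)
    gr <- refractive_index_gradient(p, tt[i], prof)
    num <- vapply(1:2, function(d) {
      e <- c(0, 0, 0); e[d] <- h
      (refractive_index(p + e, tt[i], prof) -
         refractive_index(p - e, tt[i], prof)) / (2 * h)
    }, 0)
    rel <- sqrt(sum((gr[1:2] - num)^2)) / max(sqrt(sum(num^2)), 1e-12)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
  expect_equal(gr[3], 0)  # axial component always zero
})

test_that("gradient prefactor scales as delta_n * k_r and field is periodic", {
  p1 <- acoustic_profile(delta_n = 4e-3, freq_hz = 0.6e6)
  p2 <- acoustic_profile(delta_n = 2e-3, freq_hz = 1.2e6)
  expect_equal(p1$delta_n * p1$k_r, p2$delta_n * p2$k_r)
  expect_equal(p2$k_r, 2 * pi * p2$freq_hz / p2$v_us_m_s, tolerance = 1e-12)

  prof <- acoustic_profile(delta_n = 3e-3, freq_hz = 1e6)
  pos <- c(4e-4, -2e-4, 0.01)
  for (t0 in c(0.13e-6, 0.61e-6))
    expect_equal(refractive_index(pos, t0, prof),
                 refractive_index(pos, t0 + 1 / prof$freq_hz, prof),
                 tolerance = 1e-12)
})

test_that("fast Bessel evaluations agree with the reference implementation", {
  x <- c(seq(0, 3, length.out = 301), seq(3.001, 60, length.out = 500))
  expect_lt(max(abs(sonotrace:::cpp_bessel_j0(x) - besselJ(x, 0))), 5e-7)
  expect_lt(max(abs(sonotrace:::cpp_bessel_j1(x) - besselJ(x, 1))), 5e-7)
  # truncated power series at small argument
  j0_series <- function(x) {
    k <- 0:19
    vapply(x, function(xi) sum((-1)^k / factorial(k)^2 * (xi / 2)^(2 * k)), 0)
  }
  xs <- seq(0, 2, length.out = 41)
  expect_lt(max(abs(sonotrace:::cpp_bessel_j0(xs) - j0_series(xs))), 5e-7)
})
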
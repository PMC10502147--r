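test_that("insertion loss, gain and enhancement identities", {
  eqc <- throughput_comparison(100, 100, 50e-6)
  expect_equal(insertion_loss(eqc), 0)
  expect_equal(insertion_loss(throughput_comparison(10, 100, 50e-6)), 10)
  expect_identical(insertion_loss(throughput_comparison(0, 100, 50e-6)), Inf)
  expect_error(insertion_loss(throughput_comparison(1, 0, 50e-6)), "positive")

  set.seed(2)
  for (i in 1:50) {
    fs <- runif(1, 1e-6, 1e5); ft <- runif(1, 1e-6, 1e5)
    loss <- insertion_loss(throughput_comparison(fs, ft, 1e-5))
    expect_lt(abs(10^(-loss / 10) - fs / ft), 1e-12 * max(1, fs / ft))
  }

  us <- throughput_comparison(20, 100, 12e-6, "waveguide")
  ln <- throughput_comparison(10, 100, 12e-6, "lens")
  expect_equal(enhancement(us, ln), 100)
  gain <- insertion_gain(insertion_loss(ln), insertion_loss(us))
  expect_equal(gain, 10 * log10(2), tolerance = 1e-10)
  expect_equal(enhancement(ln, ln), 0)
  expect_equal(insertion_gain(3, 3), 0)

  # gain = 10 log10(1 + enhancement/100) on random inputs
  for (i in 1:50) {
    us <- throughput_comparison(runif(1, 1, 50), runif(1, 60, 100), 1e-5,
                                "waveguide")
    ln <- throughput_comparison(runif(1, 1, 50), runif(1, 60, 100), 1e-5,
                                "lens")
    g1 <- insertion_gain(insertion_loss(ln), insertion_loss(us))
    expect_equal(g1, 10 * log10(1 + enhancement(us, ln) / 100),
                 tolerance = 1e-10)
  }
  us2 <- throughput_comparison(1, 2, 2e-5, "waveguide")
  expect_error(enhancement(us2, ln), "same target radius")
})

test_that("mechanical index arithmetic and safe-pressure inversion", {
  expect_equal(mechanical_index(1.9, 1), 1.9)
  expect_equal(mechanical_index(0, 7.5), 0)
  expect_equal(max_safe_pressure(4, 1.9), 3.8)
  expect_true(is_safe(1.0, 4))
  expect_false(is_safe(4.0, 4))
  expect_error(mechanical_index(1, 0), "positive")
})

# synthetic sweep with Gaussian ridges planted on delta_n * f = const curves
planted_grid <- function(cs = c(800, 1600, 3200), amp = c(1, 0.8, 0.6),
                         nf = 12, nd = 60, sd_ln = 0.15) {
  f <- seq(0.3e6, 1.5e6, length.out = nf)
  dn <- exp(seq(log(1e-4), log(5e-2), length.out = nd))
  flux <- matrix(0, nf, nd)
  for (k in seq_along(cs)) {
    ridge <- outer(f, dn, function(ff, dd) log(dd * ff / cs[k]))
    flux <- flux + amp[k] * exp(-ridge^2 / (2 * sd_ln^2)) * 1e4
  }
  sweep_grid(f, dn, flux)
}

test_that("focal locus extraction recovers planted hyperbolic ridges", {
  grid <- planted_grid()
  loci <- find_focal_loci(grid)
  expect_length(loci, 3)
  step <- median(diff(log(grid$delta_n)))
  for (k in 1:3) {
    df <- loci[[k]]
    expect_identical(attr(df, "order"), k)
    planted <- c(800, 1600, 3200)[k] / df$f_hz
    expect_lt(max(abs(log(df$delta_n) - log(planted))), 1.01 * step)
    # hyperbola monotonicity: delta_n strictly decreasing in f
    expect_true(all(diff(df$delta_n) < 0))
  }
  # invariance to uniform rescaling of the flux matrix
  grid2 <- sweep_grid(grid$f_hz, grid$delta_n, grid$flux * 37.2)
  loci2 <- find_focal_loci(grid2)
  expect_equal(lapply(loci2, function(d) d[c("f_hz", "delta_n")]),
               lapply(loci, function(d) d[c("f_hz", "delta_n")]))

  flat <- sweep_grid(grid$f_hz, grid$delta_n,
                     matrix(1, length(grid$f_hz), length(grid$delta_n)))
  expect_warning(l0 <- find_focal_loci(flat), "flat")
  expect_length(l0, 0)
})

test_that("safety-constrained configuration selection", {
  loci <- find_focal_loci(planted_grid())
  kappa <- 1.6e-3  # delta_n per MPa
  sm <- safety_model(limit = 1.9)
  sel <- select_safe_configs(loci, sm, coupling = kappa)
  expect_equal(nrow(sel), 3)  # three loci -> three candidates
  # closed-form intersection of dn = c/f with dn = kappa * 1.9 * sqrt(f_MHz)
  step <- log(5e-2 / 1e-4) / 59  # grid spacing in log delta_n
  for (k in 1:3) {
    c_k <- median(loci[[k]]$delta_n * loci[[k]]$f_hz)
    # dn = c/f meets dn = kappa * limit * sqrt(f / 1e6) at
    # f = (c * 1e3 / (kappa * limit))^(2/3)
    f_star <- (c_k * 1e3 / (kappa * 1.9))^(2 / 3)
    dn_star <- c_k / f_star
    row <- sel[sel$order == k, ]
    expect_lt(abs(log(row$delta_n) - log(dn_star)), 1.5 * step)
  }
  # unconstrained limit returns each locus's maximum-contrast point
  sel_inf <- select_safe_configs(loci, safety_model(limit = Inf),
                                 coupling = kappa)
  for (k in 1:3)
    expect_equal(sel_inf$delta_n[sel_inf$order == k],
                 max(loci[[k]]$delta_n))
  expect_error(select_safe_configs(loci, sm), "coupling")
})

test_that("focal condition solver places the k-th focus at the exit plane", {
  for (k in c(1L, 3L)) {
    dn <- focal_delta_n(30.52e6, 2.67e-3, k)
    prof <- acoustic_profile(1.3333, dn, 30.52e6)
    ds <- (prof$v_us_m_s / prof$freq_hz) / 40
    cr <- sonotrace:::cpp_axial_crossings(0.02 * first_zero_radius(prof),
                                          prof$n0, dn, prof$k_r, ds,
                                          6 * 2.67e-3, k)
    expect_lt(abs(cr[k] - 2.67e-3) / 2.67e-3, 5e-3)
  }
  # near the parabolic-approximation seed for order 1
  dn1 <- focal_delta_n(1e6, 0.03, 1)
  kr <- 2 * pi * 1e6 / 1500
  seed <- 2 * 1.3333 * (pi / (2 * 0.03 * kr))^2
  expect_lt(abs(dn1 - seed) / seed, 0.05)
})
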
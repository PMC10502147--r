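test_that("estimates are bit-reproducible and ballistic slabs are exact", {
  sc <- transparent_scene()
  a <- estimate_flux(sc, 5e3, seed = 1)
  b <- estimate_flux(sc, 5e3, seed = 1)
  expect_identical(a$mean_flux, b$mean_flux)
  expect_identical(a$flux_by_order, b$flux_by_order)

  # every photon lands at its launch transverse position with weight
  # w0 * T_entry * T_exit; the beam sits inside the detector disk
  expect_equal(as.numeric(a$mean_flux), 1000 * T_NORMAL^2, tolerance = 1e-12)
  expect_equal(as.numeric(a$flux_by_order[1, "0"]), 1000 * T_NORMAL^2,
               tolerance = 1e-12)
  rec <- trace_photon(sc, n_photons = 20, seed = 3)
  expect_true(all(rec$contributions$order == 0))
  expect_true(all(rec$contributions$type == "direct"))
  expect_equal(rec$contributions$weight,
               rep(1000 / 20 * T_NORMAL^2, 20), tolerance = 1e-12)
  expect_true(all(sqrt(rec$contributions$x_m^2 + rec$contributions$y_m^2)
                  <= 50e-6))
})

test_that("ballistic order obeys Beer-Lambert at 5 MFP", {
  sc <- scene(acoustic_profile(1.3333, 0, 1e6),
              medium_optics(5 / 0.03, 0.99, 0.9, 0.03),
              beam_source(100e-6, 1e4), detector_spec(150e-6))
  fe <- estimate_flux(sc, 1e5, seed = 6)
  expected <- 1e4 * T_NORMAL^2 * exp(-5)
  n0_flux <- fe$flux_by_order[1, "0"]
  se <- fe$flux_by_order_se[1, "0"]
  expect_lt(abs(n0_flux - expected), 3 * se)

  # same law through the lens ray fan aimed at the exit plane
  scl <- scene(acoustic_profile(1.3333, 0, 1e6),
               medium_optics(5 / 0.03, 0.99, 0.9, 0.03),
               lens_source(0.03, 500e-6, 1e4), detector_spec(20e-6))
  fel <- estimate_flux(scl, 1e5, seed = 7)
  expect_lt(abs(fel$flux_by_order[1, "0"] - 1e4 * exp(-5) *
                  mean(c(1, 1) * T_NORMAL^2)),  # near-normal external rays
            4 * fel$flux_by_order_se[1, "0"] + 0.02 * 1e4 * exp(-5) * T_NORMAL^2)
})

test_that("weight audit closes exactly and orders sum to the total", {
  sc <- table1_scene(mfp = 1)
  fe <- estimate_flux(sc, 2e4, seed = 2, nee = FALSE)
  expect_lt(abs(fe$launched - sum(fe$buckets)) / fe$launched, 1e-9)
  expect_lt(max(abs(rowSums(fe$flux_by_order) - fe$mean_flux)) /
              max(fe$mean_flux, 1e-12), 1e-9)

  # with a tiny event cap the overflow bucket fills but the audit still holds
  fe2 <- estimate_flux(sc, 2e3, seed = 2, nee = FALSE, max_events = 1)
  expect_gt(fe2$buckets[["max_events"]], 0)
  expect_lt(abs(fe2$launched - sum(fe2$buckets)) / fe2$launched, 1e-9)
})

test_that("next-event splitting is unbiased and reduces variance", {
  # transparent: no volume events, so both estimators coincide exactly
  sc0 <- transparent_scene()
  expect_identical(estimate_flux(sc0, 2e3, 1, nee = TRUE)$mean_flux,
                   estimate_flux(sc0, 2e3, 1, nee = FALSE)$mean_flux)

  for (mfp in c(1, 5)) {
    sc <- table1_scene(mfp = mfp)
    n <- if (mfp == 1) 2e4 else 4e4
    fa <- estimate_flux(sc, n, seed = 10 + mfp, nee = TRUE)
    fb <- estimate_flux(sc, 4 * n, seed = 20 + mfp, nee = FALSE)
    dd <- abs(as.numeric(fa$mean_flux - fb$mean_flux))
    cse <- 3 * sqrt(fa$std_error^2 + fb$std_error^2)
    expect_lt(dd, as.numeric(cse))
  }

  # matched photon budget: splitting shrinks the standard error at 5 MFP
  sc5 <- table1_scene(mfp = 5)
  se_nee <- estimate_flux(sc5, 2e4, seed = 31, nee = TRUE)$std_error
  se_plain <- estimate_flux(sc5, 2e4, seed = 31, nee = FALSE)$std_error
  expect_lt(as.numeric(se_nee), as.numeric(se_plain))
})

test_that("combined split estimator matches the closed-form single-scatter flux", {
  # isotropic scatterer on the axis of a transparent, unmodulated slab:
  # expected detector flux from one scattering event is the solid-angle
  # fraction of the disk, Omega / 4pi
  L <- 0.03; r_det <- 5e-3; z0 <- 0.015; g <- 0
  d <- L - z0
  h <- sqrt(d^2 + r_det^2)
  omega_frac <- (1 - d / h) / 2
  p_cone <- 1 / (2 * pi * (1 - d / h))
  cosmax <- d / h
  set.seed(8)
  m <- 4000
  est <- numeric(m)
  for (i in seq_len(m)) {
    # the split half, from the compiled path
    nee <- sonotrace:::cpp_nee_single(1.3333, 0, 2 * pi * 1e6 / 1500, 0, g,
                                      L, 1.3333, r_det, 1, 1e-4,
                                      c(0, 0, z0), c(0, 0, 1), 1,
                                      runif(1), runif(1))
    # the continuation half: isotropic direction, straight line, balance
    dir <- hg_sample_direction(g, c(0, 0, 1), runif(1), runif(1))
    cont <- 0
    if (dir[3] > 0) {
      land <- c(0, 0, z0) + dir * (d / dir[3])
      if (land[1]^2 + land[2]^2 <= r_det^2) {
        p_hg <- hg_pdf(g, dir[3])
        in_cone <- dir[3] >= cosmax
        cont <- p_hg / (p_hg + if (in_cone) p_cone else 0)
      }
    }
    est[i] <- nee$contrib + cont
  }
  se <- sd(est) / sqrt(m)
  expect_lt(abs(mean(est) - omega_frac), max(3 * se, 0.01 * omega_frac))
})

test_that("uniform-phase flux equals the stratified fixed-phase average", {
  sc <- table1_scene(mfp = 0.5, delta_n = 2e-3)
  fu <- estimate_flux(sc, 1.6e4, seed = 40)
  phases <- (seq_len(16) - 0.5) / 16 / 1e6
  fx <- vapply(seq_along(phases), function(i) {
    sci <- sc
    sci$time_mode <- time_spec("fixed", t_fixed_s = phases[i])
    fe <- estimate_flux(sci, 1e3, seed = 40 + i)
    as.numeric(fe$mean_flux)
  }, 0)
  sem <- sd(fx) / sqrt(16)
  comb <- sqrt(as.numeric(fu$std_error)^2 + sem^2)
  expect_lt(abs(as.numeric(fu$mean_flux) - mean(fx)), 3 * comb)
})

test_that("detected flux decreases with extinction and focusing beats no field", {
  sc_on <- table1_scene(mfp = 0, delta_n = focal_delta_n(1e6, 0.03, 1),
                        time_mode = time_spec("fixed", t_fixed_s = 0.25e-6))
  sc_off <- table1_scene(mfp = 0, delta_n = 0)
  f_on <- estimate_flux(sc_on, 1e4, seed = 50)
  f_off <- estimate_flux(sc_off, 1e4, seed = 50)
  expect_gt(as.numeric(f_on$mean_flux), 4 * as.numeric(f_off$mean_flux))

  prev <- Inf; prev_se <- 0
  for (mfp in c(0, 1, 3, 5)) {
    sc <- table1_scene(mfp = mfp, delta_n = 2e-3)
    fe <- estimate_flux(sc, 8e3, seed = 60)
    expect_lt(as.numeric(fe$mean_flux),
              prev + 3 * sqrt(as.numeric(fe$std_error)^2 + prev_se^2))
    prev <- as.numeric(fe$mean_flux); prev_se <- as.numeric(fe$std_error)
  }
})

test_that("irradiance images conserve the plane tally and stay symmetric", {
  sc <- table1_scene(mfp = 1, delta_n = 2e-3)
  kill <- 10 * first_zero_radius(sc$profile)
  grid <- list(nx = 81L, ny = 81L, pitch_m = 2.2 * kill / 81)
  img <- render_irradiance(sc, 5e3, seed = 70, grid = grid, nee = FALSE)
  fe <- attr(img, "flux_estimate")
  tally <- fe$buckets[["detected"]] + fe$buckets[["escaped_exit"]]
  expect_equal(sum(img) * grid$pitch_m^2, tally, tolerance = 1e-9)

  # transparent, field off: nonzero pixels only inside the beam footprint
  sc0 <- transparent_scene(beam_d = 400e-6, det_r = 300e-6, flux = 100)
  g0 <- list(nx = 81L, ny = 81L, pitch_m = 1e-5)
  img0 <- render_irradiance(sc0, 4e3, seed = 71, grid = g0)
  ctr <- (81 + 1) / 2
  xy <- expand.grid(i = 1:81, j = 1:81)
  rr <- sqrt((xy$i - ctr)^2 + (xy$j - ctr)^2) * g0$pitch_m
  outside <- matrix(rr, 81, 81) > 200e-6 + 2 * g0$pitch_m
  expect_true(all(img0[outside] == 0))
  expect_gt(sum(img0[!outside]), 0)

  # azimuthal symmetry of the radially symmetric scene: the detected-light
  # centroid stays within a small fraction of the image's RMS radius
  w <- sum(img)
  ix <- ((seq_len(81)) - ctr) * grid$pitch_m
  cx <- sum(sweep(img, 1, ix, "*")) / w
  cy <- sum(sweep(img, 2, ix, "*")) / w
  rr2 <- outer(ix^2, ix^2, "+")
  rms <- sqrt(sum(img * rr2) / w)
  expect_lt(sqrt(cx^2 + cy^2), 0.05 * rms)

  # quadrant balance within shot-noise-like tolerance
  q <- c(sum(img[1:40, 1:40]), sum(img[42:81, 1:40]),
         sum(img[1:40, 42:81]), sum(img[42:81, 42:81]))
  expect_lt((max(q) - min(q)) / mean(q), 0.2)

  # per-order restriction: the order-0 image is a strict part of the full
  # tally, and in a transparent slab it IS the full tally
  img_n0 <- render_irradiance(sc, 5e3, seed = 70, grid = grid, nee = FALSE,
                              order = 0)
  expect_lt(sum(img_n0), sum(img))
  imgt_all <- render_irradiance(sc0, 4e3, seed = 71, grid = g0)
  imgt_n0 <- render_irradiance(sc0, 4e3, seed = 71, grid = g0, order = 0)
  expect_equal(sum(imgt_n0), sum(imgt_all), tolerance = 1e-12)
})

test_that("deep modulated media confine light at the exit face", {
  # waveguide on at 10 MFP: a confined central peak rises far above the
  # surrounding annulus
  dn <- focal_delta_n(30.52e6, 2.67e-3, 3)
  sc <- bladder_scene(dn)
  core <- first_zero_radius(sc$profile)
  grid <- list(nx = 61L, ny = 61L, pitch_m = 8 * core / 61)
  img <- render_irradiance(sc, 3e4, seed = 80, grid = grid)
  ctr <- (61 + 1) / 2
  xy <- expand.grid(i = 1:61, j = 1:61)
  rr <- matrix(sqrt((xy$i - ctr)^2 + (xy$j - ctr)^2) * grid$pitch_m, 61, 61)
  annulus <- rr > 2.5 * core & rr < 3.5 * core
  expect_gt(max(img), 5 * max(median(img[annulus]), 1e-12))
})
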
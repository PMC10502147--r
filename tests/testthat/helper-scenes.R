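# Scene builders shared across the suite. All fixtures are built in code.

T_NORMAL <- fresnel_transmittance(1, 1.3333, 1)  # air/water, normal incidence

transparent_scene <- function(beam_d = 100e-6, det_r = 100e-6, flux = 1000,
                              f = 1e6) {
  scene(acoustic_profile(1.3333, 0, f), medium_optics(0, length_m = 0.03),
        beam_source(beam_d, flux), detector_spec(det_r))
}

# waveguide on, sigma_t chosen by optical depth in MFP over a 30 mm slab
table1_scene <- function(mfp = 5, delta_n = 2e-3, f = 1e6, det_r = 100e-6,
                         time_mode = time_spec(), albedo = 0.99) {
  scene(acoustic_profile(1.3333, delta_n, f),
        medium_optics(mfp / 0.03, albedo, 0.9, 0.03),
        beam_source(500e-6, 7.5e4), detector_spec(det_r), time_mode)
}

bladder_scene <- function(delta_n, f = 30.52e6, sigma_t = 3750,
                          det_r = c(12e-6, 50e-6),
                          time_mode = time_spec("duty"),
                          source = NULL) {
  prof <- acoustic_profile(1.3333, delta_n, f)
  if (is.null(source)) source <- beam_source(2 * first_zero_radius(prof), 7.5e4)
  scene(prof, medium_optics(sigma_t, 0.992, 0.9, 2.67e-3, n_external = 1.3333),
        source, detector_spec(det_r), time_mode)
}

# deterministic low-discrepancy-ish uniforms for parameterized loops
unit_grid <- function(n) (seq_len(n) - 0.5) / n
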
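# Fast smoke scene: 0.5 MFP, completes in seconds
schema_version = 1
tag = smoke_0p5mfp
n0 = 1.3333
delta_n = 2.0e-3
freq_hz = 1.0e6
v_us_m_s = 1500
sigma_t_per_m = 16.67
albedo = 0.99
g = 0.9
length_m = 0.03
n_external = 1
source = collimated
beam_diameter_m = 5.0e-4
flux_au = 7.5e4
det_radius_m = 1.0e-4
time_mode = uniform
n_photons = 2000
seed = 1
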
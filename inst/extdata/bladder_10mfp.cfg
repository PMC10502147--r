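# Bladder-like slab: 2.67 mm, about 10 MFP (1 TMFP), index-matched faces
schema_version = 1
tag = bladder_10mfp
n0 = 1.3333
delta_n = 1.41e-3
freq_hz = 3.052e7
v_us_m_s = 1500
sigma_t_per_m = 3750
albedo = 0.992
g = 0.9
length_m = 2.67e-3
n_external = 1.3333
source = collimated
beam_diameter_m = 1.88e-5
flux_au = 7.5e4
det_radius_m = 1.2e-5, 5.0e-5
time_mode = duty
duty_fraction = 0.1
n_photons = 10000
seed = 1
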
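# Turbid 30 mm slab at 5 mean free paths
schema_version = 1
tag = table1_5mfp
n0 = 1.3333
freq_hz = 1.0e6
v_us_m_s = 1500
sigma_t_per_m = 166.7
albedo = 0.99
g = 0.9
length_m = 0.03
n_external = 1
source = collimated
beam_diameter_m = 5.0e-4
flux_au = 7.5e4
det_radius_m = 1.0e-4
time_mode = peak
n_photons = 10000
seed = 1
f_list_hz = 3.0e5, 6.0e5, 9.0e5, 1.2e6, 1.5e6
delta_n_list = 1.0e-4, 3.2e-4, 1.0e-3, 3.2e-3, 1.0e-2, 3.2e-2
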
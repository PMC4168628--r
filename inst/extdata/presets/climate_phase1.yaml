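# Rainy-season (first round) indoor-storage climate preset, calibrated so a
# default 23-site trial reproduces the first round's reported conditions.
phase: 1
daily_mean: 26.5
diurnal_amplitude: 1.7
site_spread_sd: 0.8
noise_sd: 0.45
noise_autocorr: 0.9
interval_min: 10
initial_dose_mean: 0.651
initial_dose_sd: 0.05
no_ceiling_sd_mult: 1.5
start_date: 2011-07-25
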
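# Dry-season (second round) indoor-storage climate preset.
phase: 2
daily_mean: 30.0
diurnal_amplitude: 2.3
site_spread_sd: 1.3
noise_sd: 0.45
noise_autocorr: 0.9
interval_min: 23
initial_dose_mean: 0.55
initial_dose_sd: 0.05
no_ceiling_sd_mult: 1.5
start_date: 2012-02-01
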
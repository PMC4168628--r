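# Six-stage refrigerated shipment, batch 2 (November shipment): 13.4 days
# total, overall mean kinetic temperature near 12.1 C, hotter road leg.
stages:
  - {name: manufacturer to Buenos Aires, duration_days: 0.5, temp_C: 6.0, temp_sd: 1.0}
  - {name: en route to South Africa, duration_days: 1.5, temp_C: 5.0, temp_sd: 1.0}
  - {name: en route to Ghana, duration_days: 1.0, temp_C: 6.0, temp_sd: 1.0}
  - {name: customs and storage in Accra, duration_days: 0.70, temp_C: 28.0, temp_sd: 1.5}
  - {name: road transport to KHRC, duration_days: 0.35, temp_C: 33.0, temp_sd: 1.5}
  - {name: arrival handling at KHRC, duration_days: 9.35, temp_C: 5.0, temp_sd: 1.0}
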
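# Six-stage refrigerated shipment, batch 1 (August shipment): 8.6 days
# total, overall mean kinetic temperature near 10.3 C.
stages:
  - {name: manufacturer to Buenos Aires, duration_days: 0.5, temp_C: 6.0, temp_sd: 1.0}
  - {name: en route to South Africa, duration_days: 1.5, temp_C: 5.0, temp_sd: 1.0}
  - {name: en route to Ghana, duration_days: 1.0, temp_C: 6.0, temp_sd: 1.0}
  - {name: customs and storage in Accra, duration_days: 0.42, temp_C: 27.0, temp_sd: 1.5}
  - {name: road transport to KHRC, duration_days: 0.14, temp_C: 30.0, temp_sd: 1.5}
  - {name: arrival handling at KHRC, duration_days: 5.04, temp_C: 5.0, temp_sd: 1.0}
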
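survival:
  dfs_active:
    family: loglogistic
    shape: 1.63351
    scale: 112.73457
  dfs_control:
    family: gengamma
    mu: 2.88767
    sigma: 1.45261
    Q: -1.3076
  os_active:
    family: gengamma
    mu: 4.36038
    sigma: 1.2675
    Q: -3.13596
  os_control:
    family: lognormal
    meanlog: 4.83614
    sdlog: 1.01581
utilities:
  dfs: 0.83
  recurrence: 0.74
  death: 0.0
costs:
  osimertinib_80mg_day: 566.64
  pemetrexed_10mg: 7.51
  cisplatin_10mg: 3.17
  administration_cycle: 155.09
  imaging_event: 249.48
  laboratory_event: 340.2
  terminal_care: 10187.64
  physician_visit: 160.2
  bsc_cycle: 481.57
patient:
  body_surface_area: 1.82
  start_age: 63.0
treatment:
  subsequent_fraction_active: 0.671
  subsequent_fraction_control: 0.663
  pemetrexed_dose_mg_m2: 500.0
  cisplatin_dose_mg_m2: 75.0
  induction_cycles: 4.0
  maintenance_cap_cycles: '.inf'
discount:
  annual_rate: 0.03
wtp: 150000.0
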
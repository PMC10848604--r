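# Five-year anaesthesiology residency, Singapore 2020 circuit-breaker
# calibration: starting batch sizes per training year and the per-stage
# average length of stay (years) observed under movement restrictions.
stages:
  - {name: R1, nominal_duration: 1.0, pandemic_alos: 1.22}
  - {name: R2, nominal_duration: 1.0, pandemic_alos: 1.08}
  - {name: R3, nominal_duration: 1.0, pandemic_alos: 1.23}
  - {name: SR1, nominal_duration: 1.0, pandemic_alos: 1.32}
  - {name: SR2, nominal_duration: 1.0, pandemic_alos: 1.23}
initial_stocks: [12, 10, 10, 18, 12]
intake_rate: 12
scenario:
  onset: 0
  duration_T: 1
  baseline_impact: 1
simulation:
  horizon: 12
  dt: 0.25
  flow: conveyor
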
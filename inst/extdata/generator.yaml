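# Synthetic resident-record generator: 2020 circuit-breaker cohort with
# per-stage mean delays (months) implied by ALOS 1.22/1.08/1.23/1.32/1.23.
n_residents_per_stage: 500
stage_names: [R1, R2, R3, SR1, SR2]
mean_delay_months: [2.64, 0.96, 2.76, 3.84, 2.76]
delay_dispersion: 1
pandemic_window: ["2020-04-07", "2020-06-01"]
entry_date: "2019-07-01"
seed: 1
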
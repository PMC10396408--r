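# Desk-scale demo scenario for the synthetic birth registry.
# Keys mirror leaverdd::generator_params(); unspecified values keep the
# study-condition defaults (1981-1987 window, take-up 0.822, planted
# incidence profile, censoring rates, admin cut-off 2017-12-31).
mean_births_per_day: 8
seed: 20280326
leave_params:
  noise_sd: 20
births_per_mother:
  "1": 0.75
  "2": 0.23
  "3": 0.02
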
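# Example run configuration: Congo base case, deterministic cohort mode.
country: Congo
mode: cohort
discount_rate: 0.03
params:
  hazard_ratio: 0.59
  effect_duration: 5
costs:
  accrual_mode: per_cycle
  treatment_cost_mode: spread
output_dir: congo-base-case
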
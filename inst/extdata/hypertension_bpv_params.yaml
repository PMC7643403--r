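conventions:
  reward_timing: start
  drug_cost_states: alive
  sample_mode: direct
parameters:
  n_cycles:
    base: 20.0
    low: 20.0
    high: 20.0
    family: fixed
    units: cycles
  cycle_length_years:
    base: 1.0
    low: 1.0
    high: 1.0
    family: fixed
    units: years
  discount_rate:
    base: 0.05
    low: 0.01
    high: 0.08
    family: fixed
    units: fraction/year
  wtp_threshold:
    base: 9764.950000000000728
    low: 9764.950000000000728
    high: 9764.950000000000728
    family: fixed
    units: USD/QALY
  exchange_rate_rmb_per_usd:
    base: 6.62
    low: 6.62
    high: 6.62
    family: fixed
    units: RMB/USD
  baseline_age:
    base: 67.5
    low: 60.0
    high: 75.0
    family: fixed
    units: years
  utility_well:
    base: 0.98
    low: 0.882
    high: 1.0
    family: beta
    units: utility
  utility_stroke:
    base: 0.5
    low: 0.45
    high: 0.55
    family: beta
    units: utility
  utility_post_stroke:
    base: 0.63
    low: 0.567
    high: 0.693
    family: beta
    units: utility
  utility_mi:
    base: 0.7
    low: 0.63
    high: 0.77
    family: beta
    units: utility
  utility_post_mi:
    base: 0.8
    low: 0.72
    high: 0.88
    family: beta
    units: utility
  cost_stroke:
    base: 1843.8599999999999
    low: 1659.559999999999945
    high: 2028.349999999999909
    family: gamma
    units: USD/year
  cost_post_stroke:
    base: 1692.150000000000091
    low: 1522.930000000000064
    high: 1861.3599999999999
    family: gamma
    units: USD/year
  cost_mi:
    base: 2538.010000000000218
    low: 2284.260000000000218
    high: 2791.869999999999891
    family: gamma
    units: USD/year
  cost_post_mi:
    base: 2041.839999999999918
    low: 1837.660000000000082
    high: 2246.0300000000002
    family: gamma
    units: USD/year
  drug_cost_nifedipine:
    base: 16.309999999999999
    low: 14.68
    high: 17.949999999999999
    family: gamma
    units: USD/year
  drug_cost_combined:
    base: 102.420000000000002
    low: 92.180000000000007
    high: 112.659999999999997
    family: gamma
    units: USD/year
  p_well_stroke_nifedipine:
    base: 0.0046
    low: 0.0041
    high: 0.0051
    family: beta
    horizon_years: 1.0
    units: probability
  p_well_stroke_combined:
    base: 0.00102
    low: 0.0009
    high: 0.0011
    family: beta
    horizon_years: 1.0
    units: probability
  p_well_mi_nifedipine:
    base: 0.00199
    low: 0.0018
    high: 0.0022
    family: beta
    horizon_years: 1.0
    units: probability
  p_well_mi_combined:
    base: 0.00193
    low: 0.0017
    high: 0.0021
    family: beta
    horizon_years: 1.0
    units: probability
  p_stroke_stroke:
    base: 0.417
    low: 0.3753
    high: 0.4587
    family: beta
    horizon_years: 5.0
    units: probability
  p_stroke_death:
    base: 0.1303
    low: 0.1172
    high: 0.1433
    family: beta
    horizon_years: 5.0
    units: probability
  p_post_stroke_death:
    base: 0.256
    low: 0.2304
    high: 0.2816
    family: beta
    horizon_years: 4.0
    units: probability
  p_mi_mi:
    base: 0.125
    low: 0.1125
    high: 0.1375
    family: beta
    horizon_years: 1.0
    units: probability
  p_mi_death:
    base: 0.097
    low: 0.0873
    high: 0.1067
    family: beta
    horizon_years: 1.0
    units: probability
  p_post_mi_death:
    base: 0.061
    low: 0.0549
    high: 0.0671
    family: beta
    horizon_years: 1.0
    units: probability
  bpv_delta_sd_nifedipine:
    base: 1.87
    low: 1.683
    high: 2.057
    family: gamma
    units: mmHg
  bpv_delta_sd_combined:
    base: 2.99
    low: 2.691
    high: 3.289
    family: gamma
    units: mmHg
  bpv_delta_cv_nifedipine:
    base: 0.0
    low: 0.0
    high: 0.0
    family: fixed
    units: fraction
  bpv_delta_cv_combined:
    base: 0.01
    low: 0.009
    high: 0.011
    family: beta
    units: fraction
  stroke_baseline_rate:
    base: 0.0569
    low: 0.05121
    high: 0.06259
    family: beta
    horizon_years: 5.5
    units: probability
  mi_baseline_rate:
    base: 0.0109
    low: 0.00981
    high: 0.01199
    family: beta
    horizon_years: 5.5
    units: probability
  stroke_increment_per_sd:
    base: 0.0032
    low: 0.003
    high: 0.004
    family: beta
    units: probability/mmHg
  mi_increment_per_cv:
    base: 0.00811
    low: 0.0073
    high: 0.0089
    family: beta
    units: probability/CV
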
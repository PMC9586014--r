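model:
  cohort_size: 13250.0
  cycle_length_years: 1.0
  discount_rate_costs: 0.03
  discount_rate_effects: 0.03
  gdp_per_capita: 19866.0
  half_cycle_correction: yes
  horizon_cycles: 25
  other_cause_mortality: 0.0175
  post_treatment_progression: no
  tunnel_years: 5
  wtp_threshold: 59598.0
initial:
  adenoma: 0.804
  advanced_adenoma: 0.0562
  crc1: 0.0578
  crc2: 0.0361
  crc3: 0.0371
  crc4: 0.0088
transitions:
  adenoma_to_advanced: 0.02
  advanced_to_crc1: 0.0326
  crc_followup_mortality:
    crc1: 0.0218
    crc2: 0.0458
    crc3: 0.0994
    crc4: 0.2028
  crc1_diagnosis: 0.2
  crc1_to_crc2: 0.24
  crc2_diagnosis: 0.2
  crc2_to_crc3: 0.36
  crc3_diagnosis: 0.65
  crc3_to_crc4: 0.175
  crc4_diagnosis: 1.0
  normal_to_adenoma: 0.016
costs:
  adenoma_treatment: 0.0
  colonoscopy_unit: 158.72999999999999
  exchange_rate_rmb_per_usd: 6.3743
  n_colonoscopies: 82729.0
  n_diagnosed: 13250.0
  screening_component_per_diagnosed: 280.834264150943397
  screening_oneoff_per_diagnosed: .na
  treatment:
    advanced_adenoma: 1108.819999999999936
    crc1: 8566.6299999999992
    crc2: 10554.700000000000728
    crc3: 13395.729999999999563
    crc4: 11177.510000000000218
utilities:
  adenoma: 0.871
  adenoma_followup: 0.871
  advanced_adenoma: 0.827
  advanced_adenoma_followup: 0.827
  crc:
    crc1: 0.829
    crc2: 0.86
    crc3: 0.814
    crc4: 0.738
  normal: 1.0
  undiagnosed_full_health: yes
registry:
  cost_dispersion: 0.6
  cost_medians:
    advanced_adenoma: 1108.819999999999936
    crc1: 8566.6299999999992
    crc2: 10554.700000000000728
    crc3: 13395.729999999999563
    crc4: 11177.510000000000218
  diagnosis_mix:
    adenoma: 0.804
    advanced_adenoma: 0.05622641509434
    crc1: 0.057811320754717
    crc2: 0.036075471698113
    crc3: 0.037132075471698
    crc4: 0.008754716981132
  followup_horizon: 5
  missing_cost_fraction: 0.0
  n_participants: 10000
  other_cause_mortality: 0.0175
  outlier_fraction: 0.02
  outlier_multiplier_range:
  - 10.0
  - 30.0
  p_colonoscopy: 0.291005216559322
  p_diagnosis: 0.160161491133702
  p_positive: 0.258994621265679
  seed: 1
  survival_5yr:
    crc1: 0.8957
    crc2: 0.7912
    crc3: 0.5924
    crc4: 0.322
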
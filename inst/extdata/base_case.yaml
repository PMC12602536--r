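model:
  horizon_years: 40.0
  cycle_schedule:
  - 0.25
  - 0.25
  - 0.25
  - 0.25
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  discount_rate_costs: 0.035
  discount_rate_outcomes: 0.035
  wtp_thresholds:
  - 27117.0
  - 30000.0
  - 34000.0
  max_treatment_years: 2.0
  stopping_rule_week: 12.0
  stopping_rule_threshold: 0.05
  stopping_rule_enabled: yes
  catch_up_years: 3.0
  natural_weight_gain: 0.47
  weight_gain_units: kg
  payer_share: 0.75
  post_treatment_pathway: diet_exercise
  joint_acquisition: no
  discount_timing: mid
  baseline_utility_mode: fixed
  seed: 1
cohort:
  age: 48.600000000000001
  bmi: 41.5
  height: 1.7
  female_fraction: 0.736
  sbp: 128.400000000000006
  tchol: 186.0
  hdl: 50.899999999999999
  trig: 128.199999999999989
  smoker_fraction: 0.452
  smoke_previous_fraction: 0.0
  prediabetes_fraction: 0.488
  t2d_fraction: 0.108
  normoglycemic_fraction: 0.404
  cvd_history_fraction: 0.05
  on_lipid_lowering: 0.314
  on_antihypertensive: 0.447
  hba1c_t2d: 0.075
  t2d_duration: 6.0
arms:
  semaglutide:
    non_responder_rate: 0.246
    ae_discontinuation_rate: 0.035
    gi_event_rate: 0.02
    hypo_nonsevere_rate: 0.01
    hypo_severe_rate: 0.002
    estimand: treatment_policy
    timelines:
      treatment_policy:
        weeks:
        - 0.0
        - 12.0
        - 20.0
        - 36.0
        - 52.0
        - 68.0
        - 104.0
        change:
        - 0.0
        - -0.069
        - -0.098
        - -0.135
        - -0.152
        - -0.159
        - -0.159
      trial_product:
        weeks:
        - 0.0
        - 12.0
        - 20.0
        - 36.0
        - 52.0
        - 68.0
        - 104.0
        change:
        - 0.0
        - -0.075
        - -0.107
        - -0.148
        - -0.166
        - -0.173
        - -0.173
    titration:
      labels:
      - sema_025
      - sema_05
      - sema_1
      - sema_17
      weeks:
      - 4.0
      - 4.0
      - 4.0
      - 4.0
    maintenance_label: sema_24
    pack_days: 7.0
  liraglutide:
    non_responder_rate: 0.386
    ae_discontinuation_rate: 0.03
    gi_event_rate: 0.015
    hypo_nonsevere_rate: 0.008
    hypo_severe_rate: 0.002
    estimand: treatment_policy
    timelines:
      treatment_policy:
        weeks:
        - 0.0
        - 12.0
        - 20.0
        - 36.0
        - 52.0
        - 68.0
        - 104.0
        change:
        - 0.0
        - -0.047
        - -0.055
        - -0.062
        - -0.064
        - -0.064
        - -0.064
      trial_product:
        weeks:
        - 0.0
        - 12.0
        - 20.0
        - 36.0
        - 52.0
        - 68.0
        - 104.0
        change:
        - 0.0
        - -0.051
        - -0.06
        - -0.068
        - -0.07
        - -0.07
        - -0.07
    titration:
      labels: []
      weeks: []
    maintenance_label: lira_3
    pack_days: 7.0
  diet_exercise:
    non_responder_rate: 0.0
    ae_discontinuation_rate: 0.0
    gi_event_rate: 0.0
    hypo_nonsevere_rate: 0.0
    hypo_severe_rate: 0.0
    estimand: treatment_policy
    timelines:
      treatment_policy:
        weeks:
        - 0.0
        - 12.0
        - 20.0
        - 36.0
        - 52.0
        - 68.0
        - 104.0
        change:
        - 0.0
        - -0.01
        - -0.014
        - -0.018
        - -0.019
        - -0.019
        - -0.019
      trial_product:
        weeks:
        - 0.0
        - 12.0
        - 20.0
        - 36.0
        - 52.0
        - 68.0
        - 104.0
        change:
        - 0.0
        - -0.01
        - -0.014
        - -0.018
        - -0.019
        - -0.019
        - -0.019
    titration:
      labels: []
      weeks: []
    maintenance_label: .na.character
    pack_days: .na.real
costs:
  drug_prices:
    sema_025: 123.620000000000005
    sema_05: 123.620000000000005
    sema_1: 123.620000000000005
    sema_17: 167.930000000000007
    sema_24: 190.210000000000008
    lira_3: 162.97999999999999
  consumables_annual: 33.579999999999998
  monitoring_annual: 124.879999999999995
  noncomplication_extra: 0.0
  state_costs:
    T2D: 1125.910000000000082
    hypertension: 593.840000000000032
    CKD: 811.460000000000036
    OSA: 1688.400000000000091
    dyslipidemia: 924.210000000000036
    asthma: 796.580000000000041
    ACS: 1819.309999999999945
  event_costs:
    mi_fatal: 4166.0
    mi_nonfatal: 2724.0
    angina_fatal: 940.0
    angina_nonfatal: 424.0
    stroke_fatal: 2475.0
    stroke_nonfatal: 1625.0
    tia: 806.5
    gi_major: 654.5
    hypo_nonsevere: 287.769999999999982
    hypo_severe: 805.769999999999982
  cpi_reference_year: 2025.0
utilities:
  baseline_fixed: 0.78
  baseline_fixed_se: 0.023
  regression:
    intercept: 0.942975
    age: -0.0005414
    heart_circ: -0.0742818
    hypertension: -0.0097531
    smoke_current: 0.0039044
    smoke_previous: -0.0081972
    bmi: 0.0065954
    bmi2: -0.0002476
    bmi3: 1.75e-06
    prediabetes: -0.0031133
  state_disutilities:
    T2D: -0.029
    ACS: -0.037
    OSA: -0.013
    asthma: -0.021
    dyslipidemia: -0.037
    hypertension: -0.014
    CKD: -0.049
  state_disutility_se:
    T2D: 0.006
    ACS: 0.008
    OSA: 0.004
    asthma: 0.005
    dyslipidemia: 0.004
    hypertension: 0.003
    CKD: 0.002
  event_disutilities:
    acs: -0.129
    stroke: -0.181
    tia: -0.033
    gi_major: -0.001
    hypo_severe: -0.015
    hypo_nonsevere: -0.0062
  event_disutility_se:
    acs: 0.032
    stroke: 0.045
    tia: 0.008
    gi_major: 0.0002
    hypo_severe: 0.002
    hypo_nonsevere: 0.004
risks:
  conditions:
    T2D:
      base_annual_rate: 0.006
      reference_bmi: 30.0
      log_rr_per_bmi_unit: 0.086177696241052
      covariate_multipliers:
        prediabetes_fraction: 2.5
    ACS:
      base_annual_rate: 0.003
      reference_bmi: 30.0
      log_rr_per_bmi_unit: 0.039220713153281
      covariate_multipliers:
        smoker_fraction: 1.6
    hypertension:
      base_annual_rate: 0.02
      reference_bmi: 30.0
      log_rr_per_bmi_unit: 0.058268908123976
      covariate_multipliers: []
    dyslipidemia:
      base_annual_rate: 0.02
      reference_bmi: 30.0
      log_rr_per_bmi_unit: 0.048790164169432
      covariate_multipliers: []
    asthma:
      base_annual_rate: 0.0035
      reference_bmi: 30.0
      log_rr_per_bmi_unit: 0.029558802241544
      covariate_multipliers: []
    CKD:
      base_annual_rate: 0.004
      reference_bmi: 30.0
      log_rr_per_bmi_unit: 0.048790164169432
      covariate_multipliers: []
    OSA:
      base_annual_rate: 0.008
      reference_bmi: 30.0
      log_rr_per_bmi_unit: 0.086177696241052
      covariate_multipliers: []
  acute_events:
    stroke:
      base_annual_rate: 0.002
      reference_bmi: 30.0
      log_rr_per_bmi_unit: 0.039220713153281
      covariate_multipliers: []
      fatal_fraction: 0.15
    tia:
      base_annual_rate: 0.001
      reference_bmi: 30.0
      log_rr_per_bmi_unit: 0.039220713153281
      covariate_multipliers: []
  acs_event:
    mi_share: 0.6
    fatal_fraction: 0.05
mortality:
  gompertz:
    makeham: 0.0002
    b_female: 1.9e-05
    b_male: 3.2e-05
    theta: 0.095
    age_min: 18.0
    age_max: 110.0
  cause_fractions:
    ACS: 0.18
    T2D: 0.05
    CKD: 0.04
    asthma: 0.02
    hypertension: 0.04
    dyslipidemia: 0.01
    OSA: 0.01
  bmi_hr_enabled: yes
  bmi_hr_bands:
    breaks:
    - 18.5
    - 25.0
    - 30.0
    - 35.0
    - 40.0
    hr:
    - 1.1
    - 1.0
    - 1.1
    - 1.3
    - 1.6
    - 2.0
  state_excess_multipliers:
    T2D: 1.6
    ACS: 2.0
    CKD: 1.8
    hypertension: 1.2
    dyslipidemia: 1.1
    asthma: 1.1
    OSA: 1.3
psa:
  n_iterations: 1000.0
  default_se_fraction: 0.2
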
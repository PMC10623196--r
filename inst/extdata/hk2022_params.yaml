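# Baseline Hong Kong 2022 parameter set: 13 myopia-control strategies.
# Money in HK$ per year; SER effects in D/yr (benefit-positive as stored);
# AL effects in mm/yr raw sign (negative = slowed elongation).
# Adverse-event unit costs are 0: the published annual totals bundle them.
model:
  start_distribution: {low: 0.70, moderate: 0.25, high: 0.05}
  horizon_years: 5
  accrual_events: 6
  discount_rate_costs: 0.03
  discount_rate_effects: 0.0
  exchange_rate: 7.85
  reference_strategy: SVLs
  reference_annual_change: 0.81
strategies:
  - name: SVLs
    modality: spectacle
    annual_cost: 5888
    cost_range: [3234, 10158]
    cost_distribution: gamma
    ser_effect: -0.81
    ser_ci: [-0.91, -0.71]
    al_effect_raw: 0.41
    al_ci_raw: [0.09, 0.46]
    effect_distribution: normal
  - name: BSLs
    modality: spectacle
    annual_cost: 8062
    cost_range: [4318, 12748]
    cost_distribution: gamma
    ser_effect: -0.07
    ser_ci: [-0.38, 0.23]
    al_effect_raw: -0.07
    al_ci_raw: [-0.50, 0.38]
    effect_distribution: normal
  - name: DIMS
    modality: spectacle
    annual_cost: 10527
    cost_range: [7214, 13149]
    cost_distribution: gamma
    ser_effect: 0.28
    ser_ci: [-0.24, 0.80]
    al_effect_raw: -0.16
    al_ci_raw: [-0.78, 0.46]
    effect_distribution: normal
  - name: PALs
    modality: spectacle
    annual_cost: 11799
    cost_range: [4851, 12913]
    cost_distribution: gamma
    ser_effect: 0.13
    ser_ci: [-0.07, 0.33]
    al_effect_raw: 0.15
    al_ci_raw: [-0.13, 0.44]
    effect_distribution: normal
  - name: HALs
    modality: spectacle
    annual_cost: 9907
    cost_range: [6272, 14648]
    cost_distribution: gamma
    ser_effect: 0.34
    ser_ci: [-0.79, 1.50]
    al_effect_raw: -0.17
    al_ci_raw: [-0.94, 0.61]
    effect_distribution: normal
  - name: "Atropine eye drops, 0.05%"
    modality: drop
    annual_cost: 8415
    cost_range: [5055, 13376]
    cost_distribution: gamma
    ser_effect: 0.57
    ser_ci: [0.28, 0.86]
    al_effect_raw: -0.30
    al_ci_raw: [-0.65, 0.05]
    effect_distribution: normal
    adverse_events:
      - {event: photophobia, probability: 0.08, unit_cost: 0}
      - {event: allergic_conjunctivitis, probability: 0.03, unit_cost: 0}
  - name: "Atropine eye drops, 0.01%"
    modality: drop
    annual_cost: 8439
    cost_range: [5087, 13321]
    cost_distribution: gamma
    ser_effect: 0.33
    ser_ci: [0.15, 0.52]
    al_effect_raw: -0.17
    al_ci_raw: [-0.38, 0.04]
    effect_distribution: normal
    adverse_events:
      - {event: photophobia, probability: 0.08, unit_cost: 0}
      - {event: allergic_conjunctivitis, probability: 0.03, unit_cost: 0}
  - name: "Daily disposable CLs"
    modality: contact_lens
    annual_cost: 15064
    cost_range: [8808, 17772]
    cost_distribution: gamma
    ser_effect: 0.25
    ser_ci: [0.07, 0.43]
    al_effect_raw: -0.12
    al_ci_raw: [-0.25, 0.01]
    effect_distribution: normal
    adverse_events:
      - {event: microbial_keratitis, probability: 0.0003, unit_cost: 0}
      - {event: corneal_infiltrate, probability: 0.004, unit_cost: 0}
      - {event: ocular_allergies, probability: 0.14, unit_cost: 0}
      - {event: hordeolum, probability: 0.07, unit_cost: 0}
      - {event: corneal_staining, probability: 0.28, unit_cost: 0}
  - name: MSCLs
    modality: contact_lens
    annual_cost: 14099
    cost_range: [7936, 16721]
    cost_distribution: gamma
    ser_effect: 0.26
    ser_ci: [-0.25, 0.77]
    al_effect_raw: -0.07
    al_ci_raw: [-0.69, 0.56]
    effect_distribution: normal
    adverse_events:
      - {event: microbial_keratitis, probability: 0.0003, unit_cost: 0}
      - {event: corneal_infiltrate, probability: 0.004, unit_cost: 0}
      - {event: ocular_allergies, probability: 0.14, unit_cost: 0}
      - {event: hordeolum, probability: 0.07, unit_cost: 0}
      - {event: corneal_staining, probability: 0.28, unit_cost: 0}
  - name: RGPCLs
    modality: contact_lens
    annual_cost: 12261
    cost_range: [6288, 14695]
    cost_distribution: gamma
    ser_effect: 0.30
    ser_ci: [-0.01, 0.62]
    al_effect_raw: -0.05
    al_ci_raw: [-0.42, 0.31]
    effect_distribution: normal
    adverse_events:
      - {event: microbial_keratitis, probability: 0.0003, unit_cost: 0}
      - {event: corneal_infiltrate, probability: 0.004, unit_cost: 0}
      - {event: ocular_allergies, probability: 0.14, unit_cost: 0}
      - {event: hordeolum, probability: 0.07, unit_cost: 0}
      - {event: corneal_staining, probability: 0.28, unit_cost: 0}
  - name: Orthokeratology
    modality: contact_lens
    annual_cost: 19013
    cost_range: [15535, 21093]
    cost_distribution: gamma
    ser_effect: .na
    ser_ci: [.na, .na]
    al_effect_raw: -0.36
    al_ci_raw: [-0.53, -0.20]
    effect_distribution: normal
    adverse_events:
      - {event: microbial_keratitis, probability: 0.0003, unit_cost: 0}
      - {event: corneal_infiltrate, probability: 0.004, unit_cost: 0}
      - {event: ocular_allergies, probability: 0.14, unit_cost: 0}
      - {event: hordeolum, probability: 0.07, unit_cost: 0}
      - {event: corneal_staining, probability: 0.28, unit_cost: 0}
  - name: Outdoor
    modality: behavior
    annual_cost: 5888
    cost_range: [0, 10158]
    cost_distribution: gamma
    ser_effect: 0.16
    ser_ci: [-0.01, 0.35]
    al_effect_raw: -0.10
    al_ci_raw: [-0.35, 0.15]
    effect_distribution: normal
  - name: "Red light therapy"
    modality: light_therapy
    annual_cost: 16147
    cost_range: [12921, 19374]
    cost_distribution: gamma
    ser_effect: 0.59
    ser_ci: [0.06, 1.10]
    al_effect_raw: -0.25
    al_ci_raw: [-0.86, 0.39]
    effect_distribution: normal
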
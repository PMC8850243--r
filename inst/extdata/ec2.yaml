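# Worked example EC2: a benzopyrone with mild non-specific toxicity
# (coumarin-like), assessed for drum filling and household cleaning.
# Screening-step doses are synthetic representative values inside the
# published Category A; the refined ranges are as published.
name: EC2
description: >-
  Benzopyrone with mild non-specific toxicity (coumarin-like); two
  long-term uses taken through tier-2 in vitro + IVIVE hazard assessment
  with stepwise exposure refinement; conventional hazard data carried for
  comparison.
dossier:
  schema_version: 1
  substance_id: EC2
  name: example chemical 2 (benzopyrone, coumarin-like)
  ttc:
    genotoxic_alert: true
    op_or_carbamate: false
    cramer_class: unknown
    in_domain: true
  pod_records:
  - endpoint: carcinogenicity
    pod_type: NOEL
    value: [6.0, 60.0]
    units: uM
    tier: tier2_invitro
    ivive:
      mode: fixed_factor
      factor: 6.0
    study_note: >-
      Driving in vitro PoD range 6-60 uM (CYP450 induction pathways;
      liver hypertrophy/hyperplasia, possible hepatocarcinogenicity at
      high doses). Fixed conversion factor back-calculated from the
      published pair 6-60 uM -> 36-360 mg/kg (fixture data, not a kinetic
      model).
  - endpoint: carcinogenicity
    pod_type: NOEL
    value: [16.0, 42.0]
    units: mg/kg/day
    tier: conventional
    study_note: >-
      Two-year rat study; mild non-specific toxicity with liver
      enlargement, hepatocarcinogenicity at high doses, NOEL 16-42 mg/kg.
  overrides: []
  dnel_overrides: []
scenarios:
  schema_version: 1
  duration: long_term
  plan:
  - exposure_step: tier1_screening
    hazard_tier: tier2_invitro
  - exposure_step: tier1_refined
    hazard_tier: tier2_invitro
  - exposure_step: tier2_higher
    hazard_tier: tier2_invitro
  scenarios:
  - scenario_id: drum_filling
    route: dermal
    population: industrial workers
    doses:
      tier1_screening:
        value: 15.0
        units: mg/kg/day
      tier1_refined:
        value: [0.5, 1.45]
        units: mg/kg/day
      tier2_higher:
        value: [0.5, 2.1]
        units: mg/kg/day
  - scenario_id: household_cleaning
    route: dermal
    population: consumers
    doses:
      tier1_screening:
        value: 12.0
        units: mg/kg/day
      tier1_refined:
        value: 12.0
        units: mg/kg/day
      tier2_higher:
        value: [0.09, 3.2]
        units: mg/kg/day
# The tier1_screening doses (and the unchanged household tier1_refined
# dose) are synthetic representative values inside the published Category
# A; the drum-filling refined range 0.5-1.45, the drum-filling higher-tier
# range 0.5-2.1 and the household higher-tier range 0.09-3.2 mg/kg/day are
# as published.
expected:
  display_sigfigs: 2
  dnel:
    tier2_invitro: [0.36, 3.6]
    conventional: [0.16, 0.42]
  dnel_display:
    tier2_invitro: "0.36-3.6"
    conventional: "0.16-0.42"
  ivive:
    conc_um: [6.0, 60.0]
    factor: 6.0
    in_vivo_pod: [36.0, 360.0]
  categories:
    carcinogenicity:
      tier2_invitro: 2
      conventional: 2
  trajectory:
    drum_filling:
      exposure_categories: [A, B, B]
      colours: [red, amber, amber]
      verdicts: [unacceptable, borderline, borderline]
      recommendations: [refine_exposure, refine_exposure, escalate_hazard_tier]
      terminal: borderline
    household_cleaning:
      exposure_categories: [A, A, B]
      colours: [red, red, amber]
      verdicts: [unacceptable, unacceptable, borderline]
      recommendations: [refine_exposure, refine_exposure, escalate_hazard_tier]
      terminal: borderline
  animals_used:
    tier2_invitro: 0
    conventional: 1000
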
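# Worked example EC1: an anti-androgenic chemical with a potent specific
# mode of action (vinclozolin-like), assessed for three long-term uses.
# Published values are carried verbatim; doses marked "synthetic" in their
# notes are representative values inside the published category, which is
# all that was printed.
name: EC1
description: >-
  Potent anti-androgen (vinclozolin-like); three long-term uses taken
  through tier-2 in vitro, tier-3 targeted in vivo and conventional hazard
  assessment.
dossier:
  schema_version: 1
  substance_id: EC1
  name: example chemical 1 (anti-androgenic, vinclozolin-like)
  ttc:
    genotoxic_alert: false
    op_or_carbamate: false
    cramer_class: III
    in_domain: true
  pod_records:
  - endpoint: reproductive
    pod_type: NOEL
    value: 0.6
    units: mg/kg/day
    tier: tier2_invitro
    study_note: >-
      Androgen receptor blocker; LOEL 2, NOEL 0.6 mg/kg from in vitro
      assays and IVIVE (converted dose stored directly; no concentration
      was published).
  - endpoint: stot_re
    pod_type: NOEL
    value: 2
    units: mg/kg/day
    tier: tier2_invitro
    study_note: >-
      Mitochondrial toxicity; LOEL 6, NOEL 2 mg/kg from in vitro assays
      and IVIVE.
  - endpoint: carcinogenicity
    pod_type: NOEL
    value: 2
    units: mg/kg/day
    tier: tier2_invitro
    study_note: >-
      CYP induction, liver enlargement / potential carcinogenicity; LOEL
      6, NOEL 2 mg/kg from in vitro assays and IVIVE.
  - endpoint: carcinogenicity
    pod_type: NOEL
    value: 2
    units: mg/kg/day
    tier: tier2_invitro
    study_note: >-
      PPAR activation, liver enlargement / peroxisomes; LOEL 6, NOEL 2
      mg/kg from in vitro assays and IVIVE.
  - endpoint: reproductive
    pod_type: NOEL
    value: 25
    units: mg/kg/day
    tier: tier3_targeted_invivo
    study_note: >-
      Hershberger assay; anti-androgenic effects with NOEL 25 mg/kg.
      Multigeneration NOEL predicted equal by AOP read-across.
  - endpoint: stot_re
    pod_type: NOAEL
    value: 4
    units: mg/kg/day
    tier: tier3_targeted_invivo
    study_note: >-
      Rat 90-day study; liver, adrenal and Leydig cell hypertrophy, NOAEL
      4 mg/kg/day.
  - endpoint: carcinogenicity
    pod_type: NOAEL
    value: 4
    units: mg/kg/day
    tier: tier3_targeted_invivo
    study_note: >-
      CYP induction and anti-androgenicity predicting liver and Leydig
      cell tumours; potency anchored to the 90-day NOAEL 4 mg/kg/day
      (medium potency).
  - endpoint: reproductive
    pod_type: NOAEL
    value: 2.5
    units: mg/kg/day
    tier: conventional
    study_note: >-
      Rat multigeneration study; hypospadias and prostate effects at 50
      mg/kg and above, NOAEL 2.5 mg/kg.
  - endpoint: stot_re
    pod_type: NOAEL
    value: 2.5
    units: mg/kg/day
    tier: conventional
    study_note: >-
      General repeat-dose toxicity in the conventional programme; lowest
      conventional NOAEL 2.5 mg/kg (synthetic attribution to STOT-RE,
      consistent with the published category 1).
  - endpoint: carcinogenicity
    pod_type: NOEL
    value: 2.7
    units: mg/kg/day
    tier: conventional
    study_note: >-
      Rat long-term bioassay; Leydig cell and adrenal tumours, NOEL 2.7
      mg/kg/day.
  - endpoint: carcinogenicity
    pod_type: NOEL
    value: 24
    units: mg/kg/day
    tier: conventional
    study_note: Mouse long-term bioassay; liver tumours, NOEL 24 mg/kg/day.
  overrides:
  - endpoint: carcinogenicity
    tier: tier2_invitro
    category: 1
    note: >-
      Published tier-2 carcinogenicity category is 1; the tier-2 NOEL of 2
      mg/kg falls in the T25 medium-potency band (1-100) and is not
      derivable as category 1 by banding. Expert-assigned as printed.
  - endpoint: reproductive
    tier: conventional
    category: 2
    note: >-
      Published conventional reproductive category is 2 (medium potency)
      although the multigeneration NOAEL of 2.5 mg/kg lies below the ED10
      high-potency limit of 4; the NOAEL is evidently not treated as an
      ED10 surrogate here. Expert-assigned as printed.
  dnel_overrides:
  - tier: conventional
    value: 0.024
    note: >-
      Published conventional DNEL is 0.024 mg/kg; the lowest published
      conventional NOAEL (2.5 mg/kg) would give 0.025 under UF 100.
      Expert-assigned as printed.
scenarios:
  schema_version: 1
  duration: long_term
  plan:
  - exposure_step: tier1_screening
    hazard_tier: tier2_invitro
  - exposure_step: tier2_higher
    hazard_tier: tier2_invitro
  - exposure_step: tier2_higher
    hazard_tier: tier3_targeted_invivo
  scenarios:
  - scenario_id: chemical_intermediate
    route: inhalation
    population: industrial workers
    doses:
      tier1_screening:
        value: 5.0
        units: mg/kg/day
      tier2_higher:
        value: 0.004
        units: mg/kg/day
  - scenario_id: metal_working_fluid
    route: inhalation
    population: professional workers
    doses:
      tier1_screening:
        value: 4.0
        units: mg/kg/day
      tier2_higher:
        value: 0.002
        units: mg/kg/day
  - scenario_id: hobby_glue
    route: dermal
    population: consumers
    doses:
      tier1_screening:
        value: 2.0
        units: mg/kg/day
      tier2_higher:
        value: 0.03
        units: mg/kg/day
# Screening (tier1_screening) doses are synthetic representative values
# inside the published Category B; the higher-tier refined doses 0.004 and
# 0.002 mg/kg/day are as published; the hobby-glue refined dose is a
# synthetic representative value inside the published Category C.
expected:
  display_sigfigs: 2
  dnel:
    tier2_invitro: 0.006
    tier3_targeted_invivo: 0.04
    conventional: 0.024
  dnel_display:
    tier2_invitro: "0.006"
    tier3_targeted_invivo: "0.04"
    conventional: "0.024"
  categories:
    stot_re:
      tier2_invitro: 1
      tier3_targeted_invivo: 1
      conventional: 1
    reproductive:
      tier2_invitro: 1
      tier3_targeted_invivo: 2
      conventional: 2
    carcinogenicity:
      tier2_invitro: 1
      tier3_targeted_invivo: 2
      conventional: 2
  trajectory:
    chemical_intermediate:
      exposure_categories: [B, D, D]
      colours: [red, amber, amber]
      verdicts: [unacceptable, insufficient_confidence, acceptable]
      recommendations: [refine_exposure, escalate_hazard_tier, accept]
      terminal: accept
    metal_working_fluid:
      exposure_categories: [B, D, D]
      colours: [red, amber, amber]
      verdicts: [unacceptable, insufficient_confidence, acceptable]
      recommendations: [refine_exposure, escalate_hazard_tier, accept]
      terminal: accept
    hobby_glue:
      exposure_categories: [B, C, C]
      colours: [red, red, red]
      verdicts: [unacceptable, unacceptable, unacceptable]
      terminal: reject
  animals_used:
    tier2_invitro: 0
    tier3_targeted_invivo: 100
    conventional: 2200
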
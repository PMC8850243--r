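# Worked example EC3: a preservative with non-specific toxicity
# (phenoxyethanol-like). Hazard assessment only: no exposure scenarios
# were published, so the fixture carries none and the decision engine is
# exercised on EC1/EC2.
name: EC3
description: >-
  Preservative with non-specific toxicity (phenoxyethanol-like); tier-2
  in vitro + IVIVE hazard assessment compared against a conventional
  90-day study. Hazard only.
dossier:
  schema_version: 1
  substance_id: EC3
  name: example chemical 3 (preservative, phenoxyethanol-like)
  ttc:
    genotoxic_alert: false
    op_or_carbamate: false
    cramer_class: I
    in_domain: true
  pod_records:
  - endpoint: stot_re
    pod_type: NOEL
    value: [1.9, 3.1]
    units: mg/kg/day
    tier: tier2_invitro
    study_note: >-
      General toxicity (likely liver/kidney); published IVIVE output
      stored directly: in vitro PoD range 171-557 uM (parent; major
      metabolite 217-359 uM) -> in vivo PoD 1.9-3.1 mg/kg. The published
      concentration/dose pair is not a single linear factor, so the
      converted dose, not a factor, is fixture data.
  - endpoint: stot_re
    pod_type: NOEL
    value: [360.0, 650.0]
    units: mg/kg/day
    tier: conventional
    study_note: >-
      90-day rat study; liver weight increase, kidney/bladder effects,
      red-cell decreases. NOAEL 369 (male) / 652 (female) mg/kg, published
      as NOEL 360-650 mg/kg.
  overrides:
  - endpoint: stot_re
    tier: tier2_invitro
    category: not_classified
    note: >-
      Published STOT-RE category is "None": no specific target-organ
      toxicity was identified and no classification was proposed, although
      the NOEL of 1.9-3.1 mg/kg falls inside the STOT-RE bands.
      Expert-assigned as printed.
  - endpoint: stot_re
    tier: conventional
    category: not_classified
    note: >-
      Published STOT-RE category is "None" for the conventional study
      (non-specific toxicity, no classification proposed).
      Expert-assigned as printed.
  dnel_overrides: []
scenarios:
  schema_version: 1
  duration: long_term
  plan: []
  scenarios: []
expected:
  # The published tier-2 DNEL "0.02-0.03" implies 1-significant-figure
  # display of 1.9-3.1 / 100; the conventional DNEL is shown at 2.
  display_sigfigs:
    tier2_invitro: 1
    conventional: 2
  dnel:
    tier2_invitro: [0.019, 0.031]
    conventional: [3.6, 6.5]
  dnel_display:
    tier2_invitro: "0.02-0.03"
    conventional: "3.6-6.5"
  ivive_pod: [1.9, 3.1]
  categories:
    stot_re:
      tier2_invitro: not_classified
      conventional: not_classified
  animals_used:
    tier2_invitro: 0
    conventional: 160
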
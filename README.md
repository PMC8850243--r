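# namtier

A deterministic decision engine for **tiered chemical safety assessment**
with new approach methodologies (NAMs). It is written for regulatory and
industry toxicologists who want to replay, audit or prototype
exposure-led assessments in which hazard data are generated only to the
depth a use actually requires — TTC screen first, then in silico, in
vitro + IVIVE, targeted in vivo, and conventional studies only as a last
resort.

## What it computes

**Hazard potency banding.** Each endpoint's point of departure (PoD) is
banded into categories 1–4 (1 most severe) using CLP-derived dose limits,
e.g. STOT-RE (NOAEL, mg/kg/day): `<10 | 10–100 | 100–1000 | >1000`;
carcinogenicity uses the T25 specific-concentration-limit potency bands
`<1 | 1–100 | >100`, reproductive toxicity the ED10 bands
`<4 | 4–400 | >400` (high/medium/low potency → category 1/2/3). Intervals
classify by their health-protective lower end; boundary ties go to the
more severe category.

**DNEL.** `DNEL = PoD / UF` with a default uncertainty factor of
100 (10 interspecies × 10 intraspecies), computed exactly; rounding is
display-only. In vitro concentrations (µM) are first converted to
oral-equivalent doses, either by a stored linear factor or by steady-state
reverse dosimetry: `dose = C · CL · 24 · MW / 1000 / f_abs` (mg/kg/day).

**Exposure categories A–E.** Per exposure duration, boundaries are
derived from the same band tables: the Category A lower limit is the
duration's study limit dose / UF; the B/C and C/D boundaries are the
category-2 and category-1 upper limits of the driving endpoint
(lowest category-1 limit) / UF; the D/E boundary is the substance-specific
TTC (0.0025 µg/kg/day with a genotoxicity alert, 0.3 for
OPs/carbamates, 1.5 / 9.0 / 30 for Cramer III/II/I). With defaults this
yields, in mg/kg/day:

| Duration | A | B | C | D |
|---|---|---|---|---|
| 1 day | > 50 | 20–50 | 3–20 | TTC–3 |
| ≤ 3 months | > 10 | 4–10 | 0.04–4 | TTC–0.04 |
| > 3 months | > 10 | 1–10 | 0.01–1 | TTC–0.01 |

**Decision matrix.** Hazard category × exposure category maps to
red/amber/green; amber cells force a margin-of-exposure comparison of the
full DNEL and exposure intervals, with a tier-dependent confidence
multiplier (default 10 for tier-2 in vitro hazard data): an exposure that
clears the DNEL but not DNEL/10 signals *insufficient confidence* —
escalate the hazard tier — rather than rejection. `assess()` replays a
dossier through the exposure/hazard refinement steps present in the
inputs and emits a decision record per step.

## Worked example

```r
library(namtier)

# a 90-day rat study NOAEL of 4 mg/kg/day
pod <- pod_record("stot_re", "NOAEL", 4, tier = "tier3_targeted_invivo")
classify_endpoint(default_band_tables()$stot_re, pod)
#> <hazard result> stot_re: category 1
derive_dnel(pod)
#> <DNEL> 0.04 mg/kg/day (PoD NOAEL 4, UF 100)

# replay the packaged anti-androgen worked example (three long-term uses)
fx <- load_fixture("EC1")
assess(fx$dossier, fx$scenarios)
#> <assessment trajectory> EC1 (long_term)
#>            scenario_id refinement_step           hazard_tier exposure_category
#>  chemical_intermediate               1         tier2_invitro                 B
#>  chemical_intermediate               2         tier2_invitro                 D
#>  chemical_intermediate               3 tier3_targeted_invivo                 D
#>  ...
#>  hazard_category colour                 verdict       recommendation
#>                1    red            unacceptable      refine_exposure
#>                1  amber insufficient_confidence escalate_hazard_tier
#>                1  amber              acceptable               accept
#>  ...
#> terminal states:
#>   chemical_intermediate: accept
#>   metal_working_fluid: accept
#>   hobby_glue: reject
```

Reading the trajectory: at the screening exposure estimate every use sits
at Category B against a category 1 hazard (red — exposure far above the
DNEL of 0.006 mg/kg/day). Refined exposure moves two uses to Category D
(amber), but the tier-2 margin of exposure (0.006/0.004 = 1.5) is below
the ×10 confidence requirement for in vitro data, so the engine escalates
the hazard tier. The targeted in vivo DNEL of 0.04 mg/kg/day gives a
margin of 10 at multiplier 1: both worker uses are accepted; the hobby
glue use stays red and is rejected. An interval comparison such as
`moe_verdict(c(0.36, 3.6), c(0.5, 1.45))` returns `borderline`
(moe 0.25): overlapping DNEL and exposure ranges.

`render_report(trajectory, "markdown")` produces the full report —
boundary derivation trace, per-tier hazard/DNEL table, decision table,
text matrix with scenario markers and expert-override disclosures — and
`render_report(trajectory, "json")` its exact-value twin.

A thin command line lives at `exec/namtier`
(`namtier boundaries | classify | dnel | ttc | assess | fixtures | generate`).

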
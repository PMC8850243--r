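---
title: "Methods: the tiered hazard-exposure decision engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tiered hazard-exposure decision engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namtier)
```

# The assessment model

`namtier` implements an exposure-led, tiered safety assessment. The
guiding idea is that hazard information should be generated to the depth
a use requires, not to a fixed study menu: a use with negligible exposure
can be cleared by a threshold-of-toxicological-concern (TTC) screen with
no data at all, while a high-exposure use may need targeted in vivo work.
The engine is deterministic throughout — every decision is a table lookup
or an interval comparison — so a dossier replays to the identical
trajectory every time, which is the property that makes the output
auditable.

Four pieces interlock:

1. **Potency banding.** A point of departure (PoD) for an endpoint is
   banded into hazard categories 1–4 (1 most severe) by CLP-derived dose
   limits (`default_band_tables()`). STOT-SE/STOT-RE use NOAELs;
   carcinogenicity and reproductive toxicity reuse the specific
   concentration limit potency scheme (T25 and ED10 bands, with
   high/medium/low potency mapping to categories 1/2/3); acute oral uses
   the ATE bands; dermal sensitisation uses induction concentrations in
   percent and never enters dose arithmetic.
2. **DNEL derivation.** The tier's driving PoD (minimal lower bound among
   systemic endpoints) divided by an uncertainty factor, default 100
   (10 interspecies × 10 intraspecies). The division is exact; display
   rounding is a report concern.
3. **Exposure categorisation.** Duration-specific boundaries A–E derived
   from the same band tables, the study limit doses and the substance
   TTC; exposures are oral-equivalent systemic doses.
4. **Decision matrix.** Hazard category × exposure category → colour;
   amber resolves by a margin-of-exposure (MoE) comparison with
   tier-dependent confidence multipliers.

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Uncertainty factor | 100 | – | 10 inter- × 10 intra-species; used for DNELs and for exposure boundary derivation |
| TTC values | 0.0025 / 0.3 / 1.5 / 9.0 / 30 | µg/kg/day | genotoxic alert / OP-carbamate / Cramer III / II / I, for a 60 kg individual, uncertainty already included |
| Limit doses | 2000 (single), 1000 (repeat) | mg/kg | study limit doses anchoring Category A; the one-day A boundary uses the 5000 mg/kg STOT-SE top band |
| Body weight | 60 | kg | the TTC reference individual; used for inhalation conversion |
| Absorption fractions | 1.0 per route | – | worst-case screening default (100 % absorption) |
| Tier confidence multipliers | 10 (tier 2), 1 (tier 3, conventional) | – | in vitro + IVIVE PoDs carry 1–2 extra orders of magnitude of uncertainty; 10 is the minimum consistent with the packaged worked examples (a raw tier-2 margin of 1.5 escalates, a tier-3 margin of 10 accepts) |

All are configurable (`assessment_config()`, `tier_confidence()`,
`limit_doses()`, band tables via `potency_band_table()`), and the matrix
accepts a user-supplied cell map which is validated for monotonicity at
load.

# Design choices where the design was open

**Boundary derivation is a reconstruction.** The stated principle —
health-protective lower values with an uncertainty factor of 100 — does
not by itself determine the inner boundaries when several endpoints are
relevant to a duration. An element-wise minimum across endpoints would
give a short-term B/C boundary of 1 mg/kg/day (from the STOT-RE
category-2 limit of 100), not the published 4. The published limits
follow a single *driving endpoint* per duration — the one with the lowest
category-1 limit (STOT-SE for one-day, ED10 for short-term, T25 for
long-term) — whose whole band set is used. That rule is the default
(`strategy = "driving_endpoint"`), it reproduces the published table
cell-for-cell, and every boundary records its source in
`derivation_trace`. The stricter element-wise rule remains available as
`strategy = "elementwise_min"` without any claim that it was intended.

**Tie-breaks are health-protective and mirrored.** A PoD exactly on a
shared band limit takes the more severe hazard category; a dose exactly
on an exposure boundary takes the higher exposure category; a dose
exactly equal to the TTC fails the tier-0 screen. Interval PoDs classify
by their lower end; exposure intervals categorise by their upper end.

**The full matrix is anchored, not copied.** Only some cells of the
colour matrix are pinned by the worked assessments (hazard 1 × B red,
1 × D amber, 1 × E green, 2 × A red, unclassified × A green only after a
limit-dose study). The remaining cells were filled in as the most
conservative assignment consistent with monotonicity, and blended
"red/amber" narrations are treated as the more conservative pure colour.
Category A for an unclassified substance is amber unless a tier-3+ study
confirmed no toxicity at the limit dose (`limit_dose_clearance`).

**MoE verdicts compare full intervals, and multipliers only gate
acceptance.** Acceptable means the exposure range clears the whole DNEL
range by the tier's multiplier; exposure entirely above the DNEL range is
unacceptable; overlap is borderline. When raw intervals would be
acceptable but the multiplier flips the outcome, the verdict is
`insufficient_confidence`: the obstacle is the data quality, so the
signal is hazard-tier escalation, not rejection. Applying the multiplier
to the borderline/unacceptable split as well would misclassify the
packaged borderline comparisons (an overlapping tier-2 DNEL range would
become "unacceptable"), so the raw intervals decide that split.

**TTC precedence.** Genotoxicity alert before OP/carbamate before Cramer
class — the most conservative applicable basis. An unknown Cramer class
without alerts is an error, not a silent Cramer III default; the
conservative fallback is explicit (`assume_cramer_iii = TRUE`). A TTC at
or above a duration's C/D boundary (e.g. Cramer I, 0.03 mg/kg/day,
against the long-term boundary of 0.01) would invert the D band;
`derive_boundaries()` refuses it rather than silently collapsing the
category, and the property suite asserts the refusal.

**Worked-example values that banding cannot derive are overrides.** Three
published results are not reproducible from the published inputs by the
engine's own rules (a tier-2 carcinogenicity category printed one band
more severe than its PoD implies; a conventional reproductive category
printed one band less severe than naive ED10 banding of a NOAEL; a
conventional DNEL of 0.024 mg/kg/day where the lowest NOAEL/100 gives
0.025). The fixtures store these as expert overrides with provenance
notes; profiles and reports disclose them, and the replay tests assert
the disclosure rather than pretending derivation. Similarly, exposure
doses for screening steps whose published record is only a category
letter are synthetic representative values inside that category, labelled
as such in the fixture.

**Display precision is per-fixture.** Published tables round
inconsistently (0.04 vs 0.36–3.6 at two significant figures, but
0.02–0.03 from 1.9–3.1/100 at one). The core never rounds; each fixture
records the display precision its published table used.

# The synthetic generator

`generate_random_dossier()` emulates the *shape* of real inputs for
property testing: PoDs log-uniform over 10^-4^–10^4^ mg/kg/day (spanning
every band of every endpoint), exposure doses log-uniform over
10^-7^–10^3^ mg/kg/day (spanning Category E below any TTC up to above
every Category A limit), sampled TTC flags, routes and durations, and
seeded determinism without disturbing the caller's RNG. It does **not**
emulate correlations found in real data — between endpoints, between
tiers of the same endpoint, or between use pattern and dose — nor data
gaps, unit heterogeneity or reporting error. Passing property tests
therefore demonstrates the engine's invariants (monotonicity, contiguity,
linearity, trichotomy, determinism) over the full input space, not
predictive performance on real chemicals.

# Numerical notes and degenerate inputs

* All internal doses are mg/kg/day (µg/kg/day inputs divide by 1000 on
  read); dermal sensitisation concentrations stay in percent; µM records
  must pass through `oral_equivalent_dose()` before classification.
* A zero dose is Category E and passes the tier-0 screen with infinite
  margin; a zero exposure is acceptable with infinite MoE. Zero or
  negative PoDs are rejected — "no effect at any dose" is an explicit
  `no_response` flag, not a zero.
* IVIVE is linear in concentration in both modes, so interval endpoints
  convert independently; steady-state conversion matches total plasma
  concentration by default, free-concentration matching is opt-in.
* Boundary contiguity is exact: every positive dose receives exactly one
  category, verified at the boundaries themselves and at
  epsilon-perturbed values.
* A scenario duration with no relevant endpoint data at a tier is a
  reported data gap (lowest-severity matrix row, `data_gap` flag), not an
  exception.

# Test problem sizes

The classification-versus-oracle sweep runs 10,000 random PoDs against an
independently hand-written banding oracle; the cross-module acceptance
sweep runs 10,000 seeded cases over banding monotonicity, DNEL linearity,
exposure contiguity, tier-0 consistency and MoE trichotomy; the
end-to-end generator sweep replays 150 full synthetic dossiers and the
coverage check up to 300. These sizes exercise every band, category and
verdict many times over while keeping the default suite quick.

# Known limitations

* Exposure estimation itself (TRA/ART/ConsExpo-class modelling) is out of
  scope: exposure doses are inputs.
* The IVIVE steady-state converter is deliberately minimal (no
  multi-compartment PBK, no metabolites); worked-example conversions are
  stored fixture factors back-calculated from published pairs.
* Cramer classification, structural alerts and TTC domain membership are
  input flags, never computed from structure.
* Inhalation/dermal-specific CLP band variants are not implemented; route
  adjustment is by absorption fraction to an oral-equivalent dose.
* Strength-of-evidence carcinogenicity/reproductive classification is
  intentionally replaced by potency banding.
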
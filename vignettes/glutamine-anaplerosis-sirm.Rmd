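---
title: "Methods: first-turn glutamine tracing, MID correction and cohort simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: first-turn glutamine tracing, MID correction and cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glntrace)
```

## The measurement problem

An intravenous ¹³C-glutamine infusion reaches a plateau plasma enrichment
of a few percent within roughly 15 minutes. Glutamine entering cells is
deamidated to glutamate, transaminated/deaminated to α-ketoglutarate, and
oxidized around the TCA cycle (anaplerosis). After a bone marrow aspirate
and CD138-based sorting, GC-MS selected ion monitoring (SIM) measures, for
each metabolite fragment, the intensities of the isotopologue channels
M0..M(n+2), where n is the number of backbone carbons and the two extra
channels absorb heavy isotopes of the derivatization atoms. The analysis
must (1) know which isotopologue the tracer should produce, (2) strip
natural isotope abundance from the measured channels, and (3) express the
resulting labeling on a scale comparable across subjects who reached
different plasma plateaus.

## First-turn positional carbon tracking

The atom maps (shipped as `inst/extdata/tca_atom_maps.yaml`, user
replaceable) encode one oxidative turn: glutamine C1–C5 pass unchanged to
glutamate and α-ketoglutarate; the α-ketoglutarate dehydrogenase step
releases C1 as CO₂ and the remaining C2–C5 become succinate C1–C4;
succinate and fumarate are symmetric, so each label state splits into its
two equiprobable orientations; oxaloacetate condenses with acetyl-CoA —
modeled as fully unlabeled in the first turn — to form citrate, and is
transaminated to aspartate.

```{r shifts}
propagate_first_turn(tracer_spec("u13c5"))
propagate_first_turn(tracer_spec("5c13"))
```

Uniform labeling therefore predicts m+5 glutamate/α-ketoglutarate and m+4
four-carbon intermediates (and m+4 citrate, since only the oxaloacetate
carbons carry label); C5-only labeling predicts m+1 everywhere because C5
survives the decarboxylation, which removes C1.

Scope choices, made deliberately: the model is first-turn and oxidative
only. Reductive carboxylation (which would put m+5 on citrate), second-turn
isotopomers, pyruvate-carboxylase anaplerosis and exchange fluxes are out
of scope — the model answers "which single isotopologue does the tracer
create in one turn", which is what the enrichment statistics consume. A
full EMU/cumomer flux model is explicitly not attempted. Whether
second-turn contributions are negligible at 60-minute infusions is not
decidable from the data this package targets; the single-turn reading is
the stated assumption.

## The forward MID model

`ideal_mid()` is the two-component mixture used by the simulator: with
anaplerotic fraction *f* (fraction of the metabolite pool derived from
plasma glutamine) and plasma tracer enrichment *e*, a metabolite with
single-turn shift *s* has MID `(1 − f·e)` at M0 and `f·e` at Ms. Its mole
percent enrichment is therefore `f·e·s/n`, which is what makes the
downstream inversion (`recover_anaplerotic_fraction()`) a one-liner:
`f = relative_enrichment · n / s`.

## Natural-abundance correction

For a derivatized fragment with elemental composition (C, H, N, O, Si, S),
column *j* of the correction matrix is the convolution of the
natural-abundance mass distributions of all atoms except the *j* labeled
backbone carbons with the binomial purity distribution of those *j*
carbons (purity default 0.99, configurable; isotope abundances default to
IUPAC values and are overridable via `isotope_table(overrides = ...)`).
The measured channel vector is `A·x`; `correct_mid()` solves for `x ≥ 0`
by nonnegative least squares (`pracma::lsqnonneg`), truncates to M0..Mn
and renormalizes.

Numerical choices: nonnegative least squares rather than direct inversion,
so noise cannot produce negative isotopologue fractions; a condition-number
guard (κ > 1e10) rejects degenerate compositions; correction is invariant
to uniform intensity scaling, so raw ion counts are accepted; the M(n+1),
M(n+2) channels are used during the solve (they carry Si/S heavy-isotope
signal) and dropped afterwards. MPE is defined as the carbon-weighted
average labeling Σᵢ i·Mᵢ/n; the plain "fraction of labeled molecules"
1 − M0 is exposed separately as `fraction_labeled()`.

The shipped fragment catalog gives the TBDMS/ethoxime [M−57]⁺ compositions
for the TCA panel; every composition reproduces its monitored nominal M0
m/z. It is an example configuration: laboratories monitoring different
fragments supply their own catalog CSV.

## Enrichment statistics

Precursor–product normalization divides each metabolite's MPE by the
subject's steady-state plasma glutamine enrichment, removing dose and
plateau differences; it does not require intracellular isotopic steady
state. Paired CD138+/CD138− contrasts use the two-sided paired t test;
concentrations use Mann-Whitney U (exact for both arms ≤ 8 without ties,
normal approximation with tie correction otherwise). Enrichment summaries
are mean ± SEM and concentration summaries are medians, matching field
conventions for these data types. Per-subject fractional ratios are
multiplicative, so the group summary is a geometric mean. No
multiple-testing correction is applied by default (per-metabolite
reporting); `enrichment_contrast(adjust = TRUE)` adds Benjamini–Hochberg.
Subjects missing one metabolite are dropped per metabolite, not listwise.
Significance at 0.05 is reported, never used to filter rows.

## Quantitation

Calibration curves are unweighted least-squares lines of response ratio
(analyte / isotope-labeled internal standard) on concentration, with an
optional 1/x weighting for variance growing with level; at least five
points are required and r² < 0.98 warns. Back-calculation inverts the
line; responses above 1.5× the top calibrator are flagged as extrapolation
but not rejected, since clinical samples can exceed calibrated ranges.
Internal-standard normalization makes concentrations invariant to global
intensity scaling.

## What the synthetic cohorts emulate — and what they do not

`cohort_config()` defaults describe a study with 7 volunteers, 11 MGUS and
12 MM subjects; plateau enrichments uniform on 0.04–0.10 (volunteers) and
0.03–0.07 (patients); a base anaplerotic fraction of 0.15 in CD138− cells;
a multiplicative CD138+/CD138− effect of 1.5 in MM for every metabolite,
1.0 in MGUS except 1.3 for aspartate, 1.0 in volunteers; between-subject
lognormal CV 0.4 (shared by both fractions of a subject, preserving the
paired structure) and within-subject per-fraction CV 0.15; SIM noise of
1% multiplicative CV per channel plus additive Gaussian noise at 1e-4 of
the total ion count; plasma-enrichment measurement CV 2%; BMPC% uniform on
0.5–3 / 1–9 / 10–60 for volunteer/MGUS/MM; bone-marrow plasma
concentrations linear in BMPC% (glutamate 55 + 1.2·BMPC, aspartate
8 + 0.3·BMPC, glutamine 480 − 2.5·BMPC µmol/L, lognormal CV 0.15) with a
5% CV LC-MS re-measurement. All of these are modeling choices of this
package — plausible magnitudes for GC-MS SIM tracer studies — not measured
study values, and every one is a config parameter.

The generator emulates the *statistical structure* the pipeline assumes:
paired fractions, heterogeneous subjects, group-specific effects,
enrichment-independent concentration contrasts. It does not emulate
chromatographic artifacts, sorting attrition beyond what the paired
normalization cancels, second-turn labeling, inter-batch drift, or
non-lognormal outlier subjects. Passing recovery tests therefore shows the
chain is a correct inverse of its own forward model at realistic noise,
not that real cohorts will be free of those artifacts.

Problem sizes used in the shipped tests were chosen to exercise the
statistics at study-like scale: single cohorts at the default n for
qualitative pattern checks, and 100 replicate MM arms (n = 11) for
parameter-recovery and power checks, where the pipeline recovers
anaplerotic fractions with median absolute error under 10% and detects the
MM paired contrast in well over 80% of replicates.

## Known limitations

Single-tracer, single-turn, oxidative-only labeling; no flux estimation;
no peak integration (vendor software is assumed upstream); the exact-p
Mann-Whitney switches to the normal approximation in the presence of ties
even in small samples; calibration assumes a linear response over the
calibrated range.
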
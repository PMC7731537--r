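# glntrace

In vivo ¹³C-glutamine stable-isotope-resolved metabolomics (SIRM) of the
TCA cycle, for studies that infuse labeled glutamine into human subjects
and read out tracer incorporation in sorted cell fractions by GC-MS
selected ion monitoring (SIM). The motivating application is multiple
myeloma: comparing glutamine anaplerosis in CD138+ (pre-)malignant bone
marrow plasma cells against the remainder of the paired bone marrow
mononuclear cells (CD138−) in volunteers, MGUS and MM patients.

## What it computes

**First-turn isotopologue prediction.** Glutamine carbons are tracked
position by position through glutamate → α-ketoglutarate → (CO₂ release of
C1) → succinate → fumarate → malate → oxaloacetate → {aspartate, citrate
(condensation with unlabeled acetyl-CoA)}. Under uniformly labeled
[¹³C₅]-glutamine the first oxidative turn yields m+5 glutamate and
α-ketoglutarate and m+4 succinate, fumarate, malate, aspartate and
citrate; under [5-¹³C]-glutamine every intermediate is m+1. Succinate and
fumarate are symmetric and carried as equiprobable orientations.

**Natural-abundance correction.** Each monitored SIM channel vector
(M0..M(n+2), n backbone carbons) is modeled as *A·x*, where column *j* of
*A* is the theoretical spectrum of a molecule with exactly *j* labeled
backbone carbons — the convolution of the natural-abundance distributions
of all remaining atoms of the derivatized fragment (C, H, N, O, Si, S)
with the binomial isotopic-purity distribution of the *j* labels. The
backbone mass isotopomer distribution (MID) *x* is recovered by
nonnegativity-constrained least squares, and summarized as mole percent
enrichment MPE = Σᵢ i·Mᵢ / n.

**Enrichment statistics.** MPE is normalized to the steady-state plasma
glutamine enrichment of the same subject (precursor–product
normalization), CD138+/CD138− pairs are contrasted with the paired t test,
per-subject fractional ratios (CD138+/CD138−) are summarized by geometric
mean, and concentrations are compared by Mann-Whitney U and correlated
with marrow plasma-cell percentage by OLS/Pearson.

**Quantitation.** Internal-standard response ratios are converted to
µmol/L through 12-point least-squares calibration curves, with
cross-platform (GC-MS vs LC-MS) concordance checks.

**Synthetic cohorts.** `generate_cohort()` draws cohorts with the
statistical structure the analysis assumes (plateau enrichments of 3–10%,
heterogeneous per-subject anaplerotic fractions, group-specific
CD138+/CD138− effects, BMPC%-linked concentrations) plus a truth table,
so the whole chain is testable end to end without patient data.

## Worked example

```r
library(glntrace)

propagate_first_turn(tracer_spec("u13c5"))
#>           glutamine           glutamate alpha_ketoglutarate           succinate
#>                   5                   5                   5                   4
#>            fumarate              malate        oxaloacetate           aspartate
#>                   4                   4                   4                   4
#>             citrate
#>                   4

res <- run_pipeline(list(simulate = TRUE, seed = 7, out_dir = "demo_out",
                         cohort = list(n_volunteer = 0, n_mgus = 10, n_mm = 11)))
res$contrasts[res$contrasts$group == "MM",
              c("metabolite", "n", "t", "p", "geomean_ratio")]
#>      metabolite  n    t        p geomean_ratio
#> MM.1  aspartate 11 3.70 0.004125          1.31
#> MM.2    citrate 11 3.98 0.002583          1.43
#> MM.3   fumarate 11 5.17 0.000419          1.47
#> MM.4  glutamate 11 4.38 0.001375          1.50
#> MM.5     malate 11 4.60 0.000978          1.48
```

All five TCA readouts are significantly more labeled in MM CD138+ cells
than in the paired CD138− cells (paired t, p < 0.05), with geometric-mean
fractional ratios near the configured 1.5× effect; in the MGUS arm of the
same run only aspartate reaches significance (p = 0.038, ratio 1.14),
mirroring the intended group structure. `demo_out/` receives tidy CSVs of
corrected MIDs, MPE, relative enrichments, per-subject ratios, group
contrasts, concentration tests and a run log.

A shell entry point wrapping the same functions is included at
`inst/cli/glntrace.R` (subcommands `simulate`, `correct`, `enrich`,
`quantify`, `report`).

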
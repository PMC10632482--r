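---
title: "Methods: immuno-metabolic profiling of DC vaccines"
author: "immunomet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immuno-metabolic profiling of DC vaccines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunomet)
```

# Scope and model

`immunomet` analyses the metabolic state of dendritic-cell (DC) vaccine
products and circulating myeloid cells from three complementary readouts,
and relates them to clinical outcome:

1. **SCENITH**: per-cell protein synthesis (anti-puromycin staining
   intensity) measured after short treatments with metabolic inhibitors.
   Translation is the dominant ATP consumer, so the drop in puromycin
   incorporation under an inhibitor reads out how much of the cell's
   energy supply depends on the blocked pathway.
2. **Extracellular flux (Seahorse)**: kinetic oxygen-consumption (OCR,
   pmol O~2~/min) and acidification (ECAR, mpH/min) traces through the
   mitochondrial stress test, reduced to the standard bioenergetic
   indices.
3. **Supernatant chemistry and immunogenicity**: culture-media glucose and
   lactate over differentiation, and IFN-γ ELISPOT response calls.

Survival association ties these biomarkers to overall and
progression-free survival via maximally selected rank-statistic cutpoints,
Kaplan–Meier curves, the log-rank test and univariate Cox regression.

## SCENITH parameters

With median puromycin MFI per condition — `C` control, `2DG`
2-deoxy-glucose, `O` oligomycin, `Eto` etomoxir, `Tele` CB-839, `DGO`
2DG + oligomycin — the percent-scale parameters are

$$\mathrm{glucose\ dep} = 100\frac{C - 2DG}{C - DGO},\qquad
  \mathrm{mito\ dep} = 100\frac{C - O}{C - DGO},$$
$$\mathrm{FAO\ dep} = 100\frac{C - Eto}{C - DGO},\qquad
  \mathrm{glutaminolysis\ dep} = 100\frac{C - Tele}{C - DGO},$$
$$\mathrm{glycolytic\ capacity} = 100 - \mathrm{mito\ dep},\qquad
  \mathrm{FAAO} = 100 - \mathrm{glucose\ dep}.$$

The denominator `C − DGO` is the full translation dynamic range;
`validatePanel()` hard-errors when it is non-positive and flags panels
where `(C − DGO)/C` falls below `min_dynamic_range` (default 0.2 — our QC
threshold; the underlying assay protocol does not prescribe one, so it is
configurable).

**Clamping.** Measurement noise can push an inhibitor median above the
control (raw dependence < 0) or below the full block (> 100). Because
these parameters are percentages of a bounded budget, the default reports
values truncated to [0, 100] with `clamped_low`/`clamped_high` flags, and
recomputes the capacities from the clamped dependencies so the complement
identities hold exactly on everything reported. The raw values are always
retained (`raw_*` columns) because whether out-of-range dependence values
should enter group comparisons is a judgement call; both conventions are
exportable.

**Harringtonine** (`H`) arrests translation outright. It appears in the
condition vocabulary purely as a QC anchor — we warn if its MFI exceeds
any other condition's — and never enters a formula.

**Background subtraction.** MFIs are used as measured; no unstained-control
subtraction is applied by default. The formulas are differences over a
difference, so any additive background common to all conditions cancels.

Profiles are computed from *population medians* (the field's "median MFI"
convention); the per-cell oligomycin analysis below is the deliberately
single-cell counterpart.

## Single-cell metabolic binning

After oligomycin, a cell that keeps synthesizing protein is running on
aerobic glycolysis; one whose translation collapses was
mitochondrial-dependent. `assignOligomycinQuantiles()` bins
oligomycin-condition cells into four quantiles of puromycin intensity —
bin 4 (highest) glycolytic, bin 1 mitochondrial-dependent.

Numerical conventions that decide boundary membership:

* boundaries are the empirical 25/50/75 percentiles with linear
  interpolation (type-7), documented because cells adjacent to a boundary
  depend on it;
* ties at a boundary go to the *lower* bin — deterministic and
  independent of row order;
* boundaries are pooled across the whole cohort by default. Comparing bin
  *occupancy* between clinical groups only makes sense against shared
  boundaries; a per-sample scope is provided for sensitivity analysis
  where each sample contributes 25% per bin by construction and only
  within-bin marker expression is comparable.

Binning uses only rank information, so it is invariant to any strictly
monotone intensity transform (tested property).

## Seahorse indices

Traces are segmented at the injections (pre-oligomycin, post-oligomycin,
post-FCCP, post-rotenone/antimycin A) and each segment is reduced by a
configurable aggregator. Defaults: mean for the pre-oligomycin baseline,
maximum for post-FCCP (maximal rate), minimum for the suppressed OCR
segments, maximum for post-oligomycin ECAR (glycolysis rises when ATP
synthase is blocked). These mirror common instrument-report conventions;
the aggregator set used is recorded on every output. Note two
consequences:

* with extremum aggregators on noisy segments the indices acquire a small
  noise-dependent bias; the replicate-linearity property (index of the
  mean trace = mean of per-well indices) holds exactly only for linear
  (mean/median-free) aggregators, and the tests assert it under all-mean
  aggregation;
* all indices are differences, so they are invariant to an additive OCR
  offset, and the identities `spare = maximal − basal` and
  `ATP-linked = basal − proton leak` are algebraic, not empirical.

The exogenous fatty-acid oxidation contrast is `control post-FCCP minus
palmitate+etomoxir post-FCCP`, computed only for explicitly paired wells
(no pairing by plate position). The sign convention — a positive value
means respiration attributable to exogenous palmitate — is our documented
choice. Negative indices are reported with a warning, never clipped:
a negative basal respiration is a QC failure the analyst must see.

## Supernatant flux and ELISPOT

Per-interval glucose consumption is start-minus-end concentration, with
the start reset to fresh-media glucose when a media change opens the
interval (a day-3 change is standard in DC differentiation and makes
measured glucose rise without any cellular production). The
glucose-to-lactate conversion fraction uses the glycolytic stoichiometry
of 2 lactate per glucose: `fraction = lactate / (2 × glucose)`. Values
above 1 are flagged, not truncated. Because the raw ratio is also in
circulation, both `fraction_stoich` and `ratio_raw` are exported.

ELISPOT positivity: net spots = antigen spots − empty-vector (AdVLacZ)
spots, truncated at 0; a post-vaccination response is positive when net
spots exceed 10 per well *and* reach at least twice the baseline net,
with the baseline floored at 1 net spot so a zero baseline cannot make
the fold criterion vacuous (the floor is our convention for a case the
assay rule leaves unspecified).

## Survival statistics

Kaplan–Meier, the two-group log-rank test, maxstat cutpoint selection and
univariate Cox regression are implemented in the package (and
cross-checked against the `survival` package in the test suite) because
they carry the outcome claims:

* **Cox ties**: Efron's approximation, the standard default of mainstream
  survival software.
* **maxstat**: candidates are the distinct observed biomarker values with
  quantile rank inside (0.1, 0.9); each candidate's standardized log-rank
  statistic is computed and the argmax selected, ties toward the smaller
  cutpoint. The log-rank p at the selected cutpoint is labelled
  *uncorrected*: scanning for the best split inflates type I error
  (a tested property — on null data the uncorrected p rejects far more
  often than 5%), so a seeded permutation p-value over the maximum
  statistic is available.
* **Separation**: a covariate that perfectly orders events makes the
  partial likelihood monotone; the coefficient is reported non-estimable
  instead of a large number.
* **Two-group routing**: Shapiro–Wilk per group at α = 0.05; both groups
  must pass for Student's t, otherwise Wilcoxon. For unpaired designs the
  rank-sum test is used (the "signed-rank" name only applies to paired
  data; a `paired` argument provides that variant), and the test actually
  used is recorded per comparison.
* **Multiple testing**: Holm (step-down) and Benjamini–Hochberg (step-up)
  are implemented with monotonicity enforcement and order preservation;
  Holm is used across per-bin marker contrasts within a marker, BH across
  markers in the differential test.
* The per-marker differential test is a group-indicator linear model on
  log2 sample medians, so the coefficient is directly the log2 fold
  change.

# The synthetic cohort generator

The generator exists so the full pipeline can be exercised, end to end
and deterministically, without patient data. It emulates the *structure*
of the study's data, with defaults fixed at the study's conditions:

* cohort of 13 good-outcome and 17 bad-outcome patients plus 3 healthy
  donors;
* ground-truth dependence vectors anchored at the reported group medians
  (mitochondrial dependence 84.4% good vs 76.4% bad, a ~7-point
  glutaminolysis gap, glucose dependence near 55–60%);
* per-cell intensities log-normal with σ = 0.35 (a coefficient of
  variation around 36%, typical of fluorescence intensity distributions),
  median equal to the condition-expected level
  `C·(1 − d·(1 − b))` with background fraction b = 0.05 of translation
  persisting under the full block;
* a per-cell latent glycolytic state (N(0,1)) that shifts oligomycin
  puromycin by `latent_sd = 0.3` on the log scale and couples marker
  intensities through per-marker coefficients, so bin-occupancy and
  marker-by-bin structure are recoverable;
* Seahorse plateau segments with Gaussian noise (SD 5) and a paired
  palmitate+etomoxir well whose post-FCCP plateau sits 40 (good) / 25
  (bad) units lower;
* supernatant kinetics with a day-3 media change back to 11 mM glucose
  (typical culture-media concentration);
* exponential proportional-hazards survival: hazard
  0.04/month multiplied by the configured hazard ratio for patients above
  the mitochondrial-dependence threshold, with independent exponential
  censoring calibrated to the target censoring fraction.

The inhibitor-effect model (linear suppression of expected translation by
the dependence fraction) is a modeling choice, not a claim about biology:
it is the simplest model whose population medians reproduce the SCENITH
formulas exactly, which is what makes it a useful recovery oracle.

A single master seed is split into named sub-streams (cells per sample,
traces, supernatant, survival) via a deterministic hash, so outputs are
reproducible element-for-element and adding a new generator does not
shift existing streams. What the generator does **not** emulate —
spectral spillover, autofluorescence, doublets, batch effects, instrument
drift, non-proportional hazards — bounds what passing tests show about
real data: they validate the arithmetic and inference machinery, not
robustness to instrument artefacts.

# Problem sizes and tolerances

The test-suite and acceptance runs use sizes chosen to make sampling
error comfortably smaller than the asserted tolerances: 5000
cells/condition for ±3-percentage-point dependence recovery over 20
seeds (the median's sampling error there is ≈0.3 pp), n = 500 with 20%
censoring for Cox recovery of ln 2 within ±0.15 and ≥17/20 CI coverage,
200 replicates for the null calibration of the log-rank rejection rate,
and 10 000 cells for bin-boundary agreement with the sort-based oracle.
Complement identities are asserted to 1e−9; they are exact in exact
arithmetic.

# Known limitations

* Only univariate Cox is provided; no multivariable adjustment,
  time-varying covariates or competing risks.
* The maxstat permutation p is the only selection-aware error control;
  no analytic small-sample approximation is implemented.
* FCS support covers list-mode float/double data as produced by modern
  unmixing software and this package's fixture writer; integer-mode and
  multi-dataset files are out of scope.
* Transcriptomics (microarray differential expression, GSEA) and
  embedding visualizations (UMAP/tSNE) are deliberately out of scope; the
  exported tidy tables feed any downstream tool.
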
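# immunomet

Immuno-metabolic profiling of dendritic-cell (DC) vaccine products and
circulating myeloid cells, for translational immunologists analysing
cell-therapy trials.

Autologous DC vaccines are matured ex vivo, and how a patient's cells fuel
themselves — oxidative phosphorylation versus aerobic glycolysis — tracks
with clinical outcome. `immunomet` implements the analysis chain that turns
raw assay readouts into those metabolic biomarkers and their survival
associations:

* **SCENITH metabolic dependence** from per-cell anti-puromycin staining
  under metabolic inhibitors. With median puromycin MFI per condition
  (`C` control, `2DG`, `O` oligomycin, `Eto` etomoxir, `Tele` CB-839,
  `DGO` = 2DG + oligomycin):

  ```
  glucose dependence        = 100 (C − 2DG)  / (C − DGO)
  mitochondrial dependence  = 100 (C − O)    / (C − DGO)
  FAO dependence            = 100 (C − Eto)  / (C − DGO)
  glutaminolysis dependence = 100 (C − Tele) / (C − DGO)
  glycolytic capacity       = 100 − mitochondrial dependence
  FAAO capacity             = 100 − glucose dependence
  ```

* **Single-cell metabolic states**: oligomycin-treated cells binned into
  four puromycin quantiles, bin 4 = glycolytic, bin 1 =
  mitochondrial-dependent, with bin-occupancy and per-bin marker
  comparisons across clinical groups.
* **Seahorse bioenergetics**: basal/maximal respiration, spare capacity,
  proton leak, ATP-linked respiration, exogenous fatty-acid oxidation,
  basal glycolysis and glycolytic capacity from segmented OCR/ECAR
  stress-test traces.
* **Supernatant flux**: glucose consumption and lactate production across
  media changes, and the glucose→lactate conversion fraction under 2:1
  stoichiometry.
* **ELISPOT calls**: background-subtracted IFN-γ responses with the
  ">10 spots and ≥2× baseline" positivity rule.
* **Outcome statistics**: Kaplan–Meier, log-rank, maximally selected
  rank-statistic cutpoints (with permutation control of selection
  inflation), univariate Cox (Efron ties), Shapiro-routed two-group
  tests, ANOVA+Tukey, Holm/BH correction, Spearman matrices.
* A fully **seeded synthetic cohort generator** reproducing the data
  structure of a DC-vaccine trial, so every stage is testable end to end
  without patient data.

## Worked example

```r
library(immunomet)

## SCENITH profile from one inhibitor panel (median puromycin MFI)
panel <- c(C = 1200, `2DG` = 520, O = 260, DGO = 140,
           Eto = 980, Tele = 900)
round(computeScenithProfile(panel)$profile, 1)
#>        glucose_dependence  mitochondrial_dependence            fao_dependence
#>                      64.2                      88.7                      20.8
#> glutaminolysis_dependence       glycolytic_capacity             faao_capacity
#>                      28.3                      11.3                      35.8
```

This mDC sample draws 88.7% of its translational energy budget from
mitochondrial metabolism and keeps only 11.3% glycolytic reserve — the
phenotype associated with good outcome.

```r
## End to end on a synthetic cohort (6 good, 6 bad, 2 healthy donors)
cfg <- syntheticCohortConfig(seed = 7, n_good = 6, n_bad = 6, n_hd = 2,
                             cells_per_condition = 500)
ch  <- generateCohort(cfg)
profs <- profileCohort(summarisePanel(ch$events))
asg  <- assignOligomycinQuantiles(ch$events)
binProportionsByGroup(asg, ch$groups)
#>    group bin    n proportion
#> 1    bad   1  369  0.1230000
#> ...
#> 10   bad   4 1164  0.3880000
#> 11  good   4  494  0.1646667
#> 12    HD   4   92  0.0920000
```

Bad-outcome samples hold 38.8% of their cells in the most glycolytic
bin versus 16.5% (good) and 9.2% (healthy donors) — the generated
cohort reproduces the glycolytic-shift signature the binning is designed
to detect, because its ground-truth mitochondrial dependence is 76.4%
(bad) vs 84.4% (good).

```r
## Survival association of the SCENITH biomarker (maxstat + Cox)
survivalAssociationTable(ch$survival, "mitochondrial_dependence")
#>                  covariate endpoint cutpoint n_high n_low    hr ...
#> 1 mitochondrial_dependence       OS     84.3      3     9 0.26 ...
```

High mitochondrial dependence halves-to-quarters the hazard in this tiny
demo cohort (HR 0.26, CI crossing 1 at n = 12 — the generator's effect,
recoverable with tight intervals at realistic n; see the tests).

A config-driven runner (`runPipeline()`, CLI wrapper in
`inst/scripts/immunomet`) executes any subset of stages and writes tidy
CSVs plus a JSON manifest; identical config + seed reproduces
byte-identical tables.

## Documentation

The methods vignette (`vignettes/immunomet-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, the numerical conventions (clamping, tie rules, aggregators,
Efron ties), what the synthetic generator does and does not emulate, and
known limitations.
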
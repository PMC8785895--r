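# dmnAging

Quantifies resting-state functional connectivity of the default-mode
network (DMN) from ROI-level fMRI time series and tests whether its
relationship with age differs between diagnostic groups — the analysis
design used to ask whether a psychiatric condition *accelerates* the
brain's functional aging. It is aimed at researchers who have ROI time
series (e.g. consortium-shared extractions; raw images are neither needed
nor supported) plus a phenotype table, and want the full chain from
quality control to interaction statistics to be reproducible and tested.

## What it computes

Per subject, from a `volumes x 58 ROIs` matrix:

* **Within-DMN FC strength** — the mean Pearson correlation over all
  58·57/2 = 1653 ROI pairs of the full-scan connectivity matrix.
* **Temporal variability of dynamic FC** — sliding windows (default
  100 s width, 6 s step at TR = 2 s) give one connectivity matrix per
  window; for region *k* with windowed connectivity profiles `F(i, k)`
  (row *k*, self-entry removed),

      V_k = 1 − mean_{i≠j} cor(F(i,k), F(j,k)),     V = mean_k V_k,

  both bounded in [0, 2].

At the group level: OLS of each outcome on
`diagnosis + age + diagnosis×age + sex + education + site + mean FD`
(diagnosis MDD = 0 / HC = 1, SPSS-style standardized betas), within-group
age correlations compared across groups by the Fisher r-to-z statistic
`z = (atanh r1 − atanh r2) / sqrt(1/(n1−3) + 1/(n2−3))`, partial
correlations with clinical scores, episodicity ANCOVA, a Spearman
heteroscedasticity diagnostic with natural-log refit, a window-parameter
validation grid (80/100/120 s × 6/8/10 s), and pooled-t / chi-square tests
recomputable from published summary tables. A seeded multi-site cohort
simulator (one-factor signals with slowly drifting, region-specific
coupling; scan lengths 150–250 volumes at TR = 2 s) makes the whole
pipeline testable end to end. See the methods vignette
(`vignettes/dmn-aging-methods.Rmd`) for the model details and design
rationale.

## Worked example

```r
library(dmnAging)

st  <- data.frame(site = c("s01", "s02", "s20"),
                  n_volumes = c(210, 200, 242), tr_s = 2, weight = c(2, 1, 4))
cfg <- simulationConfig(nPerGroup = 60, siteTable = st)
cohort  <- simulateCohort(cfg, seed = 1)
cohort
#> DmnCohort: 120 subjects (HC: 60, MDD: 60), 120 time series, 58 ROIs

qc      <- qcFilter(cohort)
metrics <- computeAllMetrics(qc$cohort, widthS = 100, stepS = 6)
head(metrics[, c("subject_id", "diagnosis", "age",
                 "fc_strength", "dfc_variability")], 3)
#>   subject_id diagnosis      age fc_strength dfc_variability
#> 1   MDD_0001       MDD 30.47891   0.4037888       0.8215307
#> 2   MDD_0002       MDD 35.48982   0.2917405       0.7806862
#> 3   MDD_0003       MDD 44.92411   0.4306380       0.8240747

fitInteractionModel(metrics, "fc_strength")
#> RegressionResult for fc_strength  - n = 120
#>             term          b beta_std       t         p
#>        diagnosis  0.0096315  0.06804  0.8032 4.236e-01
#>              age -0.0027683 -0.49669 -4.0622 9.095e-05
#>  diagnosis_x_age  0.0007141  0.09152  0.7380 4.621e-01
#>              sex -0.0205988 -0.14543 -1.7237 8.755e-02
```

The age row says FC strength drops by about 0.0028 correlation units per
year (standardized beta −0.50, clearly significant even at n = 120); the
`diagnosis_x_age` row is the acceleration test — its coefficient is the
difference between the control and patient age slopes (positive when
patients decline faster, given HC = 1 coding), too noisy to resolve at
this toy sample size but reliably recovered at the package's default
simulation scale of 150 subjects per group. `runAnalysis(cohort)` wraps
the whole chain (QC → metrics → both regressions → group-correlation
comparison → clinical models → heteroscedasticity → validation grid) and
writes deterministic TSV outputs. A thin CLI with `simulate`, `qc`,
`metrics`, `analyze` and `validate` subcommands lives at
`inst/scripts/dmn-aging-cli.R`.

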
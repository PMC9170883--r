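# alphaRECIST

Composite AFP–imaging response evaluation for hepatocellular carcinoma (HCC)
treated with conversion radiotherapy, with survival-based cutoff discovery
and validation statistics.

## The problem

Size-based radiological criteria struggle after radiotherapy for
unresectable HCC: RECIST 1.1 misses responders whose tumors shrink little,
and mRECIST (which measures only the arterially enhancing, "viable" portion)
is confounded by pseudo-progression — persistent enhancement that is not
viable tumor. Serum alpha-fetoprotein (AFP), meanwhile, falls quickly and
deeply in true responders. This package implements composite criteria that
overlay an AFP rule on a size rule, centred on the **alpha-RECIST** rule:

> responder ⇔ RECIST 1.1 grants CR/PR **or** AFP_Δ ≤ −0.76
> (a ≥ 76% decrease), with new lesions / progression vetoing response,

where AFP_Δ = (AFP_FU − AFP_BL)/AFP_BL, and SLD is the sum of the longest
diameters of up to five target lesions (≤ 2 per organ, each ≥ 10 mm at
baseline). The full registry holds ten criteria: RECIST 1.1, mRECIST, and
the eight composites formed by {AFP change ≤ −0.76, baseline AFP ≥ 54.4
ng/ml} × {OR, AND} × {RECIST 1.1, mRECIST}.

Around the criterion engines the package provides:

* **Cutoff discovery** — maximally selected log-rank statistics: scan every
  admissible marker split (each side ≥ 10% of patients by default), keep the
  cutoff maximizing the two-group log-rank χ², and report a
  Miller–Siegmund-corrected p-value alongside the (anti-conservative) naive
  one.
* **Survival validation** — Kaplan–Meier curves and landmark rates, log-rank
  tests, univariate Cox hazard ratios (Efron ties), reverse-KM median
  follow-up.
* **Concordance** — weighted Cohen's kappa (linear weights over
  CR < PR < SD < PD) for inter-reader agreement, pathologic response
  categories from percent residual viable tumor, Spearman correlation for
  response–pathology association.
* **Synthetic cohorts** — a calibrated generator (lesion diameters,
  correlated size/AFP response mixtures, exponential recurrence with a
  responder hazard reduction, uniform censoring) so the whole pipeline is
  testable without patient data.

## Worked example

Simulate a 600-patient cohort in step-hazard mode (recurrence hazard drops
by the factor 0.31 for patients with AFP_Δ ≤ −0.76), classify it, rediscover
the AFP cutoff from survival, and validate the responder split:

```r
library(alphaRECIST)

cohort <- generate_cohort(generator_params(n = 600, seed = 42,
                                           mode = "step-hazard"))
tbl <- evaluate_cohort(cohort, resolve_criteria(c("RECIST 1.1", "alpha-RECIST")))
attr(tbl, "counts")
#> # A tibble: 2 × 7
#>   criterion  ascii                 CR    PR    SD    PD    NE
#> 1 RECIST 1.1 recist11               0   214   385     1     0
#> 2 αΔ-RECIST  alpha_delta_recist     0   313   286     1     0

p <- cohort$patients
delta <- (p$afp_fu - p$afp_bl) / p$afp_bl
optimal_cutpoint(delta, p$rfs_months, p$rfs_event)
#> <cutpoint_result> cutoff = -0.7584, chi-square = 110.626,
#>   naive p = 7.144e-26, corrected p = 1.751e-23 (groups 277/323)

cox_univariate(tbl$responder_alpha_delta_recist, p$rfs_months, p$rfs_event)
#> <cox> HR = 0.349 (0.277, 0.439), p = 3.674e-19, 321 events / 600
```

Reading the output: the composite rule reclassifies 99 size-stable patients
as responders (313 vs 214 PR). The scan rediscovers the planted AFP cutoff
(−0.7584 ≈ a 76% decrease) from survival alone, and the responders' hazard
ratio estimate (0.35) sits near the planted 0.31 — the criterion separates
the survival curves it was designed to separate. `run_full_analysis()` runs
every stage (classification, waterfalls, cutoffs, survival, agreement,
pathology concordance) and writes CSV tables plus a JSON manifest.

Cohorts round-trip through paired CSV files
(`<stem>_patients.csv`, `<stem>_lesions.csv`; see `?load_cohort` for the
column schema), so real measurements can be analysed with the identical
code path.

## Documentation

The methods vignette (`vignettes/alpha-recist-methods.Rmd`) describes the
category cascades and their edge policies, the cutoff-scan correction, the
generator's calibration anchors, and every documented discrepancy and
limitation. Function-level documentation covers the exported API.
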
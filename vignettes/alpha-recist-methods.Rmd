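---
title: "Composite AFP-imaging response criteria: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite AFP-imaging response criteria: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphaRECIST)
```

## The problem

Radiological response criteria for hepatocellular carcinoma (HCC) judge a
treatment by how much the tumor shrinks. RECIST 1.1 works on the sum of the
longest diameters (SLD) of up to five target lesions; mRECIST measures only
the arterially enhancing ("viable") portion, which suits HCC's
hypervascularity but is confounded after radiotherapy by pseudo-progression —
persistent enhancement that does not indicate viable tumor. After
conversion radiotherapy, true responders often show only modest size
shrinkage while serum alpha-fetoprotein (AFP) falls quickly and deeply.
Composite criteria therefore overlay an AFP rule on the size rule. The
selected composite, alpha-RECIST, calls a patient a responder when either
RECIST 1.1 grants CR/PR **or** AFP falls by at least 76% from baseline, with
new lesions or progression always vetoing response.

`alphaRECIST` implements this family of criteria end to end: the two base
category engines, all eight AFP composites (AFP change or baseline level,
combined by OR or AND with either base), survival-based cutoff discovery,
Kaplan–Meier / log-rank / Cox validation, inter-reader agreement, pathology
concordance, and a synthetic cohort generator that makes every stage testable
without patient data.

## The category engines

All changes are handled internally as signed fractions (-0.42 means a 42%
decrease); diameters are millimetres, times months, AFP ng/ml. Percentages
appear only at presentation time, and thresholds are compared on the exact
fractions — never on rounded display values — so classification is
deterministic.

The RECIST 1.1 cascade, applied to the target-lesion SLD with one designated
follow-up:

1. **PD** if new lesions appeared, non-target disease progressed, or the SLD
   grew at least 20% from the nadir **and** at least 5 mm in absolute terms.
   With a single follow-up the nadir is the baseline sum; with more
   timepoints the smallest prior sum would serve (the engine exposes this as
   its progression reference).
2. **CR** if all target lesions disappeared (SLD 0) and non-target disease is
   absent or resolved.
3. **PR** if the SLD fell at least 30% from baseline.
4. **SD** otherwise.

mRECIST runs the same cascade on the viable SLD, with CR meaning
disappearance of arterial enhancement in all target lesions and no
absolute-millimetre condition on PD. All thresholds are inclusive: exactly
-30% is PR, exactly -76% satisfies the AFP condition, +20% with exactly
5.0 mm is PD. Target-lesion selection keeps measurable lesions (>= 10 mm),
largest first, at most two per organ and five overall, with ties broken by
lesion id.

A composite criterion takes the base category first. Base PD (including new
lesions) is final. Otherwise the patient is a responder when the combiner is
satisfied: `or` — size response or AFP condition; `and` — both. The AFP
condition is either AFP change <= -0.76 (the `delta` component) or baseline
AFP >= 54.4 ng/ml (the `baseline` component). Responders retain CR when the
base granted CR and are labeled PR otherwise; non-responders are labeled SD.
This binary responder/non-responder layering is a design decision: the
composite rules are published only as a PR condition, and the cohorts they
describe contain no CR or PD, so the engine gives them total semantics by
keeping the base criterion's PD veto and folding all non-response into SD.

Two deliberate edge policies:

* **Missing AFP.** A patient without an AFP pair is *non-evaluable* (`"NE"`)
  under any AFP composite, and reported as such, rather than silently counted
  as SD. Counting them as SD would bias responder rates downward in data
  where AFP is missing not at random.
* **Baseline-AFP direction.** The baseline-AFP composites count
  AFP >= 54.4 ng/ml *toward* response, exactly as the rules are printed,
  although a high baseline AFP is usually a marker of poor prognosis. The
  implementation follows the printed direction verbatim and documents the
  surprise here; the orientation is an explicit parameter of the cutoff
  search, never inferred from data.

Useful algebra follows from the definitions and is enforced by tests: on any
cohort without PD patients, responders(AND) ⊆ responders(base) ⊆
responders(OR), and |OR| + |AND| = |base responders| + |AFP-rule satisfiers|.

## Cutoff discovery

The AFP cutoffs are treated as outputs of a survival-driven search, mirroring
how such cutoffs are found with cutoff-optimization tools (X-tile style): for
every admissible split of the marker (midpoints between consecutive distinct
values, each side keeping at least a fraction `min_frac` of patients, default
10%), dichotomize and compute the two-group log-rank chi-square against the
endpoint; return the argmax. Ties break toward the more balanced split, then
the smaller cutoff, making the scan deterministic. The tool's internal
algorithm is not published, so an exhaustive maximally-selected log-rank scan
was chosen as a standard, auditable equivalent; a brute-force re-computation
at every split (via an independent log-rank implementation) is asserted to
match exactly at small n.

Because the maximum over many correlated splits inflates the naive
chi-square, the naive p-value is anti-conservative. The reported
`corrected_p` uses the Miller–Siegmund approximation for the maximally
selected standardized statistic over the scanned quantile range, and is
reported as `max(naive_p, approximation)` capped at 1, so the correction can
only inflate the naive p. Under a null simulation (marker independent of
survival) the naive p rejects at well above its nominal level while the
corrected p holds it — the package's own tests verify both.

The recovered cutoff is reported at full precision; rendering `-0.7600` as
"76%" is purely a display convention.

## Survival statistics

Kaplan–Meier curves, survival rates at 12/24/36 months, log-rank tests,
univariate Cox hazard ratios for the responder indicator, and median
follow-up by reverse Kaplan–Meier (event/censor roles swapped; undefined when
nothing is censored — reported as a status, not a number). KM and Cox
estimation delegate to the `survival` package; ties use the Efron
approximation (month-resolution data make ties likely), and confidence
intervals are Wald on the log-hazard scale. KM medians are reported with
quartiles, matching how such cohorts summarize follow-up. The log-rank
statistic is computed in-package — the cutpoint scan needs it as a cheap
primitive — and is cross-checked in tests against `survival::survdiff`, a
from-scratch observed-minus-expected oracle, and the Cox score test. A level
with no events triggers a monotone-likelihood warning rather than a silent
divergent estimate.

## Agreement and pathology concordance

Inter-reader agreement uses weighted Cohen's kappa over the fixed category
order CR < PR < SD < PD, with linear similarity weights
`w_ij = 1 - |i - j|/3` by default. The choice of weights matters little for
the tables this package targets: when only two categories carry observations,
every weighting scheme yields the same kappa (the single off-diagonal weight
scales numerator and denominator alike), a property the tests assert on
random two-category tables. The kappa confidence interval uses the
large-sample (Fleiss–Cohen–Everitt) standard error and is *not* truncated at
1 by default, since published agreement tables of this kind print upper
bounds above 1; a truncation flag is available. Degenerate tables (all mass
in one category for both readers) return an explicit undefined status.

A documented discrepancy: the published dual-reader table for RECIST 1.1
prints kappa 0.89, but the confusion matrix forced by its margins (10/29 vs
12/27 with 37 agreements) yields 0.874 under linear, quadratic and unweighted
kappa alike. The package asserts only the mRECIST (0.95) and composite (1.00)
values, which do recompute from their margins.

Pathologic response categorizes percent residual viable tumor: complete
(exactly 0), major (under 50%), minor (at least 50%). The published bins
leave (0, 1%) unassigned; this implementation assigns it to major response.
The response–pathology association is mid-rank Spearman correlation, which
for binary–binary inputs equals the phi coefficient (tested identity). Its
confidence interval uses the Fisher z transform with `1/sqrt(n - 3)` — an
approximation documented as such; the method behind the printed interval for
the published point estimate (r = 0.0730) is unstated, so only the point
estimate is asserted.

## The synthetic cohort generator

No per-patient data accompany the study, so the generator is the stand-in
that gives every pipeline stage a testable input. It emulates the *structure*
the analysis assumes, with defaults calibrated once to the study's printed
anchors:

| Parameter | Default | Anchor / rationale |
|---|---|---|
| `responder_prob` | 0.5 | roughly balanced responder rates across criteria |
| `size_change_responder` | N(-0.35, 0.12) | responders cross the -30% size threshold often but not always |
| `size_change_nonresponder` | N(-0.05, 0.10) | minimal shrinkage typical after radiotherapy |
| `afp_delta_responder` | N(-0.85, 0.10) | deep AFP falls in responders, mass on both sides of -0.76 |
| `afp_delta_nonresponder` | N(-0.30, 0.25) | shallow, variable AFP changes |
| `afp_bl_frac_ge_200` | 0.487 | 48.7% of patients at or above 200 ng/ml baseline AFP |
| `afp_bl_sdlog` | 1.5 | AFP spans orders of magnitude; log-mean solved from the anchor |
| `baseline_sld_median_mm` | 70 | 7.0 cm median tumor size |
| `baseline_sld_sdlog` | 0.49 | matches the printed 4.9–9.5 cm interquartile range |
| `two_lesion_prob` | 0.05 | 94.9% of patients have a single target lesion |
| `responder_hr` | 0.31 | the published responder hazard ratio |
| `base_median_rfs_months` | 18 | non-responder recurrence scale |
| `censor_window` | U(12, 60) months | administrative censoring over a realistic accrual window |
| `planted_afp_cutoff` | -0.76 | step location in step-hazard mode |

Size and AFP changes are truncated at -1 (nothing shrinks more than 100%).
Viable diameters start as a uniform 60–95% fraction of each lesion's diameter
and shrink faster than total size in responders, so mRECIST responds earlier
than RECIST on the same patients. Recurrence times are exponential — chosen
for analytic tractability of the recovery tests, not as a claim about real
recurrence kinetics — with the hazard multiplied by `responder_hr` for the
favorable group: latent responders in `latent` mode, or patients with AFP
change at or below the planted cutoff in `step-hazard` mode. Overall survival
adds an exponential increment to the recurrence time, so recurrence-free
never exceeds overall survival. Pathology is drawn independently of response
(Beta(2, 1.6), about 56% mean viable fraction and roughly the published
major/minor split), mirroring the near-zero response–pathology correlation
observed in this setting. The simulated second reader flips the true category
to an adjacent one with a small probability, emulating near-miss inter-reader
disagreement.

What passing tests do and do not show: recovery of the planted cutoff and
hazard ratio demonstrates that the estimators are correct and adequately
powered at these effect sizes and sample sizes; it does not validate the
clinical criteria on real patients, where AFP assay noise, non-exponential
hazards, informative censoring, measurement error in diameters and multi-site
disease are all absent from the simulator.

Every random draw happens inside `withr::with_seed` with a mandatory
user-supplied seed; the generator neither reads nor perturbs the global RNG
stream.

## Numerical choices and degenerate inputs

* Thresholds are inclusive and compared on exact fractions (no pre-rounding).
* A baseline SLD of zero is an error (no measurable disease), not SD.
* Missing values are empty CSV cells, never sentinel numbers; doubles
  round-trip exactly through the shortest-representation writer.
* All-identical marker values give an explicit "no valid cutpoint" status.
* Survival queried beyond the last observed time returns the last estimate
  with an extrapolation flag and a warning.
* Log-rank with a singular variance matrix (a group exhausted before the
  first event) falls back to a generalized inverse.
* Waterfall tables sort descending with stable ties and keep patients with a
  missing quantity, flagged, at the bottom.

## Problem sizes

The test-suite simulations use the sizes the analyses are designed around:
cutoff recovery on twenty cohorts of 600 patients, hazard-ratio recovery on
one cohort of 2,000 and interval coverage on two hundred cohorts of 300,
null-calibration of the corrected p on five hundred cohorts of 100.
Calibration checks of the generator use a single cohort of 5,000. The whole
suite completes in about two minutes on one CPU.

## Command-line use

`inst/scripts/alpharecist.R` wraps the exported functions for shell use
(`simulate`, `classify`, `run-all`); the R functions themselves are the
primary interface, and `run_full_analysis()` writes every stage's CSV plus a
JSON manifest recording seed, settings and collected warnings.

## Limitations

Single designated follow-up (no multi-timepoint best-overall-response
adjudication beyond the nadir rule); two readers only (no Fleiss kappa);
no EASL or volumetric criteria; the composite rules' CR/PD semantics are the
package's documented completion of rules published only as PR conditions.
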
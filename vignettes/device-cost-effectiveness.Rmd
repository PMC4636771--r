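---
title: "Methods: a decision-analysis model of Pap-smear collection devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-analysis model of Pap-smear collection devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocea)
```

## The question

South Africa's public-sector cervical cancer screening programme takes
conventional Pap smears from roughly 372,000 HIV-infected women per year.
The recommended collection device, a wooden elongated-tip spatula, costs
about $0.02; the plastic Cervex-Brush ("broom") costs $0.22 but samples
the ecto- and endocervix simultaneously, so its smears contain endocervical
cells far more often (83% vs 53%). Because conventional cytology is much
more sensitive when endocervical cells are present, and because national
guidelines say an inadequate negative smear must be repeated, device choice
drives both the repeat-testing burden and the number of high-grade lesions
(HSIL) found. `cytocea` models that trade-off from the provider
perspective, in 2014 USD, for the HIV-infected cohort only.

## Model structure

Each woman has a fixed true status: negative, ASC-US, LSIL or HSIL, drawn
from the grade mix (fractions of all smears: 0.31 HSIL, 0.37 LSIL, 0.05
ASC-US). Each smear is an independent draw of:

1. endocervical presence (device-specific probability),
2. satisfactoriness for evaluation (0.98),
3. the laboratory read, for satisfactory smears only: true abnormalities
   are reported with sensitivity 0.76 (endocervical cells present) or
   0.40 / 0.32-for-HSIL (absent); true negatives are reported abnormal with
   probability 1 − specificity = 0.16. A seen abnormality is always
   reported, whether or not the slide met adequacy criteria.

Unsatisfactory smears cannot be read and are recalled under both practice
models. For smears read as negative:

- **guidelines practice** recalls the woman when the smear lacked
  endocervical cells;
- **typical practice** accepts the negative as final regardless of
  endocervical cells (inadequate negatives become potential false
  negatives).

A recalled woman re-enters with probability
$c = (1-\text{LTFU}) \times p_\text{repeat} = 0.92 \times 0.90 = 0.828$;
otherwise she is *lost to care*. Terminal states per true status are
absorbed in closed form from the per-round probabilities $(a, f, r)$
(reported abnormal, final negative, recall): with loop depth $K$ and
$q = rc$,

$$P(\text{reported}) = a \sum_{j=0}^{K-1} q^j, \qquad
  E[\text{smears}] = \sum_{j=0}^{K-1} q^j,$$

and analogously for final negatives and losses; $K = \infty$ gives the
geometric limits $a/(1-q)$ and $1/(1-q)$. Every smear taken costs one
outpatient visit ($8.36) + one laboratory test ($4.89) + one device; women
who return but receive no repeat are not charged a visit (only completed
Pap encounters are costed).

## Recall-loop depth: why the default is one repeat

The published description of the recall rule does not state how many times
a woman can be recalled, and depth changes results materially. We fixed the
default by internal consistency with the published results table rather
than by guessing:

- the spatula guidelines cost per woman ($16.79) implies
  E[smears] ≈ 16.79/13.27 = 1.27, which matches the depth-2 value
  $1 + \bar r c = 1.28$ at the tabled means, while absorption to
  $K=\infty$ gives 1.39;
- depth-2 reproduces both arms' HSIL detection counts to <1%, while the
  uncapped loop lets the spatula arm "catch up" through repeated re-tests
  and drives the incremental HSIL count negative — the opposite sign of
  the published finding;
- a depth-3 loop pushes the incremental HSIL count to about a third of its
  published value.

The default is therefore `max_rounds = 2` (initial smear plus at most one
repeat); `max_rounds = Inf` remains available for sensitivity analyses. A
woman whose final allowed smear still triggers a recall has no diagnosis
and is counted as lost to care.

## Accounting choices

**False positives in "abnormal smears detected".** The typical-practice
detection counts in the source table are only explainable when false
positives are included (TP ≈ 154k + FP ≈ 16k ≈ 172k), and the printed
equality between the incremental abnormal count and the decline in false
negatives holds exactly because the false-positive count is identical in
both arms under typical practice. `fp_in_detected = TRUE` is therefore the
default; true-positive-only accounting is a flag. False-positive women exit
at referral; no colposcopy costs are modelled.

**Cost per HSIL detected.** The headline incremental is the *difference of
the two cost-per-HSIL ratios* (that is the arithmetic the published table
prints); the incremental cost-effectiveness ratio
$\Delta\text{cost}/\Delta\text{HSIL}$ is computed as well but labelled
separately (`icer_cost_per_hsil`).

**Cohort size.** The HIV-infected cohort is `women_tested_annual ×
hiv_positive_fraction` per trial (mean 723,829 × 0.51 ≈ 369,000); the
tabled "HIV-infected women tested" row is carried in the registry as a
derived quantity but not used as an input.

**Known residual discrepancies.** Two guidelines-practice quantities do not
reproduce within 10% under any loop variant we found coherent with the
rest of the table: the incremental abnormal-detection count (the published
value implies nearly equal per-grade sensitivity gains, inconsistent with
the tabled grade-specific no-endocervical sensitivities that *do*
reproduce the typical-practice increments to ~1%), and the
guidelines-practice lost-to-care rows (the published counts sit between
the depth-2 and depth-3 variants). Both are reported as computed; the
acceptance checks for them fail honestly rather than being fitted.

## Parameters and sampling

All inputs live in `inst/extdata/parameters.yaml`: name, distribution
(`normal`, `proportion`, `point`), mean, 95% interval bounds, units,
source tag. Choices:

- The interval columns are read as 95% bounds (2.5th/97.5th percentiles),
  so the implied normal scale is $(\text{high}-\text{low})/(2 \times
  1.959964)$; a `quantiles = "p5p95"` switch reinterprets them as
  5th/95th percentiles.
- Proportions are sampled as symmetric truncated-normal variates matched
  to mean and bounds (the printed intervals are symmetric about their
  means); draws are truncated to $[0,1]$ by inverse-CDF, keeping the
  stream deterministic. Normal-family quantities (counts, odds ratios)
  are truncated below at zero.
- Point parameters (all unit costs, the USD/ZAR rate) never vary.
- The odds ratios for the broom's endocervical-cell effect (1.57),
  detection with vs without endocervical cells (1.89) and severe-atypia
  detection (2.46) are carried in the registry, but the tree consumes the
  tabled probabilities directly: applying the printed odds ratios to the
  printed base rates does not reproduce the tabled "calculated" values
  (e.g. OR 1.57 on 53% gives 64%, not 83%), so the derivation is treated
  as unstated and `or_apply()` is exposed as a utility for sensitivity
  analyses only.
- The broom's $0.22 table cost is used even though narrative text
  elsewhere says $0.23; the cost table is the input of record.

The PSA (`run_psa()`) draws one parameter set per trial — both device arms
share it (common random numbers), so incremental uncertainty reflects only
between-arm differences. The published incremental intervals are wider
than a paired design produces and are consistent with independently
sampled arms; since pairing affects intervals but not means, the paired
design is kept for its variance reduction. Intervals are reported both as
95% CIs of the mean ($\pm 1.96\,\mathrm{sd}/\sqrt{n}$, the default, whose
narrow widths match the published table) and as empirical 2.5/97.5
percentile intervals.

## The synthetic cohort and what passing tests show

`simulate_cohort()` draws women one at a time through the same branch
probabilities as the expectation engine and emits one laboratory-style
record per smear (woman id, round, true grade, endocervical presence,
satisfactoriness, reported result, disposition). Because the branch
probabilities are shared, tallies of these records validate the
*absorption algebra* — the recursion, loop cap and loss bookkeeping — not
the branch probabilities themselves; a second, independently hand-coded
scalar sampler in the test suite covers those. Oracle tests run at
$10^6$ women with a 4-standard-error tolerance (false-failure probability
well below 1%).

The generator emulates: per-smear independence of adequacy across rounds
(an explicit assumption of the model), a closed cohort with fixed true
status (no regression/persistence/progression between screens — excluded
by design), and no calendar-time dynamics. Real screening data would add
within-woman correlation of inadequate smears, clinic-level clustering
and secular trends in adequacy; passing tests therefore demonstrate
internal correctness of the model, not fidelity of these simplifications
to field data.

## Numerical choices and problem sizes

Terminal probabilities must sum to 1 within $10^{-9}$ per true state
before scaling (enforced at run time); cohort conservation is tested to
$10^{-6}$ relative. A recall loop with $rc = 1$ under unbounded depth is
rejected as non-convergent. Expected counts stay real-valued; rounding to
cents/integers happens only in rendering. Reproducibility is per
`(seed, trial)`: each trial derives its own RNG substream, so trial 42 is
identical whether run alone or inside a 10,000-trial PSA. The shipped
test suite uses 10,000-trial PSAs for the results-table checks,
$10^6$-woman microsimulations for oracle and recovery checks, and
2,500-vs-10,000-trial runs for the $1/\sqrt{n}$ interval-scaling check —
all chosen so the whole model remains a desk-scale computation (the full
suite runs in about a minute and a half).

## Limitations

- Costs and outcomes stop at screening: no colposcopy, treatment,
  patient-tracing or societal costs, no multi-year horizon, no
  discounting.
- The HIV-negative cohort, HPV testing and the AGC category (0.1% of
  reports) are out of scope.
- The loop depth is an inference from published outputs (documented
  above), not an observed protocol parameter.
- Specificity is applied uniformly regardless of endocervical presence,
  and the with-endocervical sensitivity is not grade-specific; the input
  tables provide no finer resolution.
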
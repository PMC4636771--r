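# cytocea

Decision-analysis model of conventional Pap-smear screening in HIV-infected
women, comparing two cervical cytology collection devices: the wooden
elongated-tip (Aylesbury) spatula currently on public tender, and the plastic
Cervex-Brush ("broom"). The broom costs eleven times more per device ($0.22
vs $0.02 in 2014 USD) but collects endocervical cells far more often (83% vs
53% of smears), and conventional cytology is substantially more sensitive
when endocervical cells are present. The package quantifies whether the more
expensive device pays for itself — through fewer repeat smears and more
high-grade lesions (HSIL) detected — in a national screening programme of
roughly 372,000 HIV-infected women per year.

The package is aimed at health economists and screening-programme analysts
who want a transparent, fully testable implementation of the model: every
input is a declarative parameter with a distribution, every branch
probability is inspectable, and a brute-force microsimulation validates the
cohort expectations.

## The model

Each woman entering the programme has a true cytological status drawn from
the grade mix (HSIL 31%, LSIL 37%, ASC-US 5%, negative 27%). A smear is
satisfactory for evaluation with probability 0.98 and contains endocervical
cells with a device-specific probability *p*<sub>endo</sub>. Satisfactory
smears are read:

- true abnormalities are reported with sensitivity 0.76 when endocervical
  cells are present, 0.40 when absent (0.32 for HSIL) — a detected
  abnormality is always reported, adequate slide or not;
- true negatives are reported abnormal (false positive) with probability
  1 − specificity = 0.16.

Two practice models differ in what happens to a smear read as negative:

- **guidelines (intended practice)** — recall the woman for a repeat if the
  smear lacked endocervical cells or was unsatisfactory;
- **typical practice** — repeat only unsatisfactory smears; an inadequate
  negative smear becomes a final (possibly false-negative) result.

A recalled woman returns with probability 0.92 and, once back, actually
receives the repeat with probability 0.90; otherwise she is *lost to care*
(no diagnosis). The default model allows one repeat smear per woman
(`max_rounds = 2`; an uncapped loop is available), with repeat adequacy
drawn independently of the first smear. Every smear taken costs one
outpatient visit ($8.36) + one laboratory test ($4.89) + one device.

Per device *d* and practice model, the engine computes terminal-state
probabilities in closed form from the per-round branch probabilities
(*a*, *f*, *r*) = (reported abnormal, final negative, recall), e.g. with
continuation *c* = 0.92 × 0.90 and a depth-2 loop,
P(detected) = *a*(1 + *rc*), and programme cost =
*n* · E[smears] · (visit + lab + device<sub>d</sub>). Parameter uncertainty
is propagated by Monte Carlo: 10,000 trials, each drawing one parameter set
(normal or truncated-symmetric proportion distributions matched to the
tabled means and 95% intervals) shared by both device arms.

## Worked example

```r
library(cytocea)

reg <- load_parameters()          # packaged default registry
p   <- param_means(reg)           # deterministic evaluation at the means
cs  <- cost_set(p)

for (dev in c("spatula", "broom")) {
  d <- device_profile(dev, p)
  print(cost_cohort(evaluate_cohort(p, d, "guidelines"), cs, d))
}
```

```
Economics (spatula, guidelines practice)
  annual programme cost:  $    6268113.69
  cost per woman:         $         16.98
  cost per HSIL detected: $         79.19
Economics (broom, guidelines practice)
  annual programme cost:  $    5527849.04
  cost per woman:         $         14.97
  cost per HSIL detected: $         64.79
```

Under intended practice the broom arm is *dominant*: the programme spends
about $0.74M less per year (each woman needs fewer repeat smears: 1.11
vs 1.28 on average), and detects more HSIL cases, so the cost per HSIL
case detected falls by about $14. A full probabilistic run with Table-style
output, per-trial CSV and a re-executable manifest:

```r
res <- run_analysis(run_config(n_trials = 10000, seed = 1,
                               output_dir = "out"))
res$tables$guidelines
```

The microsimulation doubles as a synthetic laboratory-record generator:

```r
rec <- simulate_cohort(p, "broom", "guidelines", n_women = 1e5, seed = 1)
tally_records(rec)                        # same shape as evaluate_cohort()
estimate_parameters_from_records(rec)     # recovers the generating rates
```

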
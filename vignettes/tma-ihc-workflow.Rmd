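---
title: "Four-tier IHC scoring and TMA cohort analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-tier IHC scoring and TMA cohort analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmascore)
```

## The analysis problem

Tissue microarrays (TMAs) let a single immunohistochemistry (IHC)
experiment stain thousands of 0.6 mm tumor cores under identical
conditions. For each spot a pathologist records two quantities: a
semi-quantitative staining intensity (0, 1+, 2+, 3+) and the percentage of
neoplastic cells that stain (0–100%). Some spots are non-interpretable
(no unequivocal tumor cells, or the core is lost during sectioning) and
carry no readout at all.

`tmascore` implements the downstream statistics of such a study: turning
the raw readouts into a four-tier ordinal score, tabulating per-entity
prevalence, testing staining-vs-phenotype associations, comparing survival
across staining groups, and dichotomizing expression values against a
normal reference. A simulator generates cohorts with the same statistical
structure so every stage can be validated without patient-level data,
which for studies of this kind is typically not published.

## The four-tier scoring rule

Each interpretable readout `(intensity, percent positive)` is mapped to
one of four ordered categories:

| intensity | percent positive | category |
|---|---|---|
| 0 (or 0% stained at any intensity) | — | negative |
| 1+ | ≤ 70 | weak |
| 1+ | > 70 | moderate |
| 2+ | ≤ 30 | weak |
| 2+ | (30, 70] | moderate |
| 2+ | > 70 | strong |
| 3+ | ≤ 30 | moderate |
| 3+ | > 30 | strong |

Three reading decisions were genuinely open and are fixed as follows:

* **One dominant pair per spot, not a per-intensity fraction vector.**
  A fraction-vector reading of the published wording (e.g. 70% at 1+ *and*
  10% at 2+) is neither exhaustive nor monotone; the pair reading gives a
  clean total partition of `{0..3} × [0, 100]` consistent with the two
  quantities a pathologist actually records.
* **The weak clause enumerates two disjoint branches** — (1+, ≤ 70) or
  (2+, ≤ 30) — rather than a conjunction; this is the only reading under
  which the four clauses partition the plane.
* **Zero percent stained is negative regardless of intensity**, since "no
  staining" takes priority over an intensity grade that cannot have been
  observed on 0% of cells.

Boundaries are closed on the left exactly as printed (70% at 1+ is weak,
71% is moderate; 30%/31% and 70%/71% for the other transitions), and
real-valued percentages are accepted. The test suite checks totality,
mutual exclusivity, monotonicity in both arguments, and the exact
transition points against an independent interval-lookup oracle on the
full half-percent grid (804 points).

A spot is **positive** when its category is weak or higher. Prevalence
tables report the four category percentages rounded *half-up* to one
decimal (base R rounds half to even, which does not reproduce published
pathology tables), and the positivity percentage is computed as
`100 − (unrounded negative fraction)` rather than by summing the three
rounded positive fractions — the two conventions differ by 0.1 exactly in
the way published cross-check figures reveal (e.g. 91.0 vs 90.9 for an
entity with parts 2.4 + 6.3 + 82.2).

## Association testing

`build_contingency()` cross-tabulates staining category against one
phenotype variable at a time, excluding missing values pairwise (so each
variable keeps its own n, as phenotype tables in this field do).
`chi_square()` is the plain Pearson test without continuity correction and
without an exact-test fallback, matching the commercial-package default
used in this literature; expected counts below 5 attach a warning but do
not block the test, and no multiple-testing adjustment is applied because
per-comparison raw p-values are the field's reporting convention. The
suite checks the statistic against its closed form, verifies invariance
under row/column permutation, compares p-values to a Monte-Carlo
permutation null, and confirms the type-I error rate on simulated
independent data.

## Survival analysis

Kaplan–Meier estimation, the k-sample log-rank test, and the Cox
proportional-hazards fit are delegated to the `survival` package behind a
cohort-aware interface; the unit tests cross-check the product-limit
estimates against an independently written textbook implementation.
Two modelling defaults matter:

* **The staining category enters the Cox model as a numeric 0–3 ordinal
  score** (one log-hazard-ratio per category step). The alternative
  one-coefficient-per-level coding is available via
  `category_coding = "factor"`; the ordinal default matches the
  "high level of staining" framing of prognostic claims in this
  literature and is what the simulator's hazard model generates.
* **Efron tie handling**, because follow-up is recorded in whole months
  and tied event times are therefore common.

Degenerate inputs are signalled, not silently absorbed: zero events make
the log-rank test undefined, single-level strata are refused, and
suspected monotone-likelihood Cox fits (|log HR| > 10) are flagged with a
warning.

## Expression z-score dichotomization

`zscore_vs_normal()` standardizes tumor expression values against the
mean and (n−1) standard deviation of a normal-tissue reference; values
are assumed already log-scaled and at least two reference samples with
nonzero spread are required. `dichotomize_z()` calls a sample
expression-high when `z > 2.0` strictly, one-sided: the contrast of
interest is overexpression, so under-expressing outliers stay in the
"low" group (a two-sided `|z| > t` mode is available). Boundary values go
to "low".

## The synthetic-cohort generator

`simulate_cohort()` emulates the structure the analysis assumes, not the
biology: per entity, a spot count, a non-interpretable dropout
probability, and a 4-simplex of category probabilities; optional
phenotype variables with marginal level frequencies; survival via an
exponential hazard `baseline × exp(log_hr_per_level × category)` censored
by a uniform entry time before one administrative horizon (default 250
months, reported as whole months so the minimum observable follow-up is
1 month).

Choices worth recording:

* **(intensity, percent) pairs are drawn uniformly over the category's
  region with percent on a 1% grid.** Pathologists estimate percentages
  coarsely; the grid avoids boundary ambiguity and guarantees that
  re-scoring a generated spot recovers the drawn category exactly — an
  invariant the suite checks spot-by-spot.
* **Phenotype effects are proportional-odds shifts** on the cumulative
  logits of the category distribution (`shift × level-index`), the
  simplest mechanism that produces the monotone stage-by-stage gradients
  seen in real staining-vs-phenotype tables. Shipped effect sizes are
  illustrative; real within-entity effect magnitudes are unknown.
* **One global seed** drives all draws of a configuration, so a cohort is
  a pure function of its config.
* **`calibrated_sim_config()`** transcribes the bundled 144-entity
  prevalence table (18,508 spots, 15,915 analyzable) into generator
  probabilities with a shared dropout of 0.144. With a shared dropout the
  expected cohort-level positivity is ~38.1% rather than the table's
  37.5%, because entities differ in their real interpretability rates and
  the uniform dropout re-weights them slightly; both values sit inside
  the 3-binomial-SE band used by the calibration checks, and the shared
  rate keeps the configuration to one interpretable parameter.

What the generator does **not** emulate: spatial TMA layout,
inter-observer scoring variability, within-entity correlation between
staining and unmodelled covariates, non-exponential hazards, and
informative censoring. Passing tests therefore validate the statistical
machinery, not any biological claim about a particular tumor entity.

## Numerical conventions and problem sizes

* Reported fractions: round half-up, one decimal (a small epsilon guards
  against binary-representation ties).
* File dialect: UTF-8, tab-delimited with comma auto-detection; `NA` or
  empty cells mean missing; write→read round-trips are lossless and
  tested property-style on randomized cohorts.
* Validation problem sizes: the operating-characteristic checks use
  1,000 replicates at n = 500 (chi-square type-I), 1,000 replicates at
  n = 400 (log-rank type-I), n = 1,000 for Cox parameter recovery, and
  n = 10,000 per entity for generator distribution recovery — large
  enough that the acceptance bands (3 Monte-Carlo/binomial SEs, 2 SEs
  for parameter recovery) are diagnostic, small enough that the whole
  suite runs in well under a minute per block.

## Known limitations

* The scoring rule takes the recorded pair as ground truth; whether a
  pathologist recorded the dominant or the maximal intensity on
  heterogeneous spots is upstream of this package.
* Published phenotype tables can only be reconstructed approximately from
  rounded percentages: re-deriving integer counts from one-decimal
  percentages reproduces a published mismatch-repair association at the
  same order of magnitude (p ≈ 3.5 × 10⁻⁴ vs a printed 2 × 10⁻⁴), not
  exactly — the unrounded per-patient data are not public.
* Chi-square and log-rank p-values are asymptotic; very sparse tables get
  a warning rather than an exact test.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- example_sim_config(seed = 7)
cohort <- simulate_survival(score_cohort(simulate_cohort(cfg)), cfg)
res <- run_full_analysis(cohort, adjust = c("pT", "pN"))
cat(res$summary, sep = "\n")
res$prevalence
res$survival$cox_adjusted
```

The `analysis/` directory of the source repository chains the same calls
into a five-step scripted workflow (simulate → score/prevalence →
associations → survival → expression groups) writing its tables under
`results/`.
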
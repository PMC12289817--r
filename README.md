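# tmascore

Statistical analysis of immunohistochemistry (IHC) staining readouts from
tissue-microarray (TMA) cohorts, for pathologists and biostatisticians
running large multi-entity biomarker surveys.

A TMA study stains thousands of 0.6 mm tumor cores in one experiment and
records, per spot, a staining intensity (0, 1+, 2+, 3+) and the
percentage of positive neoplastic cells; some spots are non-interpretable
and carry no readout. `tmascore` implements everything downstream of the
microscope:

* **Four-tier scoring** — the ordinal categorization at the core of the
  analysis. With intensity *i* and percent positive *p*:

  | category | rule |
  |---|---|
  | negative | *i* = 0 or *p* = 0 |
  | weak | (*i* = 1, *p* ≤ 70) or (*i* = 2, *p* ≤ 30) |
  | moderate | (*i* = 1, *p* > 70) or (*i* = 2, 30 < *p* ≤ 70) or (*i* = 3, *p* ≤ 30) |
  | strong | (*i* = 2, *p* > 70) or (*i* = 3, *p* > 30) |

  A spot is *positive* when weak or higher. The rule is a total,
  mutually exclusive, monotone partition of the readout plane (tested
  exhaustively against an independent oracle).
* **Prevalence tables** — per-entity category percentages and positivity
  rankings, with pathology-style rounding (half-up, one decimal;
  positivity as the complement of the unrounded negative fraction).
* **Phenotype associations** — staining category × stratum contingency
  tables with pairwise missing-data handling and plain Pearson χ² tests.
* **Survival** — Kaplan–Meier curves, k-sample log-rank tests, and Cox
  proportional-hazards fits (Efron ties; staining category as an ordinal
  0–3 score by default), via the `survival` package.
* **Expression dichotomization** — z-scores of tumor expression against a
  normal reference, *z* = (x − mean(normal)) / sd(normal), split at
  z > 2.0 into expression-high vs -low groups.
* **Synthetic cohorts** — a seeded generator with per-entity category
  probabilities, non-interpretable dropout, proportional-odds phenotype
  shifts, and category-dependent exponential hazards, so the whole
  pipeline is testable without patient-level data. A bundled
  144-entity prevalence table (15,915 analyzable spots) ships as a
  calibration reference (`load_reference_prevalence()`).

## Worked example

```r
library(tmascore)

cfg <- example_sim_config(seed = 7)                 # two synthetic entities
cohort <- simulate_survival(score_cohort(simulate_cohort(cfg)), cfg)
res <- run_full_analysis(cohort, adjust = c("pT", "pN"))
cat(res$summary, sep = "\n")
#> A total of 520 (86.7%) of 600 tumor samples were interpretable.
#> Staining was found in 326 (62.7%) of the 520 interpretable tumor samples,
#> including 23 (4.4%) with weak, 49 (9.4%) with moderate, and 254 (48.8%)
#> with strong positivity.
```

520 of the 600 simulated spots survived the 14.4% dropout; the rest of
the summary is the scored category breakdown. The prevalence table
separates the two entities — the mostly-strong one scores 96.3%
positive, the mostly-negative one 27.0%:

```r
res$prevalence[, c("entity", "pct_negative", "pct_strong", "pct_positive")]
#>   entity                     pct_negative pct_strong pct_positive
#> 1 Clear cell carcinoma-like          73.0        8.3         27.0
#> 2 Papillary carcinoma-like            3.7       86.9         96.3
```

Survival differs sharply across staining categories (the generator
planted a log-hazard increment of 0.5 per category step), and the Cox
fit recovers it after adjustment for pT and pN:

```r
res$survival$log_rank_by_category
#>   statistic df  p_value   n method
#> 1      178.  3 2.3e-38  520 log-rank
res$survival$cox_adjusted[1, c("term", "estimate", "hr", "se")]
#>   term     estimate   hr     se
#> 1 category    0.498 1.65 0.0406
```

Cross-checking the bundled prevalence reference:

```r
ref_prev <- load_reference_prevalence()
positivity_rate(ref_prev)[ref_prev$entity == "Papillary thyroid carcinoma"]
#> [1] 91
```

## Cohort file schema

`read_cohort()` / `write_cohort()` use UTF-8 TSV (comma auto-detected)
with columns:

```
spot_id  entity  interpretable  intensity  percent_positive  [strata...]  [time_months  event]
```

`interpretable` is logical; `intensity` ∈ {0,1,2,3} and
`percent_positive` ∈ [0,100] are required on interpretable spots and
ignored otherwise; `NA`/empty means missing. Any additional columns
(e.g. `pT`, `pN`, `grade`, molecular flags) are treated as phenotype
strata and analyzed pairwise-complete.

## Scripted workflow

`analysis/01_simulate_cohort.R` … `05_expression_groups.R` chain the
package functions into the full study workflow (simulate a calibrated
multi-entity cohort → score and tabulate prevalence → phenotype
associations → survival by category → expression z-score groups),
writing all tables under `results/`.

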
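#!/usr/bin/env Rscript

# Step 2: score the cohort with the four-tier rule and build the
# per-entity prevalence table and positivity ranking.

library(tmascore)

cohort <- read_cohort("results/cohort.tsv")
scored <- score_cohort(cohort)

prev <- summarize_by_entity(scored)
readr::write_tsv(prev, "results/prevalence.tsv")
readr::write_tsv(rank_entities(prev, "positivity"),
                 "results/ranking_positivity.tsv")
readr::write_tsv(rank_entities(prev, "strong"),
                 "results/ranking_strong.tsv")

counts <- category_counts(scored)
n_int <- sum(counts)
cat(sprintf(
  paste0("Staining in %d (%.1f%%) of %d interpretable spots: ",
         "%d weak, %d moderate, %d strong.\n"),
  sum(counts[2:4]), 100 * sum(counts[2:4]) / n_int, n_int,
  counts[["weak"]], counts[["moderate"]], counts[["strong"]]))
top <- rank_entities(prev, "positivity")
cat("Highest positivity:",
    paste(sprintf("%s (%.1f%%)", top$entity[1:3], top$rank_value[1:3]),
          collapse = ", "), "\n")
cat("Wrote results/prevalence.tsv and the two rankings\n")
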
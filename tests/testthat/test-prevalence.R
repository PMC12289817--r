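test_that("per-entity percentages reproduce a published thyroid row", {
  co <- cohort_from_counts(
    c(negative = 30, weak = 8, moderate = 21, strong = 273),
    n_noninterpretable = 59, entity = "Papillary thyroid carcinoma"
  )
  row <- summarize_by_entity(score_cohort(co))
  expect_identical(row$n_on_tma, 391L)
  expect_identical(row$n_analyzable, 332L)
  expect_equal(
    unlist(row[, c("pct_negative", "pct_weak", "pct_moderate",
                   "pct_strong")], use.names = FALSE),
    c(9.0, 2.4, 6.3, 82.2)
  )
  expect_equal(row$pct_positive, 91.0)
})

test_that("percentages equal an independent recount on a random cohort", {
  co <- score_cohort(random_cohort(500, seed = 21))
  prev <- summarize_by_entity(co)
  for (i in seq_len(nrow(prev))) {
    sub <- co[co$entity == prev$entity[i] & !is.na(co$category), ]
    expect_identical(prev$n_analyzable[i], nrow(sub))
    recount <- table(factor(as.character(sub$category),
                            levels = c("negative", "weak", "moderate",
                                       "strong")))
    expect_equal(
      as.numeric(unlist(prev[i, c("pct_negative", "pct_weak",
                                  "pct_moderate", "pct_strong")])),
      as.numeric(floor(1000 * recount / nrow(sub) + 0.5 + 1e-9) / 10)
    )
  }
  # count conservation across entities
  expect_identical(sum(prev$n_analyzable), sum(co$interpretable))
  expect_identical(sum(prev$n_on_tma), nrow(co))
})

test_that("all-negative and zero-analyzable entities are handled", {
  co <- cohort_from_counts(c(negative = 12, weak = 0, moderate = 0,
                             strong = 0))
  row <- summarize_by_entity(score_cohort(co))
  expect_equal(unlist(row[, c("pct_negative", "pct_weak", "pct_moderate",
                              "pct_strong")], use.names = FALSE),
               c(100, 0, 0, 0))
  expect_equal(positivity_rate(row), 0)

  none <- new_cohort("s1", "empty entity", FALSE, NA, NA)
  expect_warning(prev0 <- summarize_by_entity(score_cohort(none)),
                 "no analyzable spots")
  expect_true(is.na(prev0$pct_negative))
  expect_warning(expect_true(is.na(positivity_rate(prev0))))
})

test_that("positivity is the complement of the unrounded negative fraction", {
  ref_prev <- load_reference_prevalence()
  pos <- positivity_rate(ref_prev)
  thyroid <- ref_prev$entity == "Papillary thyroid carcinoma"
  # rounded positive parts sum to 90.9; the complement convention gives 91.0
  expect_equal(sum(ref_prev[thyroid, c("pct_weak", "pct_moderate",
                                   "pct_strong")]), 90.9)
  expect_equal(pos[thyroid], 91.0)
})

test_that("the bundled prevalence table satisfies its rounding invariants", {
  ref_prev <- load_reference_prevalence()
  expect_identical(nrow(ref_prev), 144L)
  expect_true(all(ref_prev$n_analyzable <= ref_prev$n_on_tma))
  expect_identical(sum(ref_prev$n_analyzable), 15915L)
  sums <- rowSums(ref_prev[, c("pct_negative", "pct_weak", "pct_moderate",
                           "pct_strong")])
  expect_true(all(abs(sums - 100) <= 0.2))
})

test_that("entity ranking sorts descending with alphabetical tie-break", {
  rows <- tibble::tibble(
    entity = c("b entity", "a entity", "c entity", "d entity"),
    n_analyzable = 100,
    pct_negative = c(9.0, 38.3, 9.0, 4.4),
    pct_strong = c(82.2, 11.7, 10.0, 55.6)
  )
  by_pos <- rank_entities(rows, "positivity")
  expect_identical(by_pos$entity,
                   c("d entity", "a entity", "b entity", "c entity")[c(1, 3, 4, 2)])
  expect_equal(by_pos$rank_value, sort(100 - rows$pct_negative,
                                       decreasing = TRUE))
  by_strong <- rank_entities(rows, "strong")
  expect_identical(by_strong$entity[1], "b entity")
  # brute-force oracle ordering
  ord <- order(-(100 - rows$pct_negative), rows$entity)
  expect_identical(rank_entities(rows, "positivity")$entity,
                   rows$entity[ord])
  expect_error(rank_entities(rows[0, ]), class = "tmascore_domain_error")
})
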
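test_that("the same seed reproduces the cohort exactly", {
  a <- simulate_cohort(example_sim_config(seed = 5))
  b <- simulate_cohort(example_sim_config(seed = 5))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_cohort(example_sim_config(seed = 6))
  expect_false(identical(a$intensity, c$intensity))
})

test_that("scoring recovers the drawn category for every generated spot", {
  co <- simulate_cohort(example_sim_config(seed = 7, n_on_tma = 2000L))
  sc <- score_cohort(co)
  ok <- !is.na(sc$true_category)
  expect_gt(sum(ok), 0)
  expect_identical(as.character(sc$category[ok]),
                   as.character(sc$true_category[ok]))
  # non-interpretable spots carry no readout
  expect_true(all(is.na(sc$intensity[!sc$interpretable])))
})

test_that("empirical category fractions recover the configured simplex", {
  probs <- c(0.4, 0.3, 0.2, 0.1)
  cfg <- simulation_config(
    entities = tibble::tibble(
      entity = "entity A", n_on_tma = 10000L, dropout_prob = 0,
      p_negative = probs[1], p_weak = probs[2], p_moderate = probs[3],
      p_strong = probs[4]),
    seed = 141
  )
  counts <- category_counts(score_cohort(simulate_cohort(cfg)))
  n <- sum(counts)
  for (j in 1:4) {
    se <- sqrt(probs[j] * (1 - probs[j]) / n)
    expect_lt(abs(counts[j] / n - probs[j]), 3 * se)
  }
})

test_that("phenotype shifts push higher levels towards higher categories", {
  cfg <- simulation_config(
    entities = tibble::tibble(
      entity = "entity A", n_on_tma = 12000L, dropout_prob = 0,
      p_negative = 0.4, p_weak = 0.3, p_moderate = 0.2, p_strong = 0.1),
    strata_effects = list(
      pT = list(levels = c("pT1", "pT2", "pT3"),
                marginal = c(1, 1, 1) / 3, shift = 1.0)),
    seed = 142
  )
  sc <- score_cohort(simulate_cohort(cfg))
  mean_level <- tapply(as.integer(sc$category) - 1, sc$pT, mean)
  expect_true(all(diff(mean_level[c("pT1", "pT2", "pT3")]) > 0))
  # and the association test sees it
  expect_lt(associate_strata(sc, "pT")$p_value[1], 1e-6)
})

test_that("simulated follow-up respects the administrative horizon", {
  cfg <- example_sim_config(seed = 8)
  co <- simulate_survival(score_cohort(simulate_cohort(cfg)), cfg)
  tm <- co$time_months[!is.na(co$time_months)]
  expect_true(all(tm >= 1 & tm <= cfg$censoring$horizon_months))
  expect_true(all(co$event[!is.na(co$event)] %in% 0:1))
  expect_true(all(is.na(co$time_months[!co$interpretable])))
})

test_that("a zero hazard increment yields exchangeable groups", {
  cfg <- simulation_config(
    entities = tibble::tibble(
      entity = "entity A", n_on_tma = 2000L, dropout_prob = 0,
      p_negative = 0.25, p_weak = 0.25, p_moderate = 0.25,
      p_strong = 0.25),
    hazard = list(baseline_rate = 0.01, log_hr_per_level = 0),
    seed = 143
  )
  co <- simulate_survival(score_cohort(simulate_cohort(cfg)), cfg)
  res <- log_rank(co$time_months, co$event, co$category)
  expect_gt(res$p_value, 0.001)
  fit <- cox_fit(co, "category")
  expect_lt(abs(fit$estimate), 3 * fit$se)
})

test_that("invalid configurations are rejected", {
  bad_simplex <- tibble::tibble(
    entity = "x", n_on_tma = 10L, dropout_prob = 0.1,
    p_negative = 0.5, p_weak = 0.5, p_moderate = 0.2, p_strong = 0.1)
  expect_error(simulation_config(bad_simplex),
               class = "tmascore_config_error")
  bad_dropout <- bad_simplex
  bad_dropout[, 4:7] <- list(0.4, 0.3, 0.2, 0.1)
  bad_dropout$dropout_prob <- 1.4
  expect_error(simulation_config(bad_dropout),
               class = "tmascore_config_error")
  expect_error(simulate_expression(10, 10, high_fraction = 2, shift = 1),
               class = "tmascore_config_error")
})

test_that("expression simulation is seeded and labels its components", {
  a <- simulate_expression(100, 30, 0.1, 3, seed = 9)
  b <- simulate_expression(100, 30, 0.1, 3, seed = 9)
  expect_identical(a, b)
  expect_identical(nrow(a$tumor), 100L)
  expect_identical(nrow(a$normal), 30L)
})

test_that("the calibrated configuration transcribes the bundled table", {
  cfg <- calibrated_sim_config(dropout = 0.144, seed = 10)
  ref_prev <- load_reference_prevalence()
  expect_identical(cfg$entities$entity, ref_prev$entity)
  expect_identical(sum(cfg$entities$n_on_tma), sum(ref_prev$n_on_tma))
  expect_equal(rowSums(cfg$entities[, c("p_negative", "p_weak",
                                        "p_moderate", "p_strong")]),
               rep(1, nrow(ref_prev)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cfg$entities$p_negative, ref_prev$pct_negative / 100,
               tolerance = 2e-3)
})
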
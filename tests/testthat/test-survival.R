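test_that("product-limit estimates match hand calculations", {
  # all censored: flat curve at 1
  flat <- km_estimate(c(3, 8, 12, 20, 30), rep(0, 5))
  expect_true(all(flat$survival == 1))
  expect_identical(attr(flat, "n_events"), 0L)

  # two subjects with events at 1 and 2: S = 0.5 on [1, 2), 0 after
  two <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(two$survival, c(0.5, 0))

  # censoring between events: S(1) = 3/4, S(3) = 3/8
  mix <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(mix$survival[mix$time == 1], 0.75)
  expect_equal(mix$survival[mix$time == 3], 0.75 * 0.5)
})

test_that("KM matches an independent textbook implementation on random data", {
  set.seed(71)
  for (rep in 1:3) {
    time <- ceiling(rexp(80, 0.05))
    event <- rbinom(80, 1, 0.6)
    got <- km_estimate(time, event)
    want <- km_oracle(time, event)
    expect_equal(got$survival[got$n_event > 0], want$survival,
                 tolerance = 1e-12)
  }
})

test_that("without censoring KM equals the empirical survival function", {
  set.seed(72)
  time <- sample(1:20, 40, replace = TRUE)
  got <- km_estimate(time, rep(1, 40))
  for (i in seq_len(nrow(got))) {
    expect_equal(got$survival[i], mean(time > got$time[i]))
  }
})

test_that("km_estimate rejects empty or negative input", {
  expect_error(km_estimate(numeric(), integer()),
               class = "tmascore_domain_error")
  expect_error(km_estimate(c(1, -2), c(1, 1)),
               class = "tmascore_domain_error")
})

test_that("log-rank: identical groups give statistic 0, relabeling changes nothing", {
  time <- c(5, 10, 15, 20, 25, 30)
  event <- c(1, 0, 1, 1, 0, 1)
  same <- log_rank(rep(time, 2), rep(event, 2), rep(c("a", "b"), each = 6))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  set.seed(81)
  time <- ceiling(rexp(90, 0.02))
  event <- rbinom(90, 1, 0.7)
  g <- sample(c("g1", "g2", "g3"), 90, replace = TRUE)
  a <- log_rank(time, event, g)
  relabeled <- c(g1 = "x", g2 = "y", g3 = "z")[g]
  b <- log_rank(time, event, relabeled)
  expect_equal(a$statistic, b$statistic)
  expect_identical(a$df, 2L)
})

test_that("log-rank refuses degenerate inputs", {
  expect_error(log_rank(1:5, rep(1, 5), rep("a", 5)),
               class = "tmascore_degenerate")
  expect_error(log_rank(1:6, rep(0, 6), rep(c("a", "b"), 3)),
               class = "tmascore_degenerate")
})

test_that("cox fit: identical groups give a near-zero coefficient", {
  set.seed(91)
  time <- ceiling(rexp(400, 0.02))
  event <- rbinom(400, 1, 0.8)
  d <- tibble::tibble(time_months = time, event = event,
                      arm = rep(0:1, each = 200))
  fit <- cox_fit(d, "arm")
  expect_lt(abs(fit$estimate), 2 * fit$se)
})

test_that("cox fit recovers a planted log-hazard ratio within 2 SE", {
  cfg <- simulation_config(
    entities = tibble::tibble(
      entity = "entity A", n_on_tma = 1000L, dropout_prob = 0,
      p_negative = 0.25, p_weak = 0.25, p_moderate = 0.25,
      p_strong = 0.25),
    hazard = list(baseline_rate = 0.01, log_hr_per_level = 0.7),
    censoring = list(horizon_months = 250),
    seed = 101
  )
  co <- simulate_survival(score_cohort(simulate_cohort(cfg)), cfg)
  fit <- cox_fit(co, "category")
  expect_lt(abs(fit$estimate - 0.7), 2 * fit$se)
})

test_that("adjusting for a mediator shrinks the category coefficient", {
  # hazard depends on category only through pT: the adjusted category
  # coefficient must move towards 0 relative to the unadjusted one
  set.seed(111)
  n <- 2000
  level <- sample(0:3, n, replace = TRUE)
  pT <- pmin(2, pmax(0, level - 1 + rbinom(n, 1, 0.2)))
  t_event <- rexp(n, 0.01 * exp(0.8 * pT))
  t_cens <- runif(n, 0, 250)
  d <- tibble::tibble(
    time_months = ceiling(pmin(t_event, t_cens)),
    event = as.integer(t_event <= t_cens),
    category = factor(c("negative", "weak", "moderate", "strong")[level + 1],
                      levels = c("negative", "weak", "moderate", "strong"),
                      ordered = TRUE),
    pT = pT
  )
  unadj <- cox_fit(d, "category")
  adj <- cox_fit(d, c("category", "pT"))
  cat_adj <- adj$estimate[adj$term == "category"]
  expect_gt(unadj$estimate, 0.2)  # mediation induces a marginal effect
  expect_lt(abs(cat_adj), abs(unadj$estimate) / 2)
})

test_that("cox fit refuses event-free data and flags missing columns", {
  d <- tibble::tibble(time_months = 1:5, event = 0L, x = rnorm(5))
  expect_error(cox_fit(d, "x"), class = "tmascore_degenerate")
  expect_error(cox_fit(d, "nosuch"), class = "tmascore_schema_error")
})
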
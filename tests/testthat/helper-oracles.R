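# Independent oracles and fixture builders used across the suite.

# Interval-lookup re-implementation of the four-tier rule: every clause is a
# row (intensity, (lo, hi] percent interval, category). Returns NA unless
# exactly one clause fires, so it doubles as a partition checker.
oracle_categorize <- function(intensity, percent) {
  if (intensity == 0 || percent == 0) {
    return("negative")
  }
  rules <- data.frame(
    intensity = c(1, 1, 2, 2, 2, 3, 3),
    lo = c(0, 70, 0, 30, 70, 0, 30),
    hi = c(70, 100, 30, 70, 100, 30, 100),
    category = c("weak", "moderate",
                 "weak", "moderate", "strong",
                 "moderate", "strong")
  )
  hit <- rules$intensity == intensity &
    percent > rules$lo & percent <= rules$hi
  if (sum(hit) != 1) {
    return(NA_character_)
  }
  rules$category[hit]
}

# Textbook product-limit estimator written independently of the survival
# package: loop over distinct event times, multiply (1 - d_i / n_i).
km_oracle <- function(time, event) {
  event_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = event_times, survival = NA_real_)
  for (i in seq_along(event_times)) {
    t_i <- event_times[i]
    n_i <- sum(time >= t_i)
    d_i <- sum(time == t_i & event == 1)
    s <- s * (1 - d_i / n_i)
    out$survival[i] <- s
  }
  out
}

# Pearson statistic written from the formula, for permutation nulls.
pearson_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Monte-Carlo permutation p-value: expand the table to paired label vectors,
# shuffle one margin, recount.
perm_chi2_p <- function(tab, n_perm = 10000) {
  rows <- rep(rep(seq_len(nrow(tab)), ncol(tab)), as.vector(tab))
  cols <- rep(rep(seq_len(ncol(tab)), each = nrow(tab)), as.vector(tab))
  obs <- pearson_stat(tab)
  hits <- 0
  for (b in seq_len(n_perm)) {
    perm <- table(rows, sample(cols))
    if (pearson_stat(perm) >= obs - 1e-9) hits <- hits + 1
  }
  (1 + hits) / (1 + n_perm)
}

# Representative (intensity, percent) readout inside each category region.
representative_pair <- function(category) {
  switch(category,
    negative = c(0, 0), weak = c(1, 50),
    moderate = c(2, 50), strong = c(3, 80))
}

# Cohort with exact category counts (plus non-interpretable spots), for
# arithmetic checks against printed totals.
cohort_from_counts <- function(counts, n_noninterpretable = 0,
                               entity = "entity A") {
  cats <- rep(names(counts), counts)
  pairs <- t(vapply(cats, representative_pair, numeric(2)))
  n_int <- length(cats)
  n <- n_int + n_noninterpretable
  new_cohort(
    spot_id = sprintf("s%06d", seq_len(n)),
    entity = entity,
    interpretable = rep(c(TRUE, FALSE), c(n_int, n_noninterpretable)),
    intensity = c(pairs[, 1], rep(NA, n_noninterpretable)),
    percent_positive = c(pairs[, 2], rep(NA, n_noninterpretable))
  )
}

# Randomized valid cohort for round-trip and recount properties.
random_cohort <- function(n, seed, with_survival = FALSE) {
  set.seed(seed)
  interpretable <- runif(n) > 0.15
  intensity <- ifelse(interpretable, sample(0:3, n, replace = TRUE), NA)
  percent <- ifelse(interpretable,
                    round(runif(n, 0, 100), 2), NA)
  percent[!is.na(intensity) & intensity == 0] <- 0
  strata <- tibble::tibble(
    grade = sample(c("G1", "G2", "G3", NA), n, replace = TRUE),
    pN = sample(c("pN0", "pN+"), n, replace = TRUE)
  )
  tm <- ev <- NULL
  if (with_survival) {
    tm <- round(runif(n, 1, 250))
    ev <- rbinom(n, 1, 0.4)
  }
  new_cohort(
    spot_id = sprintf("s%05d", seq_len(n)),
    entity = sample(c("entity A", "entity B", "entity C"), n,
                    replace = TRUE),
    interpretable = interpretable,
    intensity = intensity,
    percent_positive = percent,
    strata = strata,
    time_months = tm, event = ev
  )
}
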
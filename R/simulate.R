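#' Configure a synthetic TMA cohort
#'
#' Bundles and validates everything the simulator needs: per-entity spot
#' numbers, non-interpretable dropout and staining-category probabilities;
#' optional phenotype variables with a proportional-odds shift linking them
#' to the staining category; optional category-dependent exponential
#' hazards with administrative censoring.
#'
#' @param entities data frame with columns `entity`, `n_on_tma`,
#'   `dropout_prob`, and category probabilities `p_negative`, `p_weak`,
#'   `p_moderate`, `p_strong` (each row summing to 1).
#' @param strata_effects optional named list, one element per phenotype
#'   variable: `list(levels = <character>, marginal = <probabilities>,
#'   shift = <numeric>)`. For a spot at the k-th level (k = 0, 1, ...),
#'   the staining-category distribution is shifted on the cumulative-logit
#'   scale by `shift * k`, so positive shifts push higher levels towards
#'   higher staining categories.
#' @param hazard optional `list(baseline_rate = <events/month>,
#'   log_hr_per_level = <numeric>)`: event times are exponential with rate
#'   `baseline_rate * exp(log_hr_per_level * category_level)` where the
#'   category level is scored 0-3.
#' @param censoring `list(horizon_months = <months>)`; per-subject censoring
#'   times are uniform on (0, horizon), i.e. staggered entry with one
#'   administrative cutoff. Follow-up is reported in whole months.
#' @param seed integer seed; all draws of [simulate_cohort()] and
#'   [simulate_survival()] descend from it.
#' @return a validated `tmascore_sim_config` list.
#' @export
simulation_config <- function(entities, strata_effects = NULL,
                              hazard = list(baseline_rate = 0.01,
                                            log_hr_per_level = 0.5),
                              censoring = list(horizon_months = 250),
                              seed = 1L) {
  entities <- tibble::as_tibble(entities)
  needed <- c("entity", "n_on_tma", "dropout_prob",
              "p_negative", "p_weak", "p_moderate", "p_strong")
  missing_cols <- setdiff(needed, names(entities))
  if (length(missing_cols) > 0) {
    abort(paste0("entities is missing: ",
                 paste(missing_cols, collapse = ", ")),
          class = "tmascore_config_error")
  }
  probs <- as.matrix(entities[, c("p_negative", "p_weak",
                                  "p_moderate", "p_strong")])
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-6)) {
    abort("category probabilities must be a 4-simplex per entity",
          class = "tmascore_config_error")
  }
  if (any(entities$dropout_prob < 0 | entities$dropout_prob > 1)) {
    abort("dropout_prob must be in [0, 1]", class = "tmascore_config_error")
  }
  if (!is.null(hazard) && hazard$baseline_rate <= 0) {
    abort("baseline hazard rate must be positive",
          class = "tmascore_config_error")
  }
  for (nm in names(strata_effects)) {
    se <- strata_effects[[nm]]
    if (length(se$levels) != length(se$marginal) ||
        abs(sum(se$marginal) - 1) > 1e-6) {
      abort(paste0("stratum ", nm,
                   ": marginal must be a simplex over its levels"),
            class = "tmascore_config_error")
    }
  }
  structure(
    list(entities = entities, strata_effects = strata_effects,
         hazard = hazard, censoring = censoring, seed = as.integer(seed)),
    class = "tmascore_sim_config"
  )
}

#' A small two-entity example configuration
#'
#' One entity with mostly strong staining and one mostly negative, a
#' three-level `pT` phenotype pushing higher stages towards higher staining
#' categories, and a category-dependent hazard. Used in examples and as a
#' quick pipeline smoke-test input.
#'
#' @param seed integer seed.
#' @param n_on_tma spots per entity.
#' @return a `tmascore_sim_config`.
#' @export
example_sim_config <- function(seed = 1L, n_on_tma = 300L) {
  simulation_config(
    entities = tibble::tibble(
      entity = c("Papillary carcinoma-like", "Clear cell carcinoma-like"),
      n_on_tma = n_on_tma,
      dropout_prob = 0.144,
      p_negative = c(0.10, 0.85),
      p_weak = c(0.05, 0.06),
      p_moderate = c(0.10, 0.05),
      p_strong = c(0.75, 0.04)
    ),
    strata_effects = list(
      pT = list(levels = c("pT1", "pT2", "pT3"),
                marginal = c(0.5, 0.3, 0.2), shift = 0.8),
      pN = list(levels = c("pN0", "pN+"),
                marginal = c(0.7, 0.3), shift = 0.5)
    ),
    hazard = list(baseline_rate = 0.01, log_hr_per_level = 0.5),
    censoring = list(horizon_months = 250),
    seed = seed
  )
}

# The (intensity, percent) cells making up each category's region of the
# scoring partition, with percent on a 1% grid. Pairs are drawn uniformly
# from these cells, so every generated readout maps back to its category.
category_region <- function(category) {
  switch(category,
    negative = cbind(intensity = 0L, percent = 0L),
    weak = rbind(cbind(intensity = 1L, percent = 1:70),
                 cbind(intensity = 2L, percent = 1:30)),
    moderate = rbind(cbind(intensity = 1L, percent = 71:100),
                     cbind(intensity = 2L, percent = 31:70),
                     cbind(intensity = 3L, percent = 1:30)),
    strong = rbind(cbind(intensity = 2L, percent = 71:100),
                   cbind(intensity = 3L, percent = 31:100))
  )
}

# Per-row category probabilities after a proportional-odds shift eta:
# P(cat <= j) = plogis(qlogis(gamma_j) - eta).
shift_category_probs <- function(base_probs, eta) {
  gamma <- cumsum(base_probs)[1:3]
  out <- matrix(NA_real_, nrow = length(eta), ncol = 4,
                dimnames = list(NULL, STAIN_LEVELS))
  g <- vapply(gamma, function(gj) plogis(qlogis(gj) - eta),
              numeric(length(eta)))
  g <- matrix(g, ncol = 3)
  out[, 1] <- g[, 1]
  out[, 2] <- g[, 2] - g[, 1]
  out[, 3] <- g[, 3] - g[, 2]
  out[, 4] <- 1 - g[, 3]
  out
}

#' Simulate a multi-entity TMA cohort
#'
#' For each configured entity, draws `n_on_tma` spots: each is
#' non-interpretable with its entity's dropout probability; phenotype
#' levels are drawn from their marginals; each interpretable spot draws a
#' staining category from the (possibly phenotype-shifted) multinomial and
#' then an (intensity, percent positive) pair uniformly from that
#' category's region of the scoring partition, so scoring the cohort
#' recovers the drawn category exactly.
#'
#' @param config a [simulation_config()].
#' @return an unscored cohort tibble; the drawn category is kept in the
#'   `true_category` column for checks.
#' @export
#' @examples
#' co <- simulate_cohort(example_sim_config(seed = 42))
#' table(score_cohort(co)$category)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "tmascore_sim_config"))
  set.seed(config$seed)
  ents <- config$entities
  pieces <- vector("list", nrow(ents))
  offset <- 0L
  for (i in seq_len(nrow(ents))) {
    n <- ents$n_on_tma[i]
    interpretable <- runif(n) >= ents$dropout_prob[i]
    strata <- NULL
    eta <- rep(0, n)
    if (!is.null(config$strata_effects)) {
      strata <- lapply(config$strata_effects, function(se) {
        k <- sample.int(length(se$levels), n, replace = TRUE,
                        prob = se$marginal)
        eta <<- eta + se$shift * (k - 1)
        factor(se$levels[k], levels = se$levels)
      })
      strata <- tibble::as_tibble(strata)
    }
    base <- as.numeric(ents[i, c("p_negative", "p_weak",
                                 "p_moderate", "p_strong")])
    probs <- shift_category_probs(base, eta)
    u <- runif(n)
    cum <- t(apply(probs, 1, cumsum))
    cat_idx <- rowSums(u > cum) + 1L
    category <- STAIN_LEVELS[cat_idx]
    intensity <- rep(NA_integer_, n)
    percent <- rep(NA_real_, n)
    for (lev in STAIN_LEVELS) {
      idx <- which(interpretable & category == lev)
      if (length(idx) > 0) {
        region <- category_region(lev)
        cell <- sample.int(nrow(region), length(idx), replace = TRUE)
        intensity[idx] <- region[cell, "intensity"]
        percent[idx] <- region[cell, "percent"]
      }
    }
    out <- new_cohort(
      spot_id = sprintf("spot%06d", offset + seq_len(n)),
      entity = ents$entity[i],
      interpretable = interpretable,
      intensity = intensity,
      percent_positive = percent,
      strata = strata
    )
    out$true_category <- factor(
      ifelse(interpretable, category, NA_character_),
      levels = STAIN_LEVELS, ordered = TRUE)
    pieces[[i]] <- out
    offset <- offset + n
  }
  cohort <- dplyr::bind_rows(pieces)
  attr(cohort, "strata") <- names(config$strata_effects)
  cohort
}

#' Attach simulated survival outcomes to a scored cohort
#'
#' Event times are exponential with rate `baseline_rate *
#' exp(log_hr_per_level * level)` where the staining category is scored
#' 0-3; censoring times are uniform on (0, horizon). Observed follow-up is
#' the rounded-up minimum of the two (whole months, so tied event times
#' occur as in real follow-up), with the event flag set when the event
#' precedes censoring. Spots without a staining category (non-interpretable)
#' get missing outcomes.
#'
#' @param cohort a scored cohort (must have a `category` column).
#' @param config a [simulation_config()] with a `hazard` element.
#' @return the cohort with `time_months` and `event` columns.
#' @export
simulate_survival <- function(cohort, config) {
  stopifnot(inherits(config, "tmascore_sim_config"))
  if (!"category" %in% names(cohort)) {
    abort("cohort is not scored; run score_cohort() first",
          class = "tmascore_schema_error")
  }
  if (is.null(config$hazard)) {
    abort("config has no hazard element", class = "tmascore_config_error")
  }
  strata <- cohort_strata(cohort)
  set.seed(config$seed + 1L)
  level <- as.integer(factor(as.character(cohort$category),
                             levels = STAIN_LEVELS)) - 1L
  n <- nrow(cohort)
  rate <- config$hazard$baseline_rate *
    exp(config$hazard$log_hr_per_level * level)
  horizon <- config$censoring$horizon_months
  t_event <- rexp(n, rate = ifelse(is.na(rate), 1, rate))
  t_cens <- runif(n, 0, horizon)
  time <- ceiling(pmin(t_event, t_cens))
  event <- as.integer(t_event <= t_cens)
  time[is.na(level)] <- NA_real_
  event[is.na(level)] <- NA_integer_
  cohort$time_months <- time
  cohort$event <- event
  attr(cohort, "strata") <- strata
  cohort
}

#' Simulate tumor and normal expression vectors
#'
#' Normal reference values are Normal(mu, sigma); each tumor sample is,
#' independently with probability `high_fraction`, drawn from the shifted
#' component Normal(mu + shift * sigma, sigma) and otherwise from the
#' reference distribution. Values play the role of already log-scaled
#' expression measurements.
#'
#' @param n_tumor,n_normal sample sizes.
#' @param high_fraction probability that a tumor sample is shifted.
#' @param shift component shift in reference-SD units.
#' @param seed integer seed.
#' @param mu,sigma reference mean and SD.
#' @return list with tibbles `tumor` (`sample_id`, `value`, `shifted`) and
#'   `normal` (`sample_id`, `value`).
#' @export
simulate_expression <- function(n_tumor, n_normal, high_fraction, shift,
                                seed = 1L, mu = 10, sigma = 1) {
  if (high_fraction < 0 || high_fraction > 1) {
    abort("high_fraction must be in [0, 1]",
          class = "tmascore_config_error")
  }
  set.seed(seed)
  normal <- rnorm(n_normal, mu, sigma)
  shifted <- runif(n_tumor) < high_fraction
  tumor <- rnorm(n_tumor, mu + ifelse(shifted, shift * sigma, 0), sigma)
  list(
    tumor = tibble::tibble(
      sample_id = sprintf("tumor%04d", seq_len(n_tumor)),
      value = tumor, shifted = shifted),
    normal = tibble::tibble(
      sample_id = sprintf("normal%04d", seq_len(n_normal)),
      value = normal)
  )
}

#' Generator configuration calibrated to the bundled prevalence table
#'
#' Builds a [simulation_config()] whose entities, spot numbers and
#' staining-category probabilities transcribe the bundled multi-entity
#' prevalence table ([load_reference_prevalence()]), with a common
#' non-interpretable dropout probability. Simulating it reproduces, in
#' expectation, the table's per-entity category distributions and the
#' cohort-level interpretable fraction.
#'
#' @param dropout shared dropout probability (default 0.144, the bundled
#'   table's overall non-interpretable fraction).
#' @param seed integer seed.
#' @param hazard,censoring,strata_effects passed to [simulation_config()].
#' @return a `tmascore_sim_config` covering all 144 entities
#'   (18,508 spots).
#' @export
calibrated_sim_config <- function(dropout = 0.144, seed = 1L,
                                  hazard = list(baseline_rate = 0.01,
                                                log_hr_per_level = 0.5),
                                  censoring = list(horizon_months = 250),
                                  strata_effects = NULL) {
  ref <- load_reference_prevalence()
  probs <- as.matrix(ref[, c("pct_negative", "pct_weak",
                             "pct_moderate", "pct_strong")])
  probs <- probs / rowSums(probs)  # printed percentages sum to 100 +- 0.2
  simulation_config(
    entities = tibble::tibble(
      entity = ref$entity,
      n_on_tma = ref$n_on_tma,
      dropout_prob = dropout,
      p_negative = probs[, 1],
      p_weak = probs[, 2],
      p_moderate = probs[, 3],
      p_strong = probs[, 4]
    ),
    strata_effects = strata_effects,
    hazard = hazard, censoring = censoring, seed = seed
  )
}
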
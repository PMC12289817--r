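#' Cross-tabulate staining category against a phenotype stratum
#'
#' Counts spots by stratum level (rows) and staining category (columns) over
#' spots where both are non-missing. Levels with no observations are dropped
#' with a message.
#'
#' @param cohort a scored cohort.
#' @param stratum name of a phenotype column.
#' @param levels optional character vector fixing the row order; defaults to
#'   factor levels or sorted unique values.
#' @return an integer matrix with stratum levels as rows and the four
#'   staining categories as columns.
#' @export
#' @examples
#' co <- score_cohort(simulate_cohort(example_sim_config(seed = 1)))
#' build_contingency(co, "pT")
build_contingency <- function(cohort, stratum, levels = NULL) {
  if (!"category" %in% names(cohort)) {
    abort("cohort is not scored; run score_cohort() first",
          class = "tmascore_schema_error")
  }
  if (!stratum %in% names(cohort)) {
    abort(paste0("unknown stratum: ", stratum),
          class = "tmascore_schema_error")
  }
  x <- cohort[[stratum]]
  lev <- levels %||% (if (is.factor(x)) base::levels(x)
                      else sort(unique(x[!is.na(x)])))
  keep <- !is.na(x) & !is.na(cohort$category)
  counts <- table(
    factor(x[keep], levels = lev),
    factor(as.character(cohort$category[keep]), levels = STAIN_LEVELS)
  )
  counts <- unclass(counts)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    inform(paste0("dropping empty level(s) of ", stratum, ": ",
                  paste(rownames(counts)[empty], collapse = ", ")))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (nrow(counts) < 2) {
    abort(paste0("stratum ", stratum,
                 " has fewer than 2 non-empty levels"),
          class = "tmascore_degenerate")
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Pearson chi-square test of a contingency table
#'
#' Plain Pearson chi-square without continuity correction, with expected
#' counts from the row/column margins and the p-value from the upper tail
#' of the chi-square distribution with `(r-1)(c-1)` degrees of freedom.
#' Columns or rows with zero margin are dropped first; a warning is attached
#' when any expected count falls below 5 (the test is still computed).
#'
#' @param counts a non-negative integer matrix (e.g. from
#'   [build_contingency()]).
#' @return a one-row tibble: `statistic`, `df`, `p_value`, `n`,
#'   `min_expected`, `method`.
#' @export
#' @examples
#' chi_square(matrix(c(20, 5, 5, 20), nrow = 2))  # statistic 18, p ~ 2e-5
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers",
          class = "tmascore_domain_error")
  }
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("fewer than 2 non-empty rows or columns",
          class = "tmascore_degenerate")
  }
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  if (any(expected == 0)) {
    abort("zero expected count", class = "tmascore_degenerate")
  }
  if (any(expected < 5)) {
    warn("expected counts below 5; chi-square approximation may be poor")
  }
  fit <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = unname(fit$p.value),
    n = n,
    min_expected = min(expected),
    method = "Pearson chi-squared (no continuity correction)"
  )
}

#' Phenotype association report
#'
#' For each requested stratum, tabulates the per-level staining-category
#' percentages with the level n and the chi-square p-value — the layout of a
#' published staining-vs-phenotype table. Degenerate strata (fewer than two
#' non-empty levels) are skipped with a message.
#'
#' @param cohort a scored cohort.
#' @param strata character vector of phenotype column names; defaults to
#'   all declared strata.
#' @return a tibble with columns `stratum`, `level`, `n`, the four
#'   `pct_*` columns, `statistic`, `df`, and `p_value` (test results
#'   repeated across the stratum's rows).
#' @export
associate_strata <- function(cohort, strata = cohort_strata(cohort)) {
  res <- lapply(strata, function(s) {
    tab <- tryCatch(build_contingency(cohort, s),
                    tmascore_degenerate = function(e) NULL)
    if (is.null(tab)) {
      inform(paste0("skipping degenerate stratum: ", s))
      return(NULL)
    }
    test <- suppressWarnings(chi_square(tab))
    n_lev <- rowSums(tab)
    pct <- round_half_up(100 * tab / n_lev)
    tibble::tibble(
      stratum = s,
      level = rownames(tab),
      n = as.integer(n_lev),
      pct_negative = unname(pct[, "negative"]),
      pct_weak = unname(pct[, "weak"]),
      pct_moderate = unname(pct[, "moderate"]),
      pct_strong = unname(pct[, "strong"]),
      statistic = test$statistic,
      df = test$df,
      p_value = test$p_value
    )
  })
  dplyr::bind_rows(res)
}
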
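#' Run the full TMA analysis workflow
#'
#' Scores a cohort, builds the per-entity prevalence table and positivity
#' ranking, tests staining-vs-phenotype associations for the requested
#' strata, and — when follow-up columns are present — compares survival
#' across staining categories (log-rank) and fits a covariate-adjusted
#' proportional-hazards model. A plain-text summary block reports the
#' interpretable fraction and the overall category fractions.
#'
#' All outputs are deterministic functions of the input cohort, so
#' re-running on identical inputs writes byte-identical tables.
#'
#' @param cohort a cohort tibble (see [read_cohort()]).
#' @param strata phenotype columns to test; defaults to all declared
#'   strata. Degenerate strata are skipped with a message.
#' @param adjust covariates for the adjusted hazards fit (in addition to
#'   the staining category), e.g. `c("pT", "pN")`; used only when survival
#'   columns are present.
#' @param out_dir optional directory; when given, every table is written
#'   there as TSV along with `summary.txt`.
#' @return a list with elements `scored`, `validation`, `prevalence`,
#'   `ranking`, `associations`, `survival` (`NULL` without follow-up:
#'   otherwise log-rank result and hazard fits), and `summary` (character
#'   vector of summary lines).
#' @export
#' @examples
#' co <- simulate_cohort(example_sim_config(seed = 7))
#' res <- run_full_analysis(co)
#' cat(res$summary, sep = "\n")
run_full_analysis <- function(cohort, strata = cohort_strata(cohort),
                              adjust = NULL, out_dir = NULL) {
  if (nrow(cohort) == 0) {
    abort("empty cohort", class = "tmascore_schema_error")
  }
  scored <- score_cohort(cohort)
  validation <- validate_cohort(scored)
  prevalence <- summarize_by_entity(scored)
  ranking <- rank_entities(prevalence, key = "positivity")
  strata <- intersect(strata, names(scored))
  associations <- if (length(strata) > 0) {
    associate_strata(scored, strata)
  } else {
    NULL
  }

  surv <- NULL
  if (all(COHORT_SURV_COLS %in% names(scored)) &&
      any(!is.na(scored$time_months))) {
    ok <- !is.na(scored$time_months) & !is.na(scored$category)
    surv <- list(
      log_rank_by_category = tryCatch(
        log_rank(scored$time_months[ok], scored$event[ok],
                 scored$category[ok]),
        tmascore_degenerate = function(e) NULL),
      cox_unadjusted = tryCatch(
        cox_fit(scored, "category"),
        tmascore_degenerate = function(e) NULL)
    )
    if (length(adjust) > 0) {
      surv$cox_adjusted <- tryCatch(
        cox_fit(scored, c("category", adjust)),
        tmascore_degenerate = function(e) NULL)
    }
  }

  counts <- category_counts(scored)
  n_pos <- sum(counts[c("weak", "moderate", "strong")])
  n_int <- validation$n_interpretable
  pct <- function(k, n) {
    format(round_half_up(100 * k / max(n, 1), 1), nsmall = 1)
  }
  summary_lines <- c(
    sprintf("A total of %d (%s%%) of %d tumor samples were interpretable.",
            n_int, pct(n_int, validation$n_spots), validation$n_spots),
    sprintf(paste0(
      "Staining was found in %d (%s%%) of the %d interpretable tumor ",
      "samples, including %d (%s%%) with weak, %d (%s%%) with moderate, ",
      "and %d (%s%%) with strong positivity."),
      n_pos, pct(n_pos, n_int), n_int,
      counts[["weak"]], pct(counts[["weak"]], n_int),
      counts[["moderate"]], pct(counts[["moderate"]], n_int),
      counts[["strong"]], pct(counts[["strong"]], n_int))
  )

  res <- list(scored = scored, validation = validation,
              prevalence = prevalence, ranking = ranking,
              associations = associations, survival = surv,
              summary = summary_lines)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(scored, file.path(out_dir, "scored_cohort.tsv"))
    readr::write_tsv(prevalence, file.path(out_dir, "prevalence.tsv"))
    readr::write_tsv(ranking, file.path(out_dir, "ranking.tsv"))
    if (!is.null(associations)) {
      readr::write_tsv(associations, file.path(out_dir, "associations.tsv"))
    }
    if (!is.null(surv$log_rank_by_category)) {
      readr::write_tsv(surv$log_rank_by_category,
                       file.path(out_dir, "log_rank.tsv"))
    }
    if (!is.null(surv$cox_adjusted)) {
      readr::write_tsv(surv$cox_adjusted,
                       file.path(out_dir, "cox_adjusted.tsv"))
    }
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }
  res
}
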
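#' Per-entity prevalence of staining categories
#'
#' Builds one row per tumor entity with the number of spots on the TMA, the
#' number of analyzable (scored) spots, the percentage of spots in each of
#' the four staining categories, and the overall positivity percentage.
#' Percentages are rounded half-up to one decimal; `pct_positive` is the
#' complement of the *unrounded* negative fraction, so it can differ from
#' the sum of the three rounded positive-category percentages.
#'
#' @param cohort a scored cohort (see [score_cohort()]).
#' @return a tibble with columns `entity`, `n_on_tma`, `n_analyzable`,
#'   `n_negative` .. `n_strong`, `pct_negative` .. `pct_strong`, and
#'   `pct_positive`, sorted by entity. Entities with no analyzable spots
#'   get `NA` percentages and a warning.
#' @export
#' @examples
#' co <- score_cohort(simulate_cohort(example_sim_config(seed = 1)))
#' summarize_by_entity(co)
summarize_by_entity <- function(cohort) {
  if (!"category" %in% names(cohort)) {
    abort("cohort is not scored; run score_cohort() first",
          class = "tmascore_schema_error")
  }
  out <- cohort |>
    dplyr::group_by(.data$entity) |>
    dplyr::summarise(
      n_on_tma = dplyr::n(),
      n_analyzable = sum(!is.na(.data$category)),
      n_negative = sum(.data$category == "negative", na.rm = TRUE),
      n_weak = sum(.data$category == "weak", na.rm = TRUE),
      n_moderate = sum(.data$category == "moderate", na.rm = TRUE),
      n_strong = sum(.data$category == "strong", na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$entity)
  frac <- function(k, n) ifelse(n > 0, 100 * k / n, NA_real_)
  out$pct_negative <- round_half_up(frac(out$n_negative, out$n_analyzable))
  out$pct_weak <- round_half_up(frac(out$n_weak, out$n_analyzable))
  out$pct_moderate <- round_half_up(frac(out$n_moderate, out$n_analyzable))
  out$pct_strong <- round_half_up(frac(out$n_strong, out$n_analyzable))
  out$pct_positive <- round_half_up(
    100 - frac(out$n_negative, out$n_analyzable))
  if (any(out$n_analyzable == 0)) {
    warn(paste0("entities with no analyzable spots: ",
                paste(out$entity[out$n_analyzable == 0], collapse = ", ")))
  }
  out
}

#' Positivity rate of prevalence rows
#'
#' The positivity rate is 100 minus the negative percentage, computed on
#' unrounded fractions where raw counts are available (output of
#' [summarize_by_entity()]) and from `pct_negative` otherwise (e.g. on a
#' transcribed published table), then rounded half-up to one decimal.
#'
#' @param rows a prevalence tibble with `pct_negative` (and optionally
#'   `n_negative`/`n_analyzable`).
#' @return numeric vector of positivity percentages, `NA` (with a warning)
#'   where no spot is analyzable.
#' @export
#' @examples
#' ref_prev <- load_reference_prevalence()
#' pos <- positivity_rate(ref_prev)
#' pos[ref_prev$entity == "Papillary thyroid carcinoma"]  # 91.0
positivity_rate <- function(rows) {
  if (all(c("n_negative", "n_analyzable") %in% names(rows))) {
    out <- ifelse(rows$n_analyzable > 0,
                  round_half_up(100 * (1 - rows$n_negative / rows$n_analyzable)),
                  NA_real_)
  } else {
    out <- round_half_up(100 - rows$pct_negative)
    if ("n_analyzable" %in% names(rows)) {
      out[rows$n_analyzable == 0] <- NA_real_
    }
  }
  if (anyNA(out)) {
    warn("positivity rate undefined for entities without analyzable spots")
  }
  out
}

#' Rank entities by positivity
#'
#' Stable descending sort of prevalence rows by overall positivity or by the
#' strong-positivity percentage; ties are broken alphabetically by entity.
#'
#' @param rows a prevalence tibble.
#' @param key `"positivity"` (default) or `"strong"`.
#' @return the rows, reordered, with a `rank_value` column.
#' @export
rank_entities <- function(rows, key = c("positivity", "strong")) {
  key <- match.arg(key)
  if (nrow(rows) == 0) {
    abort("no prevalence rows to rank", class = "tmascore_domain_error")
  }
  value <- switch(key,
    positivity = positivity_rate(rows),
    strong = rows$pct_strong
  )
  rows$rank_value <- value
  rows[order(-value, rows$entity), , drop = FALSE]
}

#' Published multi-entity HMGA2 prevalence table
#'
#' A machine-readable transcription of a published prevalence table of
#' HMGA2 immunostaining across 144 tumor entities (15,915 analyzable of
#' 18,508 listed spots), bundled for cross-checks and for calibrating the
#' synthetic-cohort generator. Columns follow [summarize_by_entity()]'s
#' percentage columns.
#'
#' @return a tibble with `entity`, `n_on_tma`, `n_analyzable`, and the four
#'   category percentages.
#' @export
load_reference_prevalence <- function() {
  path <- system.file("extdata", "hmga2_tma_prevalence.tsv",
                      package = "tmascore", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    entity = readr::col_character(),
                    n_on_tma = readr::col_integer(),
                    n_analyzable = readr::col_integer(),
                    .default = readr::col_double()
                  ))
}
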
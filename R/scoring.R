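#' Four-tier categorization of IHC staining readouts
#'
#' Classifies each (intensity, percent positive) readout into one of four
#' ordered categories. The rule partitions the readout plane:
#'
#' * **negative**: no staining (intensity 0, or 0% positive cells);
#' * **weak**: 1+ intensity in at most 70% of cells, or 2+ intensity in at
#'   most 30% of cells;
#' * **moderate**: 1+ intensity in more than 70%, 2+ intensity in 31-70%,
#'   or 3+ intensity in at most 30% of cells;
#' * **strong**: 2+ intensity in more than 70%, or 3+ intensity in more
#'   than 30% of cells.
#'
#' Boundaries are closed on the left as printed (70% at 1+ is still weak;
#' 71% is moderate). Real-valued percentages are allowed; the interval
#' 31-70 at 2+ is treated as (30, 70].
#'
#' @param intensity integer vector of staining intensities in `0:3`.
#' @param percent_positive numeric vector of percentages in `[0, 100]`.
#' @return an ordered factor with levels
#'   `negative < weak < moderate < strong`. `NA` inputs (non-interpretable
#'   spots) give `NA`.
#' @export
#' @examples
#' categorize_staining(c(0, 1, 1, 2, 2, 3), c(0, 70, 71, 50, 75, 30))
categorize_staining <- function(intensity, percent_positive) {
  n <- max(length(intensity), length(percent_positive))
  intensity <- rep_len(as.numeric(intensity), n)
  percent_positive <- rep_len(as.numeric(percent_positive), n)
  known <- !is.na(intensity) & !is.na(percent_positive)
  if (any(known & !(intensity %in% 0:3))) {
    abort("intensity must be in {0, 1, 2, 3}", class = "tmascore_domain_error")
  }
  if (any(known & (percent_positive < 0 | percent_positive > 100))) {
    abort("percent_positive must be in [0, 100]",
          class = "tmascore_domain_error")
  }
  p <- percent_positive
  out <- rep(NA_character_, n)
  out[known & (intensity == 0 | p == 0)] <- "negative"
  stained <- known & intensity > 0 & p > 0
  out[stained & intensity == 1 & p <= 70] <- "weak"
  out[stained & intensity == 1 & p > 70] <- "moderate"
  out[stained & intensity == 2 & p <= 30] <- "weak"
  out[stained & intensity == 2 & p > 30 & p <= 70] <- "moderate"
  out[stained & intensity == 2 & p > 70] <- "strong"
  out[stained & intensity == 3 & p <= 30] <- "moderate"
  out[stained & intensity == 3 & p > 30] <- "strong"
  factor(out, levels = STAIN_LEVELS, ordered = TRUE)
}

#' Positivity of a staining category
#'
#' A spot is positive if its category is weak or higher.
#'
#' @param category factor (or character) of staining categories.
#' @return logical vector; `NA` for `NA` categories.
#' @export
binarize_positivity <- function(category) {
  as.character(category) != "negative"
}

#' Score a cohort
#'
#' Appends `category` (ordered factor) and `positive` (logical) columns to a
#' cohort table. Non-interpretable spots get `NA` in both.
#'
#' @param cohort a cohort tibble (see [new_cohort()]).
#' @return the cohort with `category` and `positive` columns.
#' @export
score_cohort <- function(cohort) {
  assert_cohort(cohort)
  strata <- cohort_strata(cohort)
  cohort$category <- categorize_staining(cohort$intensity,
                                         cohort$percent_positive)
  cohort$positive <- binarize_positivity(cohort$category)
  attr(cohort, "strata") <- strata
  cohort
}

#' Category counts of a scored cohort
#'
#' @param cohort a scored cohort (see [score_cohort()]), or a factor of
#'   categories.
#' @return named integer vector of counts over the four categories; sums to
#'   the number of interpretable (scored) spots.
#' @export
category_counts <- function(cohort) {
  cat <- if (is.data.frame(cohort)) {
    if (!"category" %in% names(cohort)) {
      abort("cohort is not scored; run score_cohort() first",
            class = "tmascore_schema_error")
    }
    cohort$category
  } else {
    cohort
  }
  cat <- factor(as.character(cat), levels = STAIN_LEVELS)
  c(table(cat))
}
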
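#' Cohort tables
#'
#' A cohort table holds one row per TMA spot with columns `spot_id`, `entity`,
#' `interpretable`, `intensity`, `percent_positive`, optional phenotype
#' (stratum) columns, and optional survival columns `time_months` and `event`.
#' Stratum column names are carried in the `"strata"` attribute so downstream
#' analyses know which columns are phenotype variables.
#'
#' @name cohort
NULL

#' Construct a cohort table from columns
#'
#' Validates types and invariants and returns a tibble with the `"strata"`
#' attribute set. Non-interpretable spots must not carry staining readouts;
#' their `intensity` and `percent_positive` are forced to `NA`.
#'
#' @param spot_id character vector of unique spot identifiers.
#' @param entity character vector of tumor entity labels.
#' @param interpretable logical vector; `FALSE` marks spots without
#'   unequivocal tumor cells (no readout).
#' @param intensity integer staining intensity in `0:3` (`NA` where not
#'   interpretable).
#' @param percent_positive percentage of positive neoplastic cells in
#'   `[0, 100]` (`NA` where not interpretable).
#' @param strata optional named list or data frame of phenotype columns
#'   (e.g. `pT`, `pN`, `grade`), character or factor valued.
#' @param time_months,event optional survival follow-up (months) and event
#'   indicator (0/1 or logical).
#' @return a cohort tibble.
#' @export
#' @examples
#' new_cohort(
#'   spot_id = c("s1", "s2"), entity = "ccRCC",
#'   interpretable = c(TRUE, FALSE),
#'   intensity = c(2L, NA), percent_positive = c(80, NA)
#' )
new_cohort <- function(spot_id, entity, interpretable, intensity,
                       percent_positive, strata = NULL,
                       time_months = NULL, event = NULL) {
  tbl <- tibble::tibble(
    spot_id = as.character(spot_id),
    entity = as.character(entity),
    interpretable = as.logical(interpretable),
    intensity = as.integer(intensity),
    percent_positive = as.numeric(percent_positive)
  )
  strata_names <- character()
  if (!is.null(strata)) {
    strata <- tibble::as_tibble(strata)
    strata_names <- names(strata)
    tbl <- dplyr::bind_cols(tbl, strata)
  }
  if (!is.null(time_months)) {
    tbl$time_months <- as.numeric(time_months)
    tbl$event <- as.integer(event)
  }
  attr(tbl, "strata") <- strata_names
  assert_cohort(tbl)
  tbl
}

#' Names of phenotype columns of a cohort
#' @param cohort a cohort tibble.
#' @return character vector of stratum column names.
#' @export
cohort_strata <- function(cohort) {
  s <- attr(cohort, "strata", exact = TRUE)
  if (is.null(s)) {
    known <- c(COHORT_CORE_COLS, COHORT_SURV_COLS,
               "category", "positive")
    s <- setdiff(names(cohort), known)
  }
  s
}

# Hard validation used by constructors and readers. Collects every violation
# with a row locator before failing, so a bad file is diagnosed in one pass.
assert_cohort <- function(cohort, source = "cohort") {
  missing_cols <- setdiff(COHORT_CORE_COLS, names(cohort))
  if (length(missing_cols) > 0) {
    abort(
      paste0(source, ": missing mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "tmascore_schema_error"
    )
  }
  problems <- character()
  bad_row <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(
        what, " (row ", paste(head(rows, 10), collapse = ", "),
        if (length(rows) > 10) ", ..." else "", ")"
      ))
    }
  }
  dup <- which(duplicated(cohort$spot_id))
  bad_row(dup, "duplicate spot_id")
  bad_row(which(is.na(cohort$spot_id)), "missing spot_id")
  bad_row(which(is.na(cohort$interpretable)), "missing interpretable flag")
  interp <- !is.na(cohort$interpretable) & cohort$interpretable
  bad_row(which(interp & !(cohort$intensity %in% 0:3)),
          "intensity outside {0,1,2,3} on interpretable spot")
  pp <- cohort$percent_positive
  bad_row(which(interp & (is.na(pp) | pp < 0 | pp > 100)),
          "percent_positive outside [0,100] on interpretable spot")
  if ("time_months" %in% names(cohort)) {
    tm <- cohort$time_months
    bad_row(which(!is.na(tm) & tm < 0), "negative time_months")
    bad_row(which(!is.na(tm) & !(cohort$event %in% 0:1)),
            "event not 0/1 where time_months is present")
  }
  if (length(problems) > 0) {
    abort(paste0(source, ": invalid rows:\n  ",
                 paste(problems, collapse = "\n  ")),
          class = "tmascore_row_error")
  }
  invisible(cohort)
}

#' Read a cohort table from a TSV/CSV file
#'
#' The delimiter (tab or comma) is detected from the header line. `"NA"` and
#' empty cells mean missing. Rows violating the type invariants (intensity
#' outside `0:3`, percent positive outside `[0, 100]`, duplicate spot ids)
#' are rejected with row-level diagnostics. Staining readouts of
#' non-interpretable spots are dropped to `NA`.
#'
#' @param path file to read.
#' @param strata optional character vector naming the phenotype columns;
#'   defaults to every column that is not a core or survival column.
#' @return a validated cohort tibble (see [new_cohort()]).
#' @export
read_cohort <- function(path, strata = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path),
          class = "tmascore_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  header_cols <- gsub('^"|"$', "", strsplit(header, delim, fixed = TRUE)[[1]])
  missing_cols <- setdiff(COHORT_CORE_COLS, header_cols)
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tmascore_schema_error")
  }
  tbl <- readr::read_delim(
    path, delim = delim, na = c("", "NA"), show_col_types = FALSE,
    col_types = readr::cols(
      spot_id = readr::col_character(),
      entity = readr::col_character(),
      interpretable = readr::col_logical(),
      intensity = readr::col_integer(),
      percent_positive = readr::col_double(),
      .default = readr::col_guess()
    )
  )
  rp <- readr::problems(tbl)
  if (nrow(rp) > 0) {
    abort(paste0(
      "unparseable cells in ", path, ": ",
      paste(sprintf("row %d col %s (expected %s)", rp$row, rp$col,
                    rp$expected), collapse = "; ")
    ), class = "tmascore_row_error")
  }
  if ("category" %in% names(tbl)) {
    tbl$category <- factor(tbl$category, levels = STAIN_LEVELS,
                           ordered = TRUE)
  }
  # readouts on non-interpretable spots are undefined by construction
  noint <- !is.na(tbl$interpretable) & !tbl$interpretable
  tbl$intensity[noint] <- NA_integer_
  tbl$percent_positive[noint] <- NA_real_
  if (is.null(strata)) {
    strata <- setdiff(names(tbl), c(COHORT_CORE_COLS, COHORT_SURV_COLS,
                                    "category", "positive"))
  } else {
    missing_strata <- setdiff(strata, names(tbl))
    if (length(missing_strata) > 0) {
      abort(paste0("declared strata not present: ",
                   paste(missing_strata, collapse = ", ")),
            class = "tmascore_schema_error")
    }
  }
  attr(tbl, "strata") <- strata
  assert_cohort(tbl, source = path)
  tbl
}

#' Write a cohort table to a tab-delimited file
#'
#' Columns are written in canonical order (core columns, strata, survival,
#' derived scoring columns) and numeric values keep full precision, so that
#' `read_cohort(write_cohort(x))` reproduces `x`.
#'
#' @param cohort a cohort tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  assert_cohort(cohort)
  strata <- intersect(cohort_strata(cohort), names(cohort))
  ord <- c(COHORT_CORE_COLS, strata,
           intersect(COHORT_SURV_COLS, names(cohort)),
           intersect(c("category", "positive"), names(cohort)))
  ord <- c(ord, setdiff(names(cohort), ord))
  readr::write_tsv(cohort[, ord], path)
  invisible(path)
}

#' Summarize cohort completeness
#'
#' Report-only validation: counts of interpretable vs non-interpretable
#' spots (with the interpretable percentage rounded half-up to one decimal)
#' and per-column missingness. Never fails.
#'
#' @param cohort a cohort tibble.
#' @return a list with elements `n_spots`, `n_interpretable`,
#'   `pct_interpretable`, and `missingness` (a tibble of per-column counts
#'   of missing values).
#' @export
#' @examples
#' co <- simulate_cohort(example_sim_config(seed = 1))
#' validate_cohort(co)$pct_interpretable
validate_cohort <- function(cohort) {
  n <- nrow(cohort)
  n_int <- sum(cohort$interpretable %in% TRUE)
  miss <- tibble::tibble(
    column = names(cohort),
    n_missing = unname(vapply(cohort, function(x) sum(is.na(x)),
                              integer(1)))
  )
  list(
    n_spots = n,
    n_interpretable = n_int,
    pct_interpretable = if (n > 0) round_half_up(100 * n_int / n, 1)
                        else NA_real_,
    missingness = miss
  )
}
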
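#' Incidence table of age-by-calendar-year strata
#'
#' Validates and classes a data frame of registry-style incidence strata
#' with columns `age` (integer years), `year` (calendar year of diagnosis),
#' `cases` (non-negative integer count) and `py` (person-years).  The birth
#' cohort `cohort = year - age` is derived per row; rows with cohorts after
#' `max_cohort` are excluded (late cohorts contribute too few cases), as are
#' rows outside the optional age window.  Zero person-year rows are dropped
#' with a warning.
#'
#' @param x a data frame with columns `age`, `year`, `cases`, `py` (the
#'   alias `person_years` is accepted).
#' @param population optional population label stored as an attribute.
#' @param max_cohort latest birth cohort retained (default 1960).
#' @param min_age,max_age optional age filters (unconstrained by default).
#' @return A data frame of class `incidence_table` with derived `cohort`
#'   column and attributes `population` and `n_excluded` (rows removed by
#'   the cohort/age filters).
#' @examples
#' tbl <- incidence_table(data.frame(age = 60:64, year = 2000,
#'                                   cases = c(3, 1, 0, 2, 4), py = 1e5))
#' attr(tbl, "n_excluded")
#' @export
incidence_table <- function(x, population = NA_character_, max_cohort = 1960,
                            min_age = NULL, max_age = NULL) {
  x <- as.data.frame(x)
  if ("person_years" %in% names(x) && !"py" %in% names(x))
    names(x)[names(x) == "person_years"] <- "py"
  need <- c("age", "year", "cases", "py")
  if (!all(need %in% names(x)))
    stop("incidence table needs columns: ", paste(need, collapse = ", "))
  x <- x[need]
  if (any(x$age < 0) || any(x$age != round(x$age)))
    stop("'age' must be non-negative integers")
  if (any(x$cases < 0) || any(x$cases != round(x$cases)))
    stop("'cases' must be non-negative integers")
  if (any(x$py < 0)) stop("'py' must be non-negative")
  if (anyDuplicated(x[c("age", "year")]))
    stop("duplicate (age, year) strata")
  if (any(x$py == 0 & x$cases > 0))
    stop("strata with cases > 0 must have positive person-years")
  if (any(x$py == 0)) {
    warning(sum(x$py == 0), " zero person-year strata dropped")
    x <- x[x$py > 0, , drop = FALSE]
  }
  x$cohort <- x$year - x$age
  keep <- x$cohort <= max_cohort
  if (!is.null(min_age)) keep <- keep & x$age >= min_age
  if (!is.null(max_age)) keep <- keep & x$age <= max_age
  n_excluded <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  rownames(x) <- NULL
  structure(x, population = population, max_cohort = max_cohort,
            n_excluded = n_excluded,
            class = c("incidence_table", "data.frame"))
}

#' Read an incidence table from delimited text
#'
#' Reads a header-carrying delimited file with columns `age`, `year`,
#' `cases`, `py` (or `person_years`) and applies the validation and
#' cohort-exclusion rules of [incidence_table()], reporting the number of
#' excluded rows.
#'
#' @param path file path.
#' @param sep field separator (default: any whitespace).
#' @inheritParams incidence_table
#' @return An `incidence_table`.
#' @export
read_incidence_table <- function(path, sep = "", population = NA_character_,
                                 max_cohort = 1960, min_age = NULL,
                                 max_age = NULL) {
  raw <- read.table(path, header = TRUE, sep = sep)
  tbl <- incidence_table(raw, population = population,
                         max_cohort = max_cohort,
                         min_age = min_age, max_age = max_age)
  message(sprintf("read %d strata (%d excluded by cohort/age filters)",
                  nrow(tbl), attr(tbl, "n_excluded")))
  tbl
}

#' Write an incidence table as tab-delimited text
#'
#' @param x an `incidence_table` (or compatible data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_incidence_table <- function(x, path) {
  write.table(x[c("age", "year", "cases", "py")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf(
    "incidence table: %d strata, ages %d-%d, years %d-%d, %d cases\n",
    nrow(x), min(x$age), max(x$age), min(x$year), max(x$year), sum(x$cases)))
  if (!is.na(attr(x, "population")))
    cat("  population:", attr(x, "population"), "\n")
  NextMethod()
}
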
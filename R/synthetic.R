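#' Person-year schedule for synthetic incidence tables
#'
#' Builds a smooth, positive person-year surface over single-year
#' age-by-diagnosis-year strata, optionally scaled per birth cohort to
#' emulate registry cohort structure.  Magnitudes are order-of-magnitude
#' stand-ins for registry person-year tables, not fits to any registry.
#'
#' @param years diagnosis years (default the SEER9-like window 1975-2016).
#' @param ages single ages at diagnosis (default 0-84).
#' @param base_py person-years per stratum before cohort scaling.
#' @param cohort_shape optional function of birth year returning a positive
#'   multiplier.
#' @return A data frame with columns `age`, `year`, `py`.
#' @examples
#' sched <- make_py_schedule(1975:1980, 50:60, base_py = 2e5)
#' nrow(sched)  # 66 strata
#' @export
make_py_schedule <- function(years = 1975:2016, ages = 0:84, base_py = 1e5,
                             cohort_shape = NULL) {
  stopifnot(length(years) >= 1, length(ages) >= 1, base_py > 0)
  g <- expand.grid(age = as.integer(ages), year = as.integer(years))
  mult <- if (is.null(cohort_shape)) 1 else cohort_shape(g$year - g$age)
  if (any(mult <= 0)) stop("'cohort_shape' must return positive multipliers")
  data.frame(age = g$age, year = g$year, py = base_py * mult)
}

#' Generate a synthetic incidence table under known parameters
#'
#' Draws independent Poisson case counts with mean `h(age + 0.5; B) * py`
#' for every stratum of a person-year schedule, using the analytic hazard
#' of the chosen model.  The result carries the generating ground truth
#' only implicitly; reproducibility is guaranteed by the seed.
#'
#' @param params a [biological_params] object (ground truth).
#' @param tp a [trend_params] object.
#' @param schedule a person-year schedule from [make_py_schedule()] (or any
#'   data frame with `age`, `year`, `py`).
#' @param model `"fd"` or `"two_hit"`.
#' @param seed RNG seed.
#' @param max_cohort latest birth cohort retained; `NULL` disables the
#'   exclusion.
#' @param mu0,n_stem two-hit model parameters.
#' @param population label stored on the table.
#' @param ngrid,ngauss kernel quadrature sizes.
#' @return An [incidence_table()].
#' @export
generate_incidence_table <- function(params, tp, schedule,
                                     model = c("fd", "two_hit"), seed = NULL,
                                     max_cohort = 1960, mu0 = NULL,
                                     n_stem = 1e6, population = "synthetic",
                                     ngrid = 2000L, ngauss = 32L) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  mc <- if (is.null(max_cohort)) Inf else max_cohort
  sched <- schedule[schedule$year - schedule$age <= mc, , drop = FALSE]
  bp <- params
  if (model == "two_hit") {
    if (is.null(mu0)) stop("'mu0' is required for the two-hit model")
    bp$nu0 <- mu0 * n_stem
  }
  h <- .hazard_rows(sched$age + 0.5, sched$year - sched$age, bp, tp,
                    ngrid = ngrid, ngauss = ngauss)
  cases <- rpois(nrow(sched), h * sched$py)
  incidence_table(data.frame(age = sched$age, year = sched$year,
                             cases = cases, py = sched$py),
                  population = population, max_cohort = mc)
}
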
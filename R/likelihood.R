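#' Expected case counts per stratum
#'
#' Poisson means `lambda_i = h(age_i + 0.5; B_i) * py_i` for every stratum
#' of an incidence table, with the hazard evaluated at the stratum age
#' midpoint for the row's birth cohort `B = year - age`.  Invalid parameter
#' combinations (cohort-adjusted `beta <= 0`) signal a classed domain error
#' rather than being clipped.
#'
#' @param table an [incidence_table()].
#' @param params a [biological_params] object.
#' @param tp a [trend_params] object.
#' @param model `"fd"` for the field-defect model or `"two_hit"` for the
#'   independent stem-cell model.
#' @param mu0,n_stem two-hit model parameters (required when
#'   `model = "two_hit"`).
#' @param ngrid,ngauss kernel quadrature sizes, see [convolved_hazard()].
#' @return Numeric vector of expected counts, one per stratum.
#' @export
predict_expected_counts <- function(table, params, tp,
                                    model = c("fd", "two_hit"),
                                    mu0 = NULL, n_stem = 1e6, ngrid = 2000L,
                                    ngauss = 32L) {
  model <- match.arg(model)
  stopifnot(inherits(params, "biological_params"))
  if (model == "two_hit") {
    if (is.null(mu0)) stop("'mu0' is required for the two-hit model")
    params$nu0 <- mu0 * n_stem
  }
  h <- .hazard_rows(table$age + 0.5, table$year - table$age, params, tp,
                    ngrid = ngrid, ngauss = ngauss)
  h * table$py
}

#' Poisson log-likelihood of an incidence table
#'
#' `sum_i [cases_i log(lambda_i) - lambda_i - log(cases_i!)]` with
#' `lambda_i` from [predict_expected_counts()].  Returns `-Inf` for
#' parameter values outside the model domain (derived `beta <= 0`) or when
#' any stratum with observed cases has zero expected count.
#'
#' @inheritParams predict_expected_counts
#' @return A single number (possibly `-Inf`).
#' @export
poisson_loglik <- function(table, params, tp, model = c("fd", "two_hit"),
                           mu0 = NULL, n_stem = 1e6, ngrid = 2000L,
                           ngauss = 32L) {
  lam <- tryCatch(
    predict_expected_counts(table, params, tp, model = model, mu0 = mu0,
                            n_stem = n_stem, ngrid = ngrid, ngauss = ngauss),
    msce_domain_error = function(e) NULL)
  if (is.null(lam)) return(-Inf)
  sum(dpois(table$cases, lam, log = TRUE))
}

#' Poisson deviance against the saturated model
#'
#' `D = 2 sum_i [cases_i log(cases_i / lambda_i) - (cases_i - lambda_i)]`,
#' with the `cases = 0` term equal to `2 lambda_i` (the saturated
#' log-likelihood uses the convention `0 log 0 = 0`).  The saturated model
#' has one free mean per stratum and deviance 0 by construction.
#'
#' @inheritParams predict_expected_counts
#' @param n_free number of free parameters of the fitted model (for the
#'   residual degrees of freedom).
#' @return A list with `deviance` and `df = n_strata - n_free`.
#' @export
poisson_deviance <- function(table, params, tp, model = c("fd", "two_hit"),
                             n_free = 0L, mu0 = NULL, n_stem = 1e6,
                             ngrid = 2000L, ngauss = 32L) {
  lam <- predict_expected_counts(table, params, tp, model = model, mu0 = mu0,
                                 n_stem = n_stem, ngrid = ngrid,
                                 ngauss = ngauss)
  y <- table$cases
  term <- ifelse(y > 0, y * log(y / lam) - (y - lam), lam)
  list(deviance = 2 * sum(term), df = nrow(table) - as.integer(n_free))
}

#' Likelihood-ratio test between nested Poisson models
#'
#' Upper-tail chi-squared probability of the deviance difference between a
#' null model and a nested alternative.
#'
#' @param dev_null deviance of the restricted (null) model.
#' @param dev_alt deviance of the alternative model; must not exceed
#'   `dev_null`.
#' @param df_diff difference in free parameters (at least 1).
#' @return A list with `statistic`, `df` and `p_value`.
#' @examples
#' lr_test(10, 6.159, 1)  # p ~= 0.05
#' @export
lr_test <- function(dev_null, dev_alt, df_diff) {
  if (df_diff < 1) stop("'df_diff' must be at least 1")
  stat <- dev_null - dev_alt
  if (stat < 0)
    stop("dev_null < dev_alt: model nesting violated")
  list(statistic = stat, df = as.integer(df_diff),
       p_value = pchisq(stat, df_diff, lower.tail = FALSE))
}
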
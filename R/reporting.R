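#' Period profiles of the field-defect rate by cohort
#'
#' Tabulates `nu_FD(s; B)` over age for a set of birth cohorts, with the
#' corresponding calendar year, the text twin of a period-profile figure.
#'
#' @param nu0 background field-defect rate, per year.
#' @param tp a [trend_params] object.
#' @param cohorts birth years.
#' @param ages evaluation ages, years.
#' @return A data frame with columns `cohort`, `age`, `year`, `nu_fd`.
#' @export
fd_profile_table <- function(nu0, tp, cohorts, ages = seq(0.25, 100, 0.25)) {
  do.call(rbind, lapply(cohorts, function(B)
    data.frame(cohort = B, age = ages, year = B + ages,
               nu_fd = fd_rate(ages, B, nu0, tp))))
}

#' Field-defect prevalence by age and cohort
#'
#' Tabulates the cumulative field-defect prevalence
#' `1 - exp(-integral nu_FD)` over age for a set of birth cohorts, the text
#' twin of a prevalence-by-age figure.
#'
#' @inheritParams fd_profile_table
#' @param ages evaluation ages, years.
#' @return A data frame with columns `cohort`, `age`, `prevalence`.
#' @export
fd_prevalence_table <- function(nu0, tp, cohorts, ages = 0:100) {
  do.call(rbind, lapply(cohorts, function(B)
    data.frame(cohort = B, age = ages,
               prevalence = fd_prevalence(ages, B, nu0, tp))))
}

#' Observed and fitted incidence rates per stratum
#'
#' Adds expected counts, fitted rates and observed rates to an incidence
#' table under a given parameter configuration, the overlay surface used to
#' compare model fits with registry rates.
#'
#' @inheritParams predict_expected_counts
#' @return The table with extra columns `lambda`, `fitted_rate`,
#'   `observed_rate` (rates per person-year).
#' @export
predicted_incidence <- function(table, params, tp, model = c("fd", "two_hit"),
                                mu0 = NULL, n_stem = 1e6, ngrid = 2000L) {
  lam <- predict_expected_counts(table, params, tp, model = model, mu0 = mu0,
                                 n_stem = n_stem, ngrid = ngrid)
  out <- as.data.frame(table)
  out$lambda <- lam
  out$fitted_rate <- lam / out$py
  out$observed_rate <- out$cases / out$py
  out
}

#' Deviance comparison of fitted models
#'
#' Compares fitted models against each other and the saturated Poisson
#' baseline (one free mean per stratum, deviance 0).  The goodness-of-fit
#' p-value is the upper-tail chi-squared probability of the deviance on its
#' residual degrees of freedom.
#'
#' @param table the [incidence_table()] the models were fitted to.
#' @param fits a named list of `escc_fit` objects (see [fit_mle()]).
#' @return A data frame with one row per model plus a `saturated` row:
#'   `model`, `deviance`, `n_free`, `df`, `gof_p`.
#' @export
compare_models <- function(table, fits) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    stopifnot(inherits(f, "escc_fit"))
    data.frame(model = nm, deviance = f$deviance, n_free = f$n_free,
               df = f$df,
               gof_p = pchisq(f$deviance, f$df, lower.tail = FALSE))
  })
  rbind(do.call(rbind, rows),
        data.frame(model = "saturated", deviance = 0, n_free = nrow(table),
                   df = 0L, gof_p = NA_real_))
}
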
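#' Cell-level parameters of the MSCE model
#'
#' Container for the biological rates of the field-defect + two-stage clonal
#' expansion model for one population.  The premalignant cell division rate
#' `alpha` is not identifiable from incidence data and is fixed by default at
#' 17.4/yr, the estimated division rate of normal esophageal stem cells.  The
#' cell death rate is never stored: it is always derived as
#' `beta = alpha - g - mu2` from the (possibly cohort-adjusted) net
#' proliferation rate `g`.
#'
#' @param nu0 background field-defect rate, per year.
#' @param mu1 initiation rate per field, per year: the rate at which
#'   premalignant (dysplastic) clones are seeded once the field exists.
#' @param mu2 malignant transformation rate per dysplastic cell, per year.
#' @param g0 baseline net cell proliferation (promotion) rate, per year;
#'   cohort adjustments act multiplicatively on this value, see
#'   [promotion_g()].
#' @param alpha premalignant cell division rate, per year.
#' @param lag fixed time, in years, from the first viable malignant cell to
#'   clinical detection.
#'
#' @return An object of class `biological_params`.
#' @examples
#' biological_params(nu0 = 1e-4, mu1 = 40, mu2 = 3e-9, g0 = 0.025)
#' @export
biological_params <- function(nu0, mu1, mu2, g0, alpha = 17.4, lag = 5) {
  for (nm in c("nu0", "mu1", "mu2", "alpha", "lag")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      .domain_error(sprintf("'%s' must be a single non-negative number", nm))
  }
  # g0 is a net rate (alpha - beta - mu2) and may be negative (subcritical
  # clones); it only needs to keep the derived death rate positive
  if (!is.numeric(g0) || length(g0) != 1L || is.na(g0))
    .domain_error("'g0' must be a single number")
  if (alpha <= 0) .domain_error("'alpha' must be positive")
  if (alpha - g0 - mu2 <= 0)
    .domain_error("alpha - g0 - mu2 must be positive (derived beta > 0)")
  structure(list(nu0 = nu0, mu1 = mu1, mu2 = mu2, g0 = g0, alpha = alpha,
                 lag = lag),
            class = "biological_params")
}

#' @export
print.biological_params <- function(x, ...) {
  cat("MSCE biological parameters (rates per year):\n")
  cat(sprintf("  nu0 = %.4g  mu1 = %.4g  mu2 = %.4g\n", x$nu0, x$mu1, x$mu2))
  cat(sprintf("  g0 = %.4g  alpha = %.4g  lag = %g yr\n", x$g0, x$alpha, x$lag))
  invisible(x)
}

#' Period/cohort trend parameters for the field-defect rate and promotion
#'
#' Parameters of the regularized age-period-cohort modulation.  Period
#' effects act on the field-defect rate for calendar years `y < y0` through
#' `exp(w1 (y - y0)^2 (1 + w2 (y - y0)))` and vanish smoothly (value 1, zero
#' slope) at the reference year `y0`.  Cohort effects act through the
#' analogous factor `exp(b1 (B - B0)^2 (1 + b2 (B - B0)))` for birth years
#' `B < B0`; the cohort reference is constrained to `B0 = y0`.  An optional
#' age attenuation `log(s / s0)` forces the field-defect rate to zero below
#' age `s0`.  Birth-cohort trends on promotion use `g1`, `g2` relative to
#' the reference birth year 1800, see [promotion_g()].
#'
#' @param y0 reference calendar year (also the cohort reference `B0`).
#' @param s0 onset age threshold, years; must be positive.
#' @param w1,w2 period trend coefficients (1/yr^2 and 1/yr).
#' @param b1,b2 cohort trend coefficients (1/yr^2 and 1/yr).
#' @param g1,g2 promotion trend coefficients (1/yr each, acting on `B - 1800`).
#' @param log_attenuation logical; apply the `log(s/s0)` age attenuation
#'   (clipped at zero below `s0`).
#' @param cap_attenuation logical; cap the attenuation factor at 1 (a
#'   sensitivity-analysis option, off by default).
#'
#' @return An object of class `trend_params`.  The cohort reference `B0` is
#'   stored equal to `y0`.
#' @examples
#' trend_params(y0 = 1967.17, s0 = 0.5, w1 = 2e-4, w2 = -0.79,
#'              b1 = 0.011, b2 = 0.044)
#' @export
trend_params <- function(y0, s0 = 1, w1 = 0, w2 = 0, b1 = 0, b2 = 0,
                         g1 = 0, g2 = 0, log_attenuation = TRUE,
                         cap_attenuation = FALSE) {
  for (nm in c("y0", "s0", "w1", "w2", "b1", "b2", "g1", "g2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      .domain_error(sprintf("'%s' must be a single number", nm))
  }
  if (s0 <= 0) .domain_error("'s0' must be positive")
  if (y0 < 1850 || y0 > 2020)
    .domain_error("'y0' must lie in a plausible calendar range (1850-2020)")
  structure(list(w1 = w1, w2 = w2, y0 = y0, s0 = s0, b1 = b1, b2 = b2,
                 B0 = y0, g1 = g1, g2 = g2,
                 log_attenuation = isTRUE(log_attenuation),
                 cap_attenuation = isTRUE(cap_attenuation)),
            class = "trend_params")
}

#' @export
print.trend_params <- function(x, ...) {
  cat("APC trend parameters:\n")
  cat(sprintf("  period: w1 = %.4g, w2 = %.4g, y0 = %.4f\n", x$w1, x$w2, x$y0))
  cat(sprintf("  cohort: b1 = %.4g, b2 = %.4g, B0 = %.4f\n", x$b1, x$b2, x$B0))
  cat(sprintf("  promotion: g1 = %.4g, g2 = %.4g (reference 1800)\n",
              x$g1, x$g2))
  cat(sprintf("  attenuation: %s (s0 = %.4g yr)%s\n",
              if (x$log_attenuation) "log(s/s0)" else "off", x$s0,
              if (x$cap_attenuation) ", capped at 1" else ""))
  invisible(x)
}

#' Trend parameters with all trends switched off
#'
#' Convenience constructor for the null-trend configuration: no period,
#' cohort or promotion trends and no age attenuation, so the field-defect
#' rate is a constant `nu0` at every age and for every cohort and the
#' promotion rate equals `g0` everywhere.
#'
#' @param y0 reference year (irrelevant for the rates, kept for bookkeeping).
#' @return A `trend_params` object.
#' @export
null_trends <- function(y0 = 1900) {
  trend_params(y0 = y0, s0 = 1, log_attenuation = FALSE)
}

#' Reference parameter estimates for US ESCC incidence
#'
#' Posterior-median parameter estimates for esophageal squamous cell
#' carcinoma incidence in the four US SEER9 populations (1975-2016 diagnosis
#' years, birth cohorts up to 1960), used by the package's worked examples
#' and reporting surfaces.
#'
#' @param population one of `"black_males"`, `"black_females"`,
#'   `"white_males"`, `"white_females"`.
#' @return A list with components `bio` ([biological_params]) and `trend`
#'   ([trend_params]).
#' @examples
#' p <- escc_params("white_males")
#' p$bio
#' @export
escc_params <- function(population = c("black_males", "black_females",
                                       "white_males", "white_females")) {
  population <- match.arg(population)
  tab <- list(
    black_males = list(nu0 = 9.54e-5, mu1 = 39.4632, mu2 = 0.0345e-7,
                       g0 = 0.0249, g1 = 0.0268, g2 = -0.0029,
                       b1 = 0.0106, b2 = 0.0440, w1 = 0.0002, w2 = -0.7856,
                       y0 = 1967.1696, s0 = 0.4954),
    black_females = list(nu0 = 5.52e-5, mu1 = 15.7833, mu2 = 0.4878e-7,
                         g0 = 0.0632, g1 = 0.0096, g2 = -0.0011,
                         b1 = 0.0139, b2 = 0.0610, w1 = 0.0011, w2 = -0.2582,
                         y0 = 1961.0000, s0 = 0.3586),
    white_males = list(nu0 = 5.52e-5, mu1 = 4.3755, mu2 = 1.3273e-7,
                       g0 = 0.1836, g1 = 0.0001, g2 = 0.0688,
                       b1 = 0.0038, b2 = 0.0305, w1 = 0.0006, w2 = -0.0928,
                       y0 = 1963.0811, s0 = 1.8121),
    white_females = list(nu0 = 6.51e-5, mu1 = 1.2988, mu2 = 0.3392e-7,
                         g0 = 0.2032, g1 = 0.0000, g2 = 14.5845,
                         b1 = 0.0042, b2 = 0.0289, w1 = -0.0002, w2 = 0.2786,
                         y0 = 1961.0000, s0 = 0.6246)
  )[[population]]
  list(bio = biological_params(nu0 = tab$nu0, mu1 = tab$mu1, mu2 = tab$mu2,
                               g0 = tab$g0),
       trend = trend_params(y0 = tab$y0, s0 = tab$s0, w1 = tab$w1,
                            w2 = tab$w2, b1 = tab$b1, b2 = tab$b2,
                            g1 = tab$g1, g2 = tab$g2,
                            log_attenuation = TRUE))
}
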
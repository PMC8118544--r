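#' Period multiplier on the field-defect rate
#'
#' Multiplicative period effect on the field-defect rate: for calendar years
#' `y < y0` it equals `exp(w1 (y - y0)^2 (1 + w2 (y - y0)))`; for `y >= y0`
#' it is exactly 1.  The quadratic leading term makes the factor approach 1
#' with zero slope at `y0`, so the field-defect rate reaches its background
#' value smoothly.
#'
#' @param y calendar year(s).
#' @param tp a [trend_params] object.
#' @return Numeric vector of multipliers.
#' @export
period_factor <- function(y, tp) {
  stopifnot(inherits(tp, "trend_params"))
  x <- y - tp$y0
  ifelse(x < 0, exp(tp$w1 * x^2 * (1 + tp$w2 * x)), 1)
}

#' Birth-cohort multiplier on the field-defect rate
#'
#' For birth years `B < B0` the field-defect rate is multiplied by
#' `exp(b1 (B - B0)^2 (1 + b2 (B - B0)))`; cohort trends vanish (factor
#' exactly 1) for `B >= B0`.  The cohort reference `B0` is tied to the
#' period reference `y0`.
#'
#' @param B birth year(s).
#' @param tp a [trend_params] object.
#' @return Numeric vector of multipliers.
#' @export
cohort_factor <- function(B, tp) {
  stopifnot(inherits(tp, "trend_params"))
  x <- B - tp$B0
  ifelse(x < 0, exp(tp$b1 * x^2 * (1 + tp$b2 * x)), 1)
}

#' Age-, period- and cohort-modulated field-defect rate
#'
#' The regularized field-defect rate
#' `nu_FD(s; B) = nu0 * period_factor(B + s) * cohort_factor(B) * A(s)`
#' where `A(s) = max(0, log(s / s0))` when the age attenuation is on and 1
#' otherwise.  When both the calendar year `y = B + s` and the birth year
#' `B` are at or beyond the reference `y0`, the rate equals `nu0` exactly
#' (all modulation, including the attenuation, is dropped).  For cohorts
#' born before `y0` the cohort factor and attenuation continue to apply
#' after `y0`; only the period factor is switched off.
#'
#' @param s age(s) in years; must be non-negative.
#' @param B birth year (scalar).
#' @param nu0 background field-defect rate, per year.
#' @param tp a [trend_params] object.
#' @return Numeric vector of rates, per year.
#' @examples
#' tp <- escc_params("white_males")$trend
#' fd_rate(c(2, 5, 10, 50), B = 1920, nu0 = 5.52e-5, tp = tp)
#' @export
fd_rate <- function(s, B, nu0, tp) {
  stopifnot(inherits(tp, "trend_params"), length(B) == 1L)
  if (any(s < 0)) .domain_error("ages 's' must be non-negative")
  if (B >= tp$y0) return(rep(nu0, length(s)))
  A <- if (tp$log_attenuation) {
    a <- ifelse(s > tp$s0, log(s / tp$s0), 0)
    a[s <= tp$s0] <- 0
    if (tp$cap_attenuation) a <- pmin(a, 1)
    a
  } else 1
  nu0 * period_factor(B + s, tp) * cohort_factor(B, tp) * A
}

#' Cumulative field-defect hazard
#'
#' Integral of [fd_rate()] from 0 to `a`, computed by adaptive quadrature
#' with the integration interval split at the attenuation threshold `s0` and
#' at the calendar-reference crossing `y0 - B` where the rate has kinks.
#'
#' @param a age(s) in years.
#' @inheritParams fd_rate
#' @param rel.tol relative quadrature tolerance.
#' @return Numeric vector of cumulative hazards.
#' @export
fd_cumhaz <- function(a, B, nu0, tp, rel.tol = 1e-10) {
  stopifnot(inherits(tp, "trend_params"))
  if (any(a < 0)) .domain_error("'a' must be non-negative")
  vapply(a, function(ai) {
    if (ai == 0) return(0)
    brk <- c(0, tp$s0, tp$y0 - B, ai)
    brk <- sort(unique(pmin(pmax(brk, 0), ai)))
    tot <- 0
    for (i in seq_len(length(brk) - 1L)) {
      if (brk[i + 1L] <= brk[i]) next
      tot <- tot + integrate(fd_rate, brk[i], brk[i + 1L], B = B, nu0 = nu0,
                             tp = tp, rel.tol = rel.tol,
                             abs.tol = 1e-14)$value
    }
    tot
  }, numeric(1))
}

#' Field-defect prevalence by age
#'
#' Probability that an individual of cohort `B` has acquired the
#' field-defect by age `a`: `1 - exp(-integral of nu_FD from 0 to a)`.
#' Because the field-defect onset density may be improper, the prevalence
#' need not approach 1 at old ages.
#'
#' @param a age(s) in years.
#' @inheritParams fd_rate
#' @return Numeric vector of probabilities in `[0, 1)`.
#' @examples
#' p <- escc_params("white_males")
#' fd_prevalence(100, B = 1920, nu0 = p$bio$nu0, tp = p$trend)
#' @export
fd_prevalence <- function(a, B, nu0, tp) {
  1 - exp(-fd_cumhaz(a, B, nu0, tp))
}

#' Cohort-adjusted promotion rate
#'
#' Net cell proliferation (promotion) rate for birth cohort `B`:
#' `g0 * exp(g1 (B - 1800) (1 + g2 (B - 1800)))`.  With `g1 = g2 = 0` the
#' promotion rate is cohort-independent, which is the null model used in
#' likelihood-ratio tests for promotion trends.
#'
#' @param B birth year(s).
#' @param g0 baseline promotion rate, per year.
#' @param tp a [trend_params] object (fields `g1`, `g2`).
#' @return Numeric vector of promotion rates, per year.
#' @export
promotion_g <- function(B, g0, tp) {
  stopifnot(inherits(tp, "trend_params"))
  x <- B - 1800
  g0 * exp(tp$g1 * x * (1 + tp$g2 * x))
}

#' Density of the field-defect onset age
#'
#' `f_FD(s) = nu(s) * exp(-integral of nu from 0 to s)` for an arbitrary
#' non-negative rate function.  The density may be improper (total mass
#' below 1) when the rate vanishes; it is never renormalized.  With a
#' constant rate `nu0` the density is exactly exponential.
#'
#' @param s age(s) in years.
#' @param nu_fn a vectorized function of age returning rates (per year).
#' @param breaks optional interior break points of the quadrature (kink
#'   locations of `nu_fn`).
#' @param rel.tol relative quadrature tolerance.
#' @return Numeric vector of density values, per year.
#' @examples
#' fd_density(c(1, 10), function(s) rep(0.02, length(s)))  # 0.02*exp(-0.02*s)
#' @export
fd_density <- function(s, nu_fn, breaks = NULL, rel.tol = 1e-10) {
  if (any(s < 0)) .domain_error("'s' must be non-negative")
  vapply(s, function(si) {
    v <- nu_fn(si)
    if (v == 0) return(0)
    brk <- sort(unique(pmin(pmax(c(0, breaks, si), 0), si)))
    cum <- 0
    for (i in seq_len(length(brk) - 1L)) {
      if (brk[i + 1L] <= brk[i]) next
      cum <- cum + integrate(nu_fn, brk[i], brk[i + 1L],
                             rel.tol = rel.tol, abs.tol = 1e-14)$value
    }
    v * exp(-cum)
  }, numeric(1))
}
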
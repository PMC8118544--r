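#' Age-specific cancer hazard of the field-defect MSCE model
#'
#' The clinical cancer hazard at age `a` for birth cohort `B`, obtained by
#' convolving the (possibly improper) field-defect onset density with the
#' two-stage clonal expansion kernel and conditioning on no prior cancer:
#' \deqn{h(t) = \frac{\int_0^t f_{FD}(s) f_{MSCE}(t-s) ds}
#'                  {1 - \int_0^t f_{FD}(s) (1 - S_{MSCE}(t-s)) ds}}
#' with `t = a - lag` (clinical incidence at age `a` reflects malignant
#' transformation `lag` years earlier), `f_MSCE = h2 S2`.  The hazard is 0
#' for `a <= lag`.
#'
#' Two evaluation engines are provided: `"kernel"`, a compiled fixed-order
#' Gauss-Legendre scheme with the integration panels split at the kinks of
#' the field-defect rate (fast; used by the likelihood), and
#' `"quadrature"`, a pure-R adaptive scheme built from [fd_density()] and
#' [two_stage_survival()] (slow; reference implementation).
#'
#' @param a age(s) at diagnosis, years.
#' @param params a [biological_params] object.
#' @param tp a [trend_params] object.
#' @param B birth year (scalar).
#' @param g net proliferation rate; defaults to the cohort-adjusted
#'   [promotion_g()] value.
#' @param nu_fn optional custom field-defect rate function of age (forces
#'   the `"quadrature"` engine); defaults to [fd_rate()] with `params$nu0`.
#' @param engine `"kernel"` or `"quadrature"`.
#' @param ngrid grid size for the kernel engine's cumulative-hazard table.
#' @param ngauss Gauss-Legendre order per integration panel (kernel engine).
#' @param rel.tol tolerance for the quadrature engine.
#' @return Numeric vector of hazards, per person-year.
#' @examples
#' p <- escc_params("white_males")
#' convolved_hazard(c(40, 60, 80), p$bio, p$trend, B = 1930)
#' @export
convolved_hazard <- function(a, params, tp, B, g = NULL, nu_fn = NULL,
                             engine = c("kernel", "quadrature"),
                             ngrid = 2000L, ngauss = 32L, rel.tol = 1e-8) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "biological_params"), inherits(tp, "trend_params"))
  if (any(a < 0)) .domain_error("'a' must be non-negative")
  if (is.null(g)) g <- promotion_g(B, params$g0, tp)
  if (!is.null(nu_fn)) engine <- "quadrature"
  if (engine == "kernel") {
    .tsce_setup(params, g)  # domain checks with a classed condition
    gl <- .gauss_nodes(ngauss)
    msce_hazard_kernel(as.numeric(a), B, params$nu0, params$mu1, params$mu2,
                       params$alpha, g, params$lag, unclass(tp),
                       gl$x, gl$w, as.integer(ngrid))
  } else {
    if (is.null(nu_fn)) nu_fn <- function(s) fd_rate(s, B, params$nu0, tp)
    vapply(a, .conv_hazard_quad, numeric(1), params = params, tp = tp, B = B,
           g = g, nu_fn = nu_fn, rel.tol = rel.tol)
  }
}

.conv_hazard_quad <- function(a, params, tp, B, g, nu_fn, rel.tol = 1e-8) {
  t <- a - params$lag
  if (t <= 0) return(0)
  st <- .tsce_setup(params, g)
  brk <- c(tp$s0, tp$y0 - B)
  brk <- brk[brk > 0 & brk < t]
  fFD <- function(s) fd_density(s, nu_fn, breaks = brk)
  seg <- sort(unique(c(0, brk, t)))
  num <- den <- 0
  for (i in seq_len(length(seg) - 1L)) {
    num <- num + integrate(function(s) {
      u <- t - s
      fFD(s) * .h2(u, params$mu1, params$alpha, st$p, st$q) *
        exp(.log_S2(u, params$mu1, params$alpha, st$p, st$q))
    }, seg[i], seg[i + 1L], rel.tol = rel.tol, abs.tol = 1e-12)$value
    den <- den + integrate(function(s) {
      fFD(s) * (1 - exp(.log_S2(t - s, params$mu1, params$alpha,
                                st$p, st$q)))
    }, seg[i], seg[i + 1L], rel.tol = rel.tol, abs.tol = 1e-12)$value
  }
  num / (1 - den)
}

#' Hazard of the two-hit (no field) model
#'
#' Competing model in which the first event is a driver mutation in any of
#' `n_stem` independent normal stem cells (tissue-level rate
#' `n_stem * mu0`) rather than a multicellular field-defect.  The
#' convolution structure is identical to [convolved_hazard()] with the
#' background field-defect rate replaced by the first-hit tissue rate, which
#' is subject to the same period/cohort modulation; the model is used for
#' comparison by deviance.
#'
#' @inheritParams convolved_hazard
#' @param mu0 first driver mutation rate per stem cell, per year.
#' @param n_stem number of normal stem cells at risk.
#' @return Numeric vector of hazards, per person-year.
#' @export
two_hit_hazard <- function(a, mu0, n_stem = 1e6, params, tp, B, g = NULL,
                           engine = c("kernel", "quadrature"), ...) {
  if (mu0 < 0) .domain_error("'mu0' must be non-negative")
  bp2 <- params
  bp2$nu0 <- mu0 * n_stem
  convolved_hazard(a, bp2, tp, B, g = g, engine = match.arg(engine), ...)
}

#' Hazard and survival on an age grid
#'
#' Evaluates the model hazard on a grid of ages and accumulates the
#' corresponding tumor-free survival `exp(-cumulative hazard)` by the
#' trapezoidal rule on the same grid.
#'
#' @inheritParams convolved_hazard
#' @param ages increasing grid of ages, years.
#' @return A data frame of class `hazard_curve` with columns `age`,
#'   `hazard`, `survival`.
#' @export
hazard_curve <- function(ages, params, tp, B, ...) {
  if (is.unsorted(ages, strictly = TRUE))
    .domain_error("'ages' must be strictly increasing")
  h <- convolved_hazard(ages, params, tp, B, ...)
  ch <- c(0, cumsum(diff(ages) * (head(h, -1) + h[-1]) / 2))
  structure(data.frame(age = ages, hazard = h, survival = exp(-ch)),
            class = c("hazard_curve", "data.frame"))
}

# hazard for (age, cohort) stratum rows, grouping rows by cohort so the
# per-cohort cumulative-hazard table inside the kernel is built once
.hazard_rows <- function(age_mid, cohort, params, tp, ngrid = 2000L,
                         ngauss = 32L) {
  h <- numeric(length(age_mid))
  gl <- .gauss_nodes(ngauss)
  for (B in unique(cohort)) {
    idx <- which(cohort == B)
    g <- promotion_g(B, params$g0, tp)
    if (params$alpha - g - params$mu2 <= 0)
      .domain_error(sprintf(
        "alpha - g - mu2 <= 0 for cohort %s (cohort-adjusted g = %.4g)", B, g))
    h[idx] <- tryCatch(
      msce_hazard_kernel(age_mid[idx], B, params$nu0, params$mu1,
                         params$mu2, params$alpha, g, params$lag,
                         unclass(tp), gl$x, gl$w, as.integer(ngrid)),
      error = function(e) .domain_error(conditionMessage(e)))
  }
  h
}
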
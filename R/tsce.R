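#' Characteristic roots of the two-stage clonal expansion model
#'
#' Roots of the quadratic `alpha x^2 - (alpha + beta + mu2) x + beta` that
#' governs the two-stage hazard, expressed through the identifiable
#' combinations `p + q = -g` (with `g = alpha - beta - mu2` the net
#' proliferation) and `p q = -alpha mu2`.  The negative root `p` and
#' non-negative root `q` are computed in a cancellation-free form.
#'
#' @param alpha premalignant cell division rate, per year (must be positive).
#' @param beta premalignant cell death rate, per year.
#' @param mu2 malignant transformation rate, per year.
#' @return A list of class `two_stage_roots` with components `p` and `q`
#'   (per year), satisfying `p + q = -alpha + beta + mu2` and
#'   `p * q = -alpha * mu2`.
#' @examples
#' two_stage_roots(17.4, 10, 0)     # p = -7.4, q = 0
#' two_stage_roots(17.4, 17.2, 1e-7)
#' @export
two_stage_roots <- function(alpha, beta, mu2) {
  if (!is.numeric(alpha) || alpha <= 0) .domain_error("'alpha' must be positive")
  if (!is.numeric(beta) || beta < 0) .domain_error("'beta' must be non-negative")
  if (!is.numeric(mu2) || mu2 < 0) .domain_error("'mu2' must be non-negative")
  g <- alpha - beta - mu2
  sq <- sqrt(g^2 + 4 * alpha * mu2)
  p <- (-g - sq) / 2
  q <- if (g + sq > 0) 2 * alpha * mu2 / (g + sq) else (-g + sq) / 2
  structure(list(p = p, q = q), class = "two_stage_roots")
}

#' @export
print.two_stage_roots <- function(x, ...) {
  cat(sprintf("two-stage roots: p = %.6g, q = %.6g (per year)\n", x$p, x$q))
  invisible(x)
}

# resolve (p, q, beta) for a biological parameter set with cohort-adjusted g
.tsce_setup <- function(params, g) {
  stopifnot(inherits(params, "biological_params"))
  beta <- params$alpha - g - params$mu2
  if (beta <= 0)
    .domain_error("alpha - g - mu2 must be positive (derived beta > 0)")
  r <- two_stage_roots(params$alpha, beta, params$mu2)
  if (r$q - r$p <= 0)
    .domain_error(paste0("degenerate two-stage roots p == q (mu2 = 0 and ",
                         "alpha == beta): outside the supported domain"))
  list(p = r$p, q = r$q, beta = beta)
}

#' Hazard of the two-stage clonal expansion model
#'
#' Age-specific hazard of malignant transformation, measured from the onset
#' of the premalignant field, for the two-stage model with initiation rate
#' `mu1`, division rate `alpha`, transformation rate `mu2` and net
#' proliferation `g` (so the death rate is `beta = alpha - g - mu2`):
#' `h2(u) = (mu1/alpha) p q (e^{-qu} - e^{-pu}) / (q e^{-pu} - p e^{-qu})`.
#' Computed in an overflow-free form (exponentials of non-positive arguments
#' only), valid at arbitrarily old ages.  `h2(0) = 0` and
#' `h2(u) -> -mu1 p / alpha` as `u -> Inf`.
#'
#' @param u time(s) since field onset, years; non-negative.
#' @param params a [biological_params] object (`mu1`, `mu2`, `alpha` used).
#' @param g net proliferation rate, per year; defaults to `params$g0`.
#'   Cohort adjustment is applied upstream via [promotion_g()].
#' @return Numeric vector of hazards, per year.
#' @examples
#' bp <- escc_params("black_males")$bio
#' two_stage_hazard(c(0, 30, 60), bp)
#' @export
two_stage_hazard <- function(u, params, g = params$g0) {
  if (any(u < 0)) .domain_error("'u' must be non-negative")
  st <- .tsce_setup(params, g)
  E <- exp((st$p - st$q) * u)
  h <- (params$mu1 / params$alpha) * st$p * st$q * (E - 1) / (st$q - st$p * E)
  h[u == 0] <- 0
  h
}

#' Survival function of the two-stage clonal expansion model
#'
#' Probability that no malignant cell has appeared by time `u` after field
#' onset: `S2(u) = exp(-integral of h2)` with the closed form
#' `((q - p)/(q e^{-pu} - p e^{-qu}))^{mu1/alpha}`, evaluated on the log
#' scale to avoid overflow.
#'
#' @inheritParams two_stage_hazard
#' @return Numeric vector of probabilities in `(0, 1]`.
#' @export
two_stage_survival <- function(u, params, g = params$g0) {
  if (any(u < 0)) .domain_error("'u' must be non-negative")
  st <- .tsce_setup(params, g)
  exp(.log_S2(u, params$mu1, params$alpha, st$p, st$q))
}

.log_S2 <- function(u, mu1, alpha, p, q) {
  E <- exp((p - q) * u)
  ifelse(u <= 0, 0, (mu1 / alpha) * (log(q - p) + p * u - log(q - p * E)))
}

.h2 <- function(u, mu1, alpha, p, q) {
  E <- exp((p - q) * u)
  ifelse(u <= 0, 0, (mu1 / alpha) * p * q * (E - 1) / (q - p * E))
}
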
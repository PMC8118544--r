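#' First field-defect onset times by thinning
#'
#' Samples the first-event time of a nonhomogeneous Poisson process with
#' rate `nu_FD(s; B)` on `[0, max_age)` by thinning against a
#' piecewise-constant majorant built on a 1-year grid (finely sampled
#' maximum per year times a 1.05 safety factor).  Subjects without an event
#' get `NA` (the onset density is improper).
#'
#' @param n number of subjects.
#' @param nu0 background field-defect rate, per year.
#' @param tp optional [trend_params]; `NULL` means a constant rate `nu0`.
#' @param B birth year (used only with `tp`).
#' @param max_age censoring age, years.
#' @param nu_fn optional custom rate function overriding `nu0`/`tp`.
#' @return Numeric vector of onset ages (`NA` = no onset before `max_age`).
#' @export
sample_fd_times <- function(n, nu0, tp = NULL, B = 1900, max_age = 100,
                            nu_fn = NULL) {
  if (is.null(nu_fn)) {
    nu_fn <- if (is.null(tp)) function(s) rep(nu0, length(s))
             else function(s) fd_rate(s, B, nu0, tp)
  }
  nyear <- as.integer(ceiling(max_age))
  fine <- seq(0, nyear, by = 0.25)
  vals <- nu_fn(fine)
  if (any(vals < 0)) .domain_error("field-defect rate must be non-negative")
  idx <- pmin(pmax(ceiling(fine), 1L), nyear)  # year bin of each fine point
  M <- 1.05 * vapply(seq_len(nyear),
                     function(k) max(vals[idx == k | fine == k - 1]),
                     numeric(1))
  out <- rep(NA_real_, n)
  for (k in seq_len(nyear)) {
    if (M[k] <= 0) next
    act <- which(is.na(out))
    if (!length(act)) break
    cnt <- rpois(length(act), M[k])
    pos <- act[cnt > 0]
    if (!length(pos)) next
    cnt <- cnt[cnt > 0]
    id <- rep(pos, cnt)
    tt <- k - 1 + runif(length(id))
    keep <- runif(length(id)) < nu_fn(tt) / M[k]
    if (any(keep)) {
      first <- tapply(tt[keep], id[keep], min)
      out[as.integer(names(first))] <- as.numeric(first)
    }
  }
  out[!is.na(out) & out >= max_age] <- NA_real_
  out
}

#' Individual-level simulation of the field-defect MSCE process
#'
#' Forward simulation of the full process for a birth cohort: field-defect
#' onset by thinning ([sample_fd_times()]), then clone initiations at rate
#' `mu1`, each clone an exact Gillespie linear birth-death process
#' (division `alpha`, death `beta = alpha - g - mu2`) whose cells transform
#' at rate `mu2`; a transformation yields one malignant and one dysplastic
#' daughter, and clinical cancer follows the first transformation after a
#' fixed lag.  Subjects are censored at `max_age`.  This simulator is the
#' independent oracle used to validate the analytic hazard; use inflated
#' rates (large `mu2`, small `alpha`) so clone sizes stay modest.
#'
#' @param n number of subjects.
#' @param params a [biological_params] object.
#' @param tp optional [trend_params] (`NULL` = constant field-defect rate).
#' @param B birth year of the cohort.
#' @param max_age censoring age, years.
#' @param seed RNG seed; one seed reproduces the whole cohort.
#' @param cap maximum clone size; clones exceeding it abort the subject
#'   with a warning (choose parameters so this never triggers).
#' @param nu_fn optional custom field-defect rate function.
#' @param g optional net proliferation override (default: cohort-adjusted).
#' @return A data frame of class `simulated_cohort` with columns `id`,
#'   `fd_age`, `cancer_age` (`NA` = censored) and `censor_age`, plus
#'   attributes recording the seed and parameters.
#' @examples
#' bp <- biological_params(nu0 = 0.03, mu1 = 0.5, mu2 = 0.1, g0 = -0.1,
#'                         alpha = 2, lag = 2)
#' sim <- simulate_cohort(500, bp, max_age = 80, seed = 1)
#' mean(!is.na(sim$cancer_age))
#' @export
simulate_cohort <- function(n, params, tp = NULL, B = 1900, max_age = 100,
                            seed = NULL, cap = 1e6, nu_fn = NULL, g = NULL) {
  stopifnot(inherits(params, "biological_params"), max_age <= 120)
  if (!is.null(seed)) set.seed(seed)
  fd <- sample_fd_times(n, params$nu0, tp, B, max_age, nu_fn)
  if (is.null(g))
    g <- if (is.null(tp)) params$g0 else promotion_g(B, params$g0, tp)
  beta <- params$alpha - g - params$mu2
  if (beta <= 0) .domain_error("alpha - g - mu2 must be positive")
  sim <- tsce_clone_sim(fd, params$mu1, params$alpha, beta, params$mu2,
                        params$lag, max_age, cap)
  if (any(sim$capped > 0))
    warning(sum(sim$capped), " subject(s) hit the clone-size cap (", cap,
            ") and were censored; use tamer rates")
  structure(data.frame(id = seq_len(n), fd_age = fd,
                       cancer_age = sim$cancer_age, censor_age = max_age),
            seed = seed, B = B, params = params, tp = tp, g = g,
            class = c("simulated_cohort", "data.frame"))
}

#' @rdname simulate_cohort
#' @export
simulate_subject <- function(params, tp = NULL, B = 1900, max_age = 100,
                             seed = NULL) {
  simulate_cohort(1L, params, tp = tp, B = B, max_age = max_age, seed = seed)
}

#' Empirical hazard of a simulated cohort
#'
#' Event counts over person-time at risk per age bin, with exact Poisson
#' 95% confidence intervals (Garwood): `lower = qgamma(.025, events)/PT`,
#' `upper = qgamma(.975, events + 1)/PT`.  Bins without person-time are
#' omitted with a warning.
#'
#' @param cohort a `simulated_cohort` (or data frame with `cancer_age` and
#'   `censor_age` columns).
#' @param breaks increasing age bin boundaries.
#' @param min_events minimum total event count demanded of the cohort.
#' @return A data frame of class `empirical_hazard` with columns `age_lo`,
#'   `age_hi`, `mid`, `events`, `person_years`, `hazard`, `lower`, `upper`.
#' @export
empirical_hazard <- function(cohort, breaks = seq(0, 100, by = 5),
                             min_events = 100L) {
  stopifnot(length(breaks) >= 2, !is.unsorted(breaks, strictly = TRUE))
  end <- ifelse(is.na(cohort$cancer_age), cohort$censor_age,
                pmin(cohort$cancer_age, cohort$censor_age))
  ev_age <- cohort$cancer_age
  total_events <- sum(!is.na(ev_age) & ev_age <= cohort$censor_age)
  if (total_events < min_events)
    stop("cohort has only ", total_events, " events (need >= ", min_events,
         "); simulate more subjects or inflate rates")
  nb <- length(breaks) - 1L
  events <- person <- numeric(nb)
  for (i in seq_len(nb)) {
    lo <- breaks[i]
    hi <- breaks[i + 1L]
    events[i] <- sum(!is.na(ev_age) & ev_age > lo & ev_age <= hi &
                       ev_age <= cohort$censor_age)
    person[i] <- sum(pmax(0, pmin(end, hi) - lo))
  }
  keep <- person > 0
  if (any(!keep)) warning(sum(!keep), " empty-risk-set bins omitted")
  lower <- ifelse(events > 0, qgamma(0.025, events), 0) / person
  upper <- qgamma(0.975, events + 1) / person
  structure(data.frame(age_lo = breaks[-length(breaks)], age_hi = breaks[-1],
                       mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                       events = events, person_years = person,
                       hazard = events / person, lower = lower,
                       upper = upper)[keep, , drop = FALSE],
            class = c("empirical_hazard", "data.frame"))
}

#' Write simulated cohort records as delimited text
#'
#' @param cohort a `simulated_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
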
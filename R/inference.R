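#' Prior / bound specification for one free parameter
#'
#' One row of a prior table: a uniform prior box for a named model parameter
#' together with the sampling/optimization transform.  Strictly positive
#' rate parameters are normally given a `"log"` transform (the model's
#' rates span many orders of magnitude); trend coefficients and reference
#' years use `"identity"`.
#'
#' @param name parameter name; one of `nu0`, `mu1`, `mu2`, `g0`, `mu0`
#'   (biological), `w1`, `w2`, `y0`, `s0`, `b1`, `b2`, `g1`, `g2` (trend),
#'   or one of the curvature aliases `wq = w1*w2`, `bq = b1*b2`,
#'   `gq = g1*g2`.  The aliases are the cubic (resp. quadratic) exponent
#'   coefficients of the trend factors; the log hazard is nearly linear in
#'   them, so optimizing and sampling in these coordinates straightens the
#'   strongly curved ridges that the printed product form creates.  An
#'   alias row replaces the corresponding second-factor row (`w2`, `b2`,
#'   `g2`), whose value is reconstructed as e.g. `w2 = wq / w1`.
#' @param lower,upper prior bounds on the natural scale (`lower < upper`;
#'   positive for log-transformed parameters).
#' @param transform `"identity"` or `"log"`.
#' @param init optional starting value; defaults to the box midpoint
#'   (geometric midpoint on the log scale).
#' @return A one-row data frame; combine rows with `rbind()`.
#' @examples
#' rbind(prior_spec("nu0", 1e-7, 1e-2, "log"),
#'       prior_spec("g0", 1e-3, 1, "log"))
#' @export
prior_spec <- function(name, lower, upper,
                       transform = c("identity", "log"), init = NULL) {
  transform <- match.arg(transform)
  known <- c("nu0", "mu1", "mu2", "g0", "mu0",
             "w1", "w2", "y0", "s0", "b1", "b2", "g1", "g2",
             "wq", "bq", "gq")
  if (!name %in% known)
    stop("unknown parameter name: ", name)
  if (lower >= upper) stop("'lower' must be below 'upper' for ", name)
  if (transform == "log" && lower <= 0)
    stop("log-transformed parameter ", name, " needs a positive lower bound")
  if (is.null(init))
    init <- if (transform == "log") sqrt(lower * upper) else (lower + upper) / 2
  if (init < lower || init > upper) stop("'init' outside bounds for ", name)
  data.frame(name = name, lower = lower, upper = upper,
             transform = transform, init = init, stringsAsFactors = FALSE)
}

#' Default prior boxes around a parameter configuration
#'
#' Builds a prior table for a set of free parameters centred on the values
#' in `params`/`tp`: two decades either side for rates (log scale), one
#' decade for `s0`, +/- 50 calendar years for `y0` (clipped to the
#' plausible range) and a generous symmetric box for trend coefficients.
#'
#' @param params a [biological_params] object.
#' @param tp a [trend_params] object.
#' @param free character vector of free parameter names.
#' @return A prior table (see [prior_spec()]) with `init` at the current
#'   values.
#' @export
default_priors <- function(params, tp,
                           free = c("nu0", "mu1", "mu2", "g0", "g1", "g2",
                                    "b1", "b2", "w1", "w2", "y0", "s0")) {
  cur <- .current_values(params, tp)
  rows <- lapply(free, function(nm) {
    v <- cur[[nm]]
    if (nm %in% c("nu0", "mu1", "mu2", "g0", "mu0")) {
      prior_spec(nm, v / 100, v * 100, "log", init = v)
    } else if (nm %in% c("wq", "bq", "gq")) {
      d <- 1e-4 + 5 * abs(v)
      prior_spec(nm, v - d, v + d, "identity", init = v)
    } else if (nm == "s0") {
      prior_spec(nm, v / 10, v * 10, "log", init = v)
    } else if (nm == "y0") {
      prior_spec(nm, max(1851, v - 50), min(2019, v + 50), "identity",
                 init = v)
    } else {
      # quadratic-in-years coefficients (1/yr^2) act on (y - y0)^2 ~ 5e3, so
      # their plausible scale is much smaller than the linear (1/yr) terms
      d <- if (nm %in% c("w1", "b1")) 0.002 + 5 * abs(v) else 0.05 + 5 * abs(v)
      prior_spec(nm, v - d, v + d, "identity", init = v)
    }
  })
  do.call(rbind, rows)
}

.current_values <- function(params, tp) {
  list(nu0 = params$nu0, mu1 = params$mu1, mu2 = params$mu2, g0 = params$g0,
       mu0 = params$nu0 / 1e6,
       w1 = tp$w1, w2 = tp$w2, y0 = tp$y0, s0 = tp$s0,
       b1 = tp$b1, b2 = tp$b2, g1 = tp$g1, g2 = tp$g2,
       wq = tp$w1 * tp$w2, bq = tp$b1 * tp$b2, gq = tp$g1 * tp$g2)
}

# overwrite free parameters in (params, tp) from a named natural-scale vector
.apply_theta <- function(params, tp, theta) {
  bio <- c("nu0", "mu1", "mu2", "g0")
  trend <- c("w1", "w2", "y0", "s0", "b1", "b2", "g1", "g2")
  quad <- c(wq = "w1", bq = "b1", gq = "g1")
  mu0 <- NULL
  for (nm in names(theta)) {
    if (nm %in% bio) params[[nm]] <- theta[[nm]]
    else if (nm %in% trend) {
      tp[[nm]] <- theta[[nm]]
      if (nm == "y0") tp$B0 <- theta[[nm]]
    } else if (nm == "mu0") mu0 <- theta[[nm]]
    else if (!nm %in% names(quad)) stop("unknown parameter: ", nm)
  }
  # curvature aliases second: they divide by the (possibly updated) leading
  # coefficient to recover the printed second factor
  for (nm in intersect(names(theta), names(quad))) {
    lead <- tp[[quad[[nm]]]]
    second <- sub("1", "2", quad[[nm]])
    tp[[second]] <- if (lead != 0) theta[[nm]] / lead else 0
  }
  list(params = params, tp = tp, mu0 = mu0)
}

# transformed-scale objective closure shared by MLE and MCMC
.make_objective <- function(table, params, tp, priors, model, n_stem, ngrid,
                            ngauss = 32L) {
  nm <- priors$name
  is_log <- priors$transform == "log"
  lower_t <- priors$lower
  lower_t[is_log] <- log(lower_t[is_log])
  upper_t <- priors$upper
  upper_t[is_log] <- log(upper_t[is_log])
  to_nat <- function(th) {
    v <- th
    v[is_log] <- exp(v[is_log])
    names(v) <- nm
    v
  }
  to_t <- function(v) {
    v <- unname(v[nm])
    v[is_log] <- log(v[is_log])
    v
  }
  loglik_t <- function(th) {
    if (any(!is.finite(th)) || any(th < lower_t | th > upper_t))
      return(-Inf)
    theta <- to_nat(th)
    if (("s0" %in% nm && theta[["s0"]] <= 0) ||
        any(theta[nm %in% c("nu0", "mu1", "mu2", "g0", "mu0")] < 0))
      return(-Inf)
    ap <- tryCatch(.apply_theta(params, tp, theta), error = function(e) NULL)
    if (is.null(ap)) return(-Inf)
    poisson_loglik(table, ap$params, ap$tp, model = model, mu0 = ap$mu0,
                   n_stem = n_stem, ngrid = ngrid, ngauss = ngauss)
  }
  list(loglik_t = loglik_t, to_nat = to_nat, to_t = to_t,
       lower_t = lower_t, upper_t = upper_t, names = nm)
}

#' Maximum-likelihood fit of the MSCE-APC model
#'
#' Maximizes the Poisson log-likelihood over the free parameters listed in
#' the prior table with bounded quasi-Newton (`L-BFGS-B`) on the
#' transformed scale, optionally from multiple jittered starting points.
#'
#' @param table an [incidence_table()].
#' @param params,tp baseline parameter objects; free parameters are
#'   overwritten during optimization, fixed ones are taken from here.
#' @param priors prior/bound table from [prior_spec()] / [default_priors()].
#' @param model `"fd"` or `"two_hit"`.
#' @param init optional named vector of natural-scale starting values;
#'   defaults to the prior table's `init` column.
#' @param n_restarts number of additional optimizations from jittered
#'   starting points; the best optimum is kept.
#' @param seed RNG seed for the jitter (only used when `n_restarts > 0`).
#' @param pre_nm logical; run a derivative-free Nelder-Mead warm start
#'   before the quasi-Newton polish.  The Poisson likelihood is `-Inf` in
#'   parts of the prior box (hazard overflow), which derivative-based line
#'   searches handle poorly when started far from the optimum.
#' @param max_rounds maximum number of successive quasi-Newton restarts per
#'   starting point.  Restarting resets the approximate Hessian, which
#'   helps progress along the strongly curved likelihood ridges created by
#'   near-product parameter combinations (e.g. `nu0 * mu1`, `w1 * w2`).
#' @param round_tol stop restarting once a round improves the
#'   log-likelihood by less than this.
#' @param n_stem,ngrid,ngauss passed to the likelihood.
#' @param hessian logical; also compute the numerical Hessian of the
#'   negative log-likelihood at the optimum (transformed scale).
#' @param control passed to [stats::optim()].
#' @return An object of class `escc_fit`: parameter estimates (natural
#'   scale), `loglik`, `deviance`, residual `df`, convergence flag and
#'   optimizer diagnostics.  Non-convergence is reported via the
#'   `convergence` field and a warning, never silently.
#' @export
fit_mle <- function(table, params, tp, priors, model = c("fd", "two_hit"),
                    init = NULL, n_restarts = 0, seed = NULL, n_stem = 1e6,
                    ngrid = 2000L, ngauss = 32L, hessian = FALSE,
                    pre_nm = TRUE, max_rounds = 4L, round_tol = 1e-3,
                    control = list(maxit = 500)) {
  model <- match.arg(model)
  obj <- .make_objective(table, params, tp, priors, model, n_stem, ngrid,
                         ngauss)
  if (is.null(init)) {
    init <- priors$init
    names(init) <- priors$name
  }
  init_t <- obj$to_t(init)
  if (any(init_t < obj$lower_t | init_t > obj$upper_t))
    stop("starting values outside prior bounds")
  negll <- function(th) {
    ll <- obj$loglik_t(th)
    if (!is.finite(ll)) 1e12 else -ll
  }
  starts <- list(init_t)
  if (n_restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    span <- obj$upper_t - obj$lower_t
    for (k in seq_len(n_restarts)) {
      j <- init_t + runif(length(init_t), -0.1, 0.1) * span
      starts[[k + 1L]] <- pmin(pmax(j, obj$lower_t), obj$upper_t)
    }
  }
  ctrl <- control
  if (is.null(ctrl$ndeps)) ctrl$ndeps <- rep(1e-5, length(init_t))
  runs <- lapply(starts, function(s) {
    nm_val <- Inf
    if (pre_nm && length(s) > 1L) {
      nm_run <- optim(s, negll, method = "Nelder-Mead",
                      control = list(maxit = 500 * length(s)))
      s <- pmin(pmax(nm_run$par, obj$lower_t), obj$upper_t)
      nm_val <- nm_run$value
    }
    opt <- NULL
    val <- Inf
    for (r in seq_len(max(1L, max_rounds))) {
      o <- optim(s, negll, method = "L-BFGS-B", lower = obj$lower_t,
                 upper = obj$upper_t, control = ctrl, hessian = FALSE)
      improved <- val - o$value
      if (o$value <= val) {
        opt <- o
        val <- o$value
        s <- o$par
      }
      if (improved < round_tol && r > 1L) break
    }
    if (pre_nm && nm_val < val) {
      # quasi-Newton never improved on the simplex optimum
      opt <- nm_run
    }
    opt
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  if (best$convergence != 0)
    warning("optimizer did not report convergence: ", best$message)
  par <- obj$to_nat(best$par)
  ap <- .apply_theta(params, tp, par)
  dev <- poisson_deviance(table, ap$params, ap$tp, model = model,
                          n_free = nrow(priors), mu0 = ap$mu0,
                          n_stem = n_stem, ngrid = ngrid, ngauss = ngauss)
  H <- if (hessian)
    stats::optimHess(best$par, negll,
                     control = list(ndeps = rep(1e-5, length(best$par))))
  else NULL
  structure(list(par = par, loglik = -best$value, deviance = dev$deviance,
                 df = dev$df, n_free = nrow(priors),
                 convergence = best$convergence, message = best$message,
                 counts = best$counts, n_restarts = n_restarts,
                 model = model, priors = priors, params = ap$params,
                 tp = ap$tp, mu0 = ap$mu0, hessian_t = H),
            class = "escc_fit")
}

#' @export
print.escc_fit <- function(x, ...) {
  cat(sprintf("MSCE-APC %s-model fit: loglik = %.3f, deviance = %.3f (df %d)\n",
              x$model, x$loglik, x$deviance, x$df))
  cat(if (x$convergence == 0) "  converged\n"
      else sprintf("  NOT CONVERGED (code %d): %s\n", x$convergence,
                   x$message))
  print(signif(x$par, 5))
  invisible(x)
}

#' Adaptive random-walk Metropolis-Hastings sampler
#'
#' Generic multivariate Metropolis-Hastings with Gaussian random-walk
#' proposals on a box-bounded space.  During burn-in the proposal
#' covariance is adapted to `2.38^2/d` times the empirical covariance of
#' the chain so far (plus a small ridge); after burn-in it is frozen so the
#' sampled chain satisfies detailed balance.
#'
#' During burn-in the overall proposal scale is additionally tuned toward
#' the canonical multivariate random-walk acceptance rate of about 0.234.
#'
#' @param logpost function of a parameter vector returning the log target
#'   density (up to a constant); `-Inf` outside the support.
#' @param init starting vector (finite log posterior required).
#' @param lower,upper hard box bounds (proposals outside are rejected).
#' @param n number of iterations.
#' @param seed RNG seed (optional).
#' @param burn number of burn-in iterations (default 20% of `n`).
#' @param cov0 initial proposal covariance; defaults to a diagonal based on
#'   the box widths.
#' @param adapt logical; adapt the proposal during burn-in.
#' @param adapt_every adaptation interval, iterations.
#' @return A list with the full `chain` (n x d matrix), `logpost` values,
#'   overall and post-burn-in `acceptance` rates, and `burn`.  An
#'   all-rejected chain raises an error.
#' @export
mh_sample <- function(logpost, init, lower, upper, n, seed = NULL,
                      burn = max(100L, floor(n / 5)), cov0 = NULL,
                      adapt = TRUE, adapt_every = 100L) {
  d <- length(init)
  stopifnot(length(lower) == d, length(upper) == d, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cov0)) cov0 <- diag(((upper - lower) / 50)^2, d)
  scale <- 2.38^2 / d
  log_sf <- 0  # extra scale factor tuned toward ~0.234 acceptance
  win <- 0L
  C <- cov0
  L <- chol(exp(log_sf) * (scale * C + 1e-12 * diag(d)))
  cur <- as.numeric(init)
  curlp <- logpost(cur)
  if (!is.finite(curlp))
    stop("initial point has non-finite log posterior")
  chain <- matrix(NA_real_, n, d)
  lp <- numeric(n)
  acc <- acc_post <- acc_win <- 0L
  burn <- min(burn, n)
  for (i in seq_len(n)) {
    prop <- cur + drop(rnorm(d) %*% L)
    plp <- if (all(prop >= lower & prop <= upper)) logpost(prop) else -Inf
    if (is.finite(plp) && log(runif(1)) < plp - curlp) {
      cur <- prop
      curlp <- plp
      acc <- acc + 1L
      acc_win <- acc_win + 1L
      if (i > burn) acc_post <- acc_post + 1L
    }
    chain[i, ] <- cur
    lp[i] <- curlp
    if (adapt && i <= burn && i %% adapt_every == 0L) {
      rate <- acc_win / adapt_every
      acc_win <- 0L
      win <- win + 1L
      # Robbins-Monro scale tuning; the whole proposal (including the
      # ridge) is scaled so the tuner stays consistent when the empirical
      # covariance is still degenerate
      log_sf <- log_sf + 2 / win^0.6 * (rate - 0.234)
      log_sf <- min(max(log_sf, -20), 20)
      lo <- max(1L, i %/% 2L)
      if (i - lo > 2 * d)
        C <- cov(chain[lo:i, , drop = FALSE])
      L <- chol(exp(log_sf) * (scale * C + 1e-12 * diag(d)))
    }
  }
  if (acc == 0L)
    stop("Metropolis-Hastings chain accepted no proposals; ",
         "check the initial point and proposal scale")
  list(chain = chain, logpost = lp, acceptance = acc / n,
       acceptance_post = if (n > burn) acc_post / (n - burn) else NA_real_,
       burn = burn)
}

#' Proposal covariance from a fitted Hessian
#'
#' Builds an initial Metropolis-Hastings proposal covariance (transformed
#' scale) from the Hessian of a [fit_mle()] run with `hessian = TRUE`.
#' Falls back to the inverse of the Hessian diagonal when the full matrix
#' is not positive definite.
#'
#' @param fit an `escc_fit` with a `hessian_t` component.
#' @return A covariance matrix for [run_mcmc()]'s `cov0`.
#' @export
proposal_from_hessian <- function(fit) {
  H <- fit$hessian_t
  if (is.null(H)) stop("fit was run without 'hessian = TRUE'")
  V <- tryCatch(solve(H), error = function(e) NULL)
  ok <- !is.null(V) && all(is.finite(V)) &&
    all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > 0)
  if (!ok) {
    d <- diag(H)
    d[!is.finite(d) | d <= 0] <- 1e6
    V <- diag(1 / d, nrow(H))
  }
  V
}

#' Proposal covariance from the expected Fisher information
#'
#' Computes the expected Fisher information of the Poisson likelihood on
#' the transformed parameter scale, `J' diag(1/lambda) J` with `J` the
#' central-difference Jacobian of the expected counts, and returns its
#' inverse with small eigenvalues floored.  Unlike a numerical Hessian of
#' the log-likelihood, the expected information is positive semi-definite
#' by construction, and flooring its near-null eigenvalues assigns large
#' proposal variance to the weakly identified directions (the
#' period/cohort trade-off and the promotion-intercept extrapolation), so
#' a random-walk chain can actually traverse them.
#'
#' @inheritParams fit_mle
#' @param at named natural-scale parameter vector at which to evaluate the
#'   information (typically an MLE); defaults to the prior table's `init`.
#' @param floor relative eigenvalue floor (fraction of the largest
#'   eigenvalue).
#' @return A covariance matrix for [run_mcmc()]'s `cov0`.
#' @export
fisher_proposal <- function(table, params, tp, priors,
                            model = c("fd", "two_hit"), at = NULL,
                            n_stem = 1e6, ngrid = 2000L, ngauss = 32L,
                            floor = 1e-9) {
  model <- match.arg(model)
  obj <- .make_objective(table, params, tp, priors, model, n_stem, ngrid,
                         ngauss)
  if (is.null(at)) {
    at <- priors$init
    names(at) <- priors$name
  }
  lam_fn <- function(th) {
    ap <- .apply_theta(params, tp, obj$to_nat(th))
    predict_expected_counts(table, ap$params, ap$tp, model = model,
                            mu0 = ap$mu0, n_stem = n_stem, ngrid = ngrid,
                            ngauss = ngauss)
  }
  th0 <- obj$to_t(at)
  d <- length(th0)
  lam0 <- lam_fn(th0)
  J <- matrix(0, length(lam0), d)
  for (j in seq_len(d)) {
    eps <- 1e-5 * max(1, abs(th0[j]))
    tp_ <- th0
    tp_[j] <- tp_[j] + eps
    tm_ <- th0
    tm_[j] <- tm_[j] - eps
    J[, j] <- (lam_fn(tp_) - lam_fn(tm_)) / (2 * eps)
  }
  Fi <- crossprod(J, J / pmax(lam0, 1e-12))
  ev <- eigen(Fi, symmetric = TRUE)
  dflr <- pmax(ev$values, max(ev$values) * floor)
  ev$vectors %*% (t(ev$vectors) / dflr)
}

#' Posterior sampling of the MSCE-APC model
#'
#' Random-walk multivariate Metropolis-Hastings targeting the Poisson
#' likelihood times a uniform prior over the (transformed) prior box, via
#' [mh_sample()].  Draws are returned on the natural scale.
#'
#' @inheritParams fit_mle
#' @param n_samples chain length.
#' @param seed RNG seed (reproducibility contract).
#' @param burn burn-in length (default 20% of the chain).
#' @param cov0 initial proposal covariance on the transformed scale, e.g.
#'   an inverse Hessian from [fit_mle()].
#' @param adapt adapt the proposal covariance during burn-in.
#' @return An object of class `posterior_samples`: post-burn-in `draws`
#'   (natural scale), acceptance rates, chain metadata and the prior table.
#' @export
run_mcmc <- function(table, params, tp, priors, n_samples = 50000L,
                     seed = 1L, model = c("fd", "two_hit"), init = NULL,
                     burn = NULL, cov0 = NULL, adapt = TRUE, n_stem = 1e6,
                     ngrid = 2000L, ngauss = 32L) {
  model <- match.arg(model)
  stopifnot(n_samples >= 1)
  obj <- .make_objective(table, params, tp, priors, model, n_stem, ngrid,
                         ngauss)
  if (is.null(init)) {
    init <- priors$init
    names(init) <- priors$name
  }
  if (is.null(burn)) burn <- max(100L, floor(n_samples / 5))
  res <- mh_sample(obj$loglik_t, obj$to_t(init), obj$lower_t, obj$upper_t,
                   n = n_samples, seed = seed, burn = burn, cov0 = cov0,
                   adapt = adapt)
  keep <- res$chain[seq.int(res$burn + 1L, n_samples), , drop = FALSE]
  is_log <- priors$transform == "log"
  draws <- keep
  draws[, is_log] <- exp(keep[, is_log, drop = FALSE])
  colnames(draws) <- priors$name
  structure(list(draws = draws, acceptance = res$acceptance,
                 acceptance_post = res$acceptance_post,
                 n_samples = n_samples, burn = res$burn, seed = seed,
                 priors = priors, model = model),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "posterior samples: %d draws (%d burn-in discarded), acceptance %.2f\n",
    nrow(x$draws), x$burn, x$acceptance))
  print(posterior_summary(x))
  invisible(x)
}

#' Marginal posterior summaries
#'
#' Empirical marginal medians and central 95% credible bounds per
#' parameter.
#'
#' @param x a `posterior_samples` object or a draws matrix with named
#'   columns; at least 100 draws are required.
#' @param probs quantile levels (lower, median, upper).
#' @return A data frame with columns `param`, `lower`, `median`, `upper`.
#' @export
posterior_summary <- function(x, probs = c(0.025, 0.5, 0.975)) {
  draws <- if (inherits(x, "posterior_samples")) x$draws else as.matrix(x)
  if (nrow(draws) < 100)
    stop("at least 100 post-burn-in draws are required")
  qs <- t(apply(draws, 2, quantile, probs = probs, names = FALSE))
  data.frame(param = colnames(draws), lower = qs[, 1], median = qs[, 2],
             upper = qs[, 3], row.names = NULL)
}
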
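# MLE and Metropolis-Hastings machinery.

test_that("sampler reproduces a flat target as uniform over the prior box", {
  flat <- function(th) 0
  res <- mh_sample(flat, init = c(0.5, 0.5), lower = c(0, 0),
                   upper = c(1, 1), n = 20000, seed = 10,
                   cov0 = diag(0.3^2, 2), adapt = FALSE)
  keep <- res$chain[seq(res$burn + 1, 20000, by = 25), ]
  for (j in 1:2)
    expect_gt(stats::ks.test(keep[, j], "punif")$p.value, 0.01)
})

test_that("sampler recovers the moments of a Gaussian toy target", {
  logpost <- function(th) -0.5 * (th[1]^2 + (th[2] / 2)^2)
  res <- mh_sample(logpost, init = c(0, 0), lower = c(-20, -20),
                   upper = c(20, 20), n = 30000, seed = 11)
  keep <- res$chain[-(1:res$burn), ]
  expect_lt(abs(mean(keep[, 1])), 0.1)
  expect_lt(abs(mean(keep[, 2])), 0.2)
  expect_lt(rel_err(stats::sd(keep[, 1]), 1), 0.1)
  expect_lt(rel_err(stats::sd(keep[, 2]), 2), 0.1)
  expect_gt(res$acceptance_post, 0.1)
})

test_that("pathological targets raise diagnostics rather than silent output", {
  expect_error(mh_sample(function(th) -Inf, 0.5, 0, 1, 100),
               "non-finite")
  # a target accepting nothing: single spike at the initial point
  spike <- function(th) if (abs(th - 0.5) < 1e-12) 0 else -Inf
  expect_error(mh_sample(spike, 0.5, 0, 1, 500, seed = 2),
               "accepted no proposals")
})

test_that("posterior summaries are order statistics with sane edge cases", {
  draws <- matrix(0.7, nrow = 200, ncol = 1, dimnames = list(NULL, "x"))
  s <- posterior_summary(draws)
  expect_equal(unlist(s[c("lower", "median", "upper")], use.names = FALSE),
               c(0.7, 0.7, 0.7))
  set.seed(12)
  u <- matrix(runif(20000), ncol = 1, dimnames = list(NULL, "u"))
  s <- posterior_summary(u)
  expect_lt(abs(s$median - 0.5), 0.01)
  expect_lt(abs(s$lower - 0.025), 0.005)
  expect_lt(abs(s$upper - 0.975), 0.005)
  z <- matrix(rnorm(20000), ncol = 1, dimnames = list(NULL, "z"))
  s <- posterior_summary(z)
  expect_equal(s$lower, -1.96, tolerance = 0.08)
  expect_equal(s$upper, 1.96, tolerance = 0.08)
  expect_error(posterior_summary(u[1:50, , drop = FALSE]), "100")
})

# one-parameter toy fit used by the next three blocks: constant field-defect
# rate, all trends off, only nu0 free
toy_fit_setup <- function(py = 1e6, seed = 13) {
  p <- escc_params("white_males")
  tp0 <- null_trends()
  tbl <- generate_incidence_table(p$bio, tp0, toy_schedule(py), seed = seed,
                                  ngrid = 300)
  pri <- prior_spec("nu0", p$bio$nu0 / 100, p$bio$nu0 * 100, "log",
                    init = p$bio$nu0)
  list(p = p, tp0 = tp0, tbl = tbl, pri = pri)
}

test_that("one-parameter fit recovers the generating field-defect rate", {
  s <- toy_fit_setup()
  init <- c(nu0 = s$p$bio$nu0 * 3)
  fit <- fit_mle(s$tbl, s$p$bio, s$tp0, s$pri, init = init, ngrid = 300,
                 pre_nm = FALSE)
  expect_identical(fit$convergence, 0L)
  expect_lt(rel_err(fit$par["nu0"], s$p$bio$nu0), 0.05)
  expect_identical(fit$df, nrow(s$tbl) - 1L)
  expect_gte(fit$deviance, 0)
})

test_that("fitting from the generating truth never lowers the likelihood", {
  s <- toy_fit_setup(seed = 14)
  ll_truth <- poisson_loglik(s$tbl, s$p$bio, s$tp0, ngrid = 300)
  fit <- fit_mle(s$tbl, s$p$bio, s$tp0, s$pri, ngrid = 300, pre_nm = FALSE)
  expect_gte(fit$loglik, ll_truth - 1e-8)
})

test_that("multi-start optimization is consistent with a single run", {
  s <- toy_fit_setup(seed = 15)
  single <- fit_mle(s$tbl, s$p$bio, s$tp0, s$pri, ngrid = 300, pre_nm = FALSE)
  multi <- fit_mle(s$tbl, s$p$bio, s$tp0, s$pri, ngrid = 300, pre_nm = FALSE,
                   n_restarts = 4, seed = 16)
  expect_lt(abs(single$loglik - multi$loglik), 1e-4)
})

test_that("posterior medians track the MLE on a well-identified toy fit", {
  s <- toy_fit_setup(seed = 17)
  fit <- fit_mle(s$tbl, s$p$bio, s$tp0, s$pri, ngrid = 300, pre_nm = FALSE,
                 hessian = TRUE)
  ps <- run_mcmc(s$tbl, s$p$bio, s$tp0, s$pri, n_samples = 3000, seed = 18,
                 init = fit$par, cov0 = proposal_from_hessian(fit),
                 ngrid = 300)
  med <- posterior_summary(ps)$median
  expect_lt(rel_err(med, fit$par["nu0"]), 0.02)
  expect_true(all(ps$draws >= s$pri$lower & ps$draws <= s$pri$upper))
})

test_that("two seeds give medians within Monte-Carlo error of each other", {
  s <- toy_fit_setup(seed = 19)
  med <- sapply(c(20, 21), function(sd) {
    ps <- run_mcmc(s$tbl, s$p$bio, s$tp0, s$pri, n_samples = 4000,
                   seed = sd, init = c(nu0 = s$p$bio$nu0), ngrid = 300)
    c(posterior_summary(ps)$median,
      stats::sd(log(ps$draws[, 1])) / sqrt(nrow(ps$draws) / 20))
  })
  # compare log-medians against a combined 3-SE yardstick (thin-adjusted)
  expect_lt(abs(log(med[1, 1]) - log(med[1, 2])),
            3 * sqrt(med[2, 1]^2 + med[2, 2]^2))
})
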
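# Two-stage clonal expansion kernel: roots, hazard, survival.

test_that("root identities hold across random valid parameter draws", {
  set.seed(1)
  for (i in 1:1000) {
    alpha <- runif(1, 0.1, 20)
    beta <- runif(1, 0, 20)
    mu2 <- runif(1, 1e-9, 1)
    r <- two_stage_roots(alpha, beta, mu2)
    expect_lte(r$p, 0)
    expect_gte(r$q, 0)
    expect_lt(rel_err(r$p + r$q, -alpha + beta + mu2), 1e-10)
    expect_lt(rel_err(r$p * r$q, -alpha * mu2), 1e-10)
  }
})

test_that("degenerate and boundary root cases are exact", {
  r <- two_stage_roots(17.4, 17.4, 0)
  expect_identical(c(r$p, r$q), c(0, 0))
  r <- two_stage_roots(17.4, 10, 0)
  expect_equal(r$p, -7.4)
  expect_identical(r$q, 0)
  expect_error(two_stage_roots(-1, 1, 0), class = "msce_domain_error")
  expect_error(two_stage_roots(1, -1, 0), class = "msce_domain_error")
})

test_that("roots match an independent polynomial root finder", {
  # posterior-median white-male configuration: p, q solve y^2 + g y - alpha mu2
  alpha <- 17.4
  mu2 <- 1.3273e-7
  g <- 0.1836
  beta <- alpha - g - mu2
  r <- two_stage_roots(alpha, beta, mu2)
  pr <- sort(Re(polyroot(c(-alpha * mu2, g, 1))))
  expect_lt(rel_err(r$p, pr[1]), 1e-10)
  expect_lt(rel_err(r$q, pr[2]), 1e-10)
  expect_lt(rel_err(r$p * r$q, -alpha * mu2), 1e-12)
})

test_that("two-stage hazard vanishes at zero and plateaus at -mu1 p / alpha", {
  bp <- escc_params("black_males")$bio
  expect_identical(two_stage_hazard(0, bp), 0)
  # plateau reached once q * u >> 1
  bp2 <- biological_params(nu0 = 0, mu1 = 0.7, mu2 = 0.5, g0 = 0.5,
                           alpha = 2, lag = 0)
  r <- two_stage_roots(2, 2 - 0.5 - 0.5, 0.5)
  u_large <- 60 / r$q
  expect_lt(rel_err(two_stage_hazard(u_large, bp2),
                    -bp2$mu1 * r$p / bp2$alpha), 1e-4)
  expect_true(all(two_stage_hazard(seq(0, 100, 5), bp) >= 0))
})

test_that("two-stage hazard agrees with a stiff Kolmogorov ODE solution", {
  skip_if_not_installed("deSolve")
  # the normalized hazard z = h2 / mu1 solves z' = mu2 + g z - alpha z^2
  ode_h2 <- function(u, mu1, alpha, mu2, g) {
    sol <- deSolve::ode(y = c(z = 0), times = c(0, u),
                        func = function(t, y, p)
                          list(mu2 + g * y - alpha * y^2),
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-18)
    mu1 * sol[2, "z"]
  }
  bm <- escc_params("black_males")$bio  # posterior-median black-male rates
  expect_lt(rel_err(two_stage_hazard(60, bm),
                    ode_h2(60, bm$mu1, bm$alpha, bm$mu2, bm$g0)), 1e-6)
  bp <- desk_params_a()$bio
  expect_lt(rel_err(two_stage_hazard(35, bp),
                    ode_h2(35, bp$mu1, bp$alpha, bp$mu2, bp$g0)), 1e-6)
})

test_that("survival equals exp(-integrated hazard) to quadrature accuracy", {
  bm <- escc_params("black_males")$bio
  for (u in c(30, 70)) {
    I <- integrate(two_stage_hazard, 0, u, params = bm, rel.tol = 1e-10)$value
    expect_lt(rel_err(two_stage_survival(u, bm), exp(-I)), 1e-8)
  }
  set.seed(2)
  for (i in 1:20) {
    alpha <- runif(1, 1, 20)
    g <- runif(1, -0.5, 0.8 * alpha)
    mu2 <- runif(1, 1e-8, 0.1 * (alpha - g))
    bp <- biological_params(nu0 = 0, mu1 = runif(1, 0.01, 5), mu2 = mu2,
                            g0 = g, alpha = alpha)
    u <- runif(1, 5, 80)
    I <- integrate(two_stage_hazard, 0, u, params = bp, rel.tol = 1e-10)$value
    expect_lt(rel_err(two_stage_survival(u, bp), exp(-I)), 1e-6)
  }
})

test_that("survival derivative recovers the hazard on interior points", {
  bp <- desk_params_b()$bio
  for (u in c(5, 15, 40)) {
    eps <- 1e-5
    d <- (-log(two_stage_survival(u + eps, bp)) +
            log(two_stage_survival(u - eps, bp))) / (2 * eps)
    expect_lt(rel_err(d, two_stage_hazard(u, bp)), 1e-6)
  }
})

test_that("edge cases: mu1 = 0 survival, degenerate roots, domain errors", {
  bp <- biological_params(nu0 = 0, mu1 = 0, mu2 = 1e-7, g0 = 0.1, alpha = 2)
  expect_equal(two_stage_survival(c(0, 10, 200), bp), c(1, 1, 1))
  expect_identical(two_stage_survival(0, desk_params_a()$bio), 1)
  # p == q requires mu2 = 0 and alpha = beta: outside the supported domain
  deg <- biological_params(nu0 = 0, mu1 = 1, mu2 = 0, g0 = 0, alpha = 2)
  expect_error(two_stage_hazard(10, deg), class = "msce_domain_error")
  expect_error(two_stage_hazard(-1, desk_params_a()$bio),
               class = "msce_domain_error")
})
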
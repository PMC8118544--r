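# Regularized period/cohort trends on the field-defect rate and promotion.

bm <- escc_params("black_males")
wm <- escc_params("white_males")

test_that("period and cohort factors are exactly 1 beyond their references", {
  tp <- bm$trend
  expect_identical(period_factor(tp$y0, tp), 1)
  expect_identical(period_factor(tp$y0 + 10, tp), 1)
  expect_identical(period_factor(c(2000, 2016), tp), c(1, 1))
  expect_identical(cohort_factor(tp$B0, tp), 1)
  expect_identical(cohort_factor(tp$B0 + 25, tp), 1)
  # null coefficients: 1 everywhere
  tp0 <- trend_params(y0 = 1960)
  expect_identical(cohort_factor(c(1850, 1900, 1980), tp0), c(1, 1, 1))
})

test_that("period factor approaches 1 smoothly (zero slope) at y0", {
  tp <- bm$trend
  eps <- 1e-5
  expect_lt(abs(period_factor(tp$y0 - eps, tp) - 1) / eps, 1e-3)
})

test_that("trend factors reproduce direct-arithmetic values", {
  # frozen hand-calculator values for the posterior-median configurations
  expect_equal(period_factor(1930, bm$trend), 4208.489659, tolerance = 1e-8)
  expect_equal(cohort_factor(1920, bm$trend), 9.646249025e-12,
               tolerance = 1e-8)
  expect_equal(promotion_g(1930, bm$bio$g0, bm$trend), 0.2181973227,
               tolerance = 1e-9)
})

test_that("field-defect rate regimes follow the reference-year contract", {
  tp <- bm$trend
  nu0 <- bm$bio$nu0
  # attenuation on: rate is zero at and below s0
  expect_identical(fd_rate(tp$s0, 1920, nu0, tp), 0)
  expect_identical(fd_rate(tp$s0 / 2, 1920, nu0, tp), 0)
  # both B and y at/above y0: exactly nu0 (attenuation dropped)
  expect_identical(fd_rate(c(0.1, 3, 50), 1970, nu0, tp), rep(nu0, 3))
  # y >= y0 but B < y0: period factor off, cohort factor and attenuation on
  s_late <- (tp$y0 - 1920) + 10
  expect_equal(fd_rate(s_late, 1920, nu0, tp),
               nu0 * cohort_factor(1920, tp) * log(s_late / tp$s0))
  # attenuation off: plain product of factors near age zero
  tp_noat <- trend_params(y0 = tp$y0, s0 = tp$s0, w1 = tp$w1, w2 = tp$w2,
                          b1 = tp$b1, b2 = tp$b2, log_attenuation = FALSE)
  s <- 0.01
  expect_equal(fd_rate(s, 1920, nu0, tp_noat),
               nu0 * period_factor(1920 + s, tp_noat) *
                 cohort_factor(1920, tp_noat))
  expect_error(fd_rate(-0.5, 1920, nu0, tp), class = "msce_domain_error")
})

test_that("1920-cohort field-defect rates peak before age ten", {
  for (p in list(bm, wm)) {
    s <- seq(p$trend$s0 + 1e-3, 60, by = 0.01)
    v <- fd_rate(s, 1920, p$bio$nu0, p$trend)
    expect_lt(s[which.max(v)], 10)
  }
})

test_that("field-defect prevalence is monotone, bounded and starts at zero", {
  expect_identical(fd_prevalence(0, 1920, bm$bio$nu0, bm$trend), 0)
  set.seed(3)
  for (i in 1:5) {
    tp <- trend_params(y0 = runif(1, 1940, 1980), s0 = runif(1, 0.3, 3),
                       w1 = runif(1, -5e-4, 5e-4), w2 = runif(1, -0.5, 0.5),
                       b1 = runif(1, -5e-3, 5e-3), b2 = runif(1, -0.05, 0.05))
    prev <- fd_prevalence(seq(0, 100, 10), 1915, 8e-5, tp)
    expect_true(all(diff(prev) >= -1e-12))
    expect_true(all(prev >= 0 & prev < 1))
  }
})

test_that("lifetime 1920-cohort prevalence respects the published bounds", {
  expect_lte(100 * fd_prevalence(100, 1920, bm$bio$nu0, bm$trend), 3)
  expect_lte(100 * fd_prevalence(100, 1920, wm$bio$nu0, wm$trend), 1)
})

test_that("promotion trend reduces to g0 at null coefficients and B = 1800", {
  tp0 <- trend_params(y0 = 1960)
  expect_identical(promotion_g(c(1850, 1920, 1990), 0.2, tp0), rep(0.2, 3))
  expect_identical(promotion_g(1800, 0.0249, bm$trend), 0.0249)
})

test_that("constant-rate onset density is exactly exponential and improper", {
  nu0 <- 0.02
  cst <- function(s) rep(nu0, length(s))
  s <- c(0.5, 5, 40)
  expect_equal(fd_density(s, cst), nu0 * exp(-nu0 * s), tolerance = 1e-9)
  # zero rate: zero density
  expect_identical(fd_density(s, function(x) rep(0, length(x))), c(0, 0, 0))
  # piecewise rate (0 below s0): shifted exponential, never renormalized
  s0 <- 5
  pw <- function(s) ifelse(s > s0, nu0, 0)
  expect_equal(fd_density(c(10, 30), pw, breaks = s0),
               nu0 * exp(-nu0 * (c(10, 30) - s0)), tolerance = 1e-8)
  expect_identical(fd_density(2, pw, breaks = s0), 0)
  # improper total mass: integral of f equals 1 - exp(-integral of nu)
  mass <- integrate(fd_density, s0, 200, nu_fn = pw, breaks = s0,
                    rel.tol = 1e-10)$value
  expect_lt(rel_err(mass, 1 - exp(-nu0 * (200 - s0))), 1e-6)
})

test_that("null trends collapse the model to a constant field-defect rate", {
  tp0 <- null_trends()
  nu0 <- 7e-5
  expect_identical(fd_rate(c(0, 1, 50, 99), 1880, nu0, tp0), rep(nu0, 4))
  expect_identical(fd_rate(c(0, 50), 1975, nu0, tp0), rep(nu0, 2))
  expect_equal(fd_prevalence(80, 1900, nu0, tp0), 1 - exp(-nu0 * 80),
               tolerance = 1e-9)
})
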
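# Stochastic simulator: thinning, clone engine, empirical hazard.

test_that("constant-rate onset times from thinning are exponential", {
  set.seed(5)
  fd <- sample_fd_times(1e4, nu0 = 0.05, max_age = 100)
  obs <- fd[!is.na(fd)]
  expect_gt(length(obs), 9000)
  Ftr <- function(x) stats::pexp(x, 0.05) / stats::pexp(100, 0.05)
  expect_gt(stats::ks.test(obs, Ftr)$p.value, 0.01)
})

test_that("trend-modulated onset times match the cumulative-hazard law", {
  d <- desk_params_c()
  set.seed(6)
  fd <- sample_fd_times(5e3, nu0 = d$bio$nu0, tp = d$tp, B = d$B,
                        max_age = 100)
  Z <- 1 - exp(-fd_cumhaz(100, d$B, d$bio$nu0, d$tp))
  Ftr <- function(x) (1 - exp(-fd_cumhaz(x, d$B, d$bio$nu0, d$tp))) / Z
  expect_gt(stats::ks.test(fd[!is.na(fd)], Ftr)$p.value, 0.01)
  # no events below the attenuation threshold
  expect_true(all(fd[!is.na(fd)] > d$tp$s0))
})

test_that("zero onset rate yields a cancer-free cohort", {
  bp <- biological_params(nu0 = 0, mu1 = 5, mu2 = 0.5, g0 = 0, alpha = 2,
                          lag = 0)
  sim <- simulate_cohort(500, bp, max_age = 80, seed = 7)
  expect_true(all(is.na(sim$fd_age)))
  expect_true(all(is.na(sim$cancer_age)))
})

test_that("clone engine matches the analytic two-stage survival function", {
  # all subjects get the field at birth: P(cancer by T) = 1 - S2(T - lag)
  alpha <- 2; g <- -0.05; mu2 <- 0.08; mu1 <- 0.4
  bp <- biological_params(nu0 = 1, mu1 = mu1, mu2 = mu2, g0 = g,
                          alpha = alpha, lag = 0)
  set.seed(8)
  n <- 2e4
  cs <- msceapc:::tsce_clone_sim(rep(0, n), mu1, alpha, alpha - g - mu2,
                                 mu2, 0, 40, 1e6)
  p_obs <- mean(!is.na(cs$cancer_age))
  p_exp <- 1 - two_stage_survival(40, bp, g = g)
  expect_lt(abs(p_obs - p_exp) / sqrt(p_exp * (1 - p_exp) / n), 4)
})

test_that("instant initiation and transformation reduce cancer ages to the onset law", {
  # mu1, mu2 >> 1 with lag 0: cancer age converges to Exp(nu0)
  bp <- biological_params(nu0 = 0.05, mu1 = 100, mu2 = 50, g0 = 0,
                          alpha = 110, lag = 0)
  sim <- simulate_cohort(5e3, bp, max_age = 100, seed = 8)
  ca <- sim$cancer_age[!is.na(sim$cancer_age)]
  Ftr <- function(x) stats::pexp(x, 0.05) / stats::pexp(100, 0.05)
  expect_gt(stats::ks.test(ca, Ftr)$p.value, 0.01)
})

test_that("simulated records respect ordering, censoring and reproducibility", {
  d <- desk_params_a()
  s1 <- simulate_cohort(2000, d$bio, d$tp, B = d$B, max_age = d$max_age,
                        seed = 99)
  s2 <- simulate_cohort(2000, d$bio, d$tp, B = d$B, max_age = d$max_age,
                        seed = 99)
  expect_identical(s1$cancer_age, s2$cancer_age)
  ok <- !is.na(s1$cancer_age)
  expect_true(all(s1$cancer_age[ok] >= s1$fd_age[ok] + d$bio$lag))
  expect_true(all(s1$cancer_age[ok] <= d$max_age))
  one <- simulate_subject(d$bio, d$tp, B = d$B, seed = 1)
  expect_identical(nrow(one), 1L)
})

test_that("empirical hazard is flat for exponential event times", {
  set.seed(9)
  n <- 2e4
  ca <- stats::rexp(n, 0.1)
  coh <- data.frame(cancer_age = ifelse(ca <= 50, ca, NA), censor_age = 50)
  eh <- empirical_hazard(coh, breaks = seq(0, 50, 5))
  expect_true(mean(eh$lower <= 0.1 & 0.1 <= eh$upper) >= 0.8)
  pooled <- sum(eh$events) / sum(eh$person_years)
  expect_lt(rel_err(pooled, 0.1), 0.03)
})

test_that("empirical hazard handles censored-only cohorts and empty bins", {
  coh <- data.frame(cancer_age = rep(NA_real_, 50), censor_age = 60)
  eh <- empirical_hazard(coh, breaks = seq(0, 60, 10), min_events = 0)
  expect_true(all(eh$hazard == 0))
  expect_true(all(eh$lower == 0))
  # bins beyond the censoring age have no person-time and are omitted
  coh2 <- data.frame(cancer_age = c(5, NA), censor_age = 20)
  expect_warning(eh2 <- empirical_hazard(coh2, breaks = c(0, 10, 20, 30),
                                         min_events = 0), "omitted")
  expect_identical(nrow(eh2), 2L)
  expect_error(empirical_hazard(coh2, breaks = c(0, 30)), "events")
})
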
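# Shared fixtures: desk-scale parameter sets with inflated rates so that
# simulated event counts and likelihood signals are large at small n, and
# small helpers used across test files.

# subcritical clones, high transformation rate: cheap exact simulation
desk_params_a <- function() {
  list(bio = biological_params(nu0 = 0.03, mu1 = 0.5, mu2 = 0.1, g0 = -0.1,
                               alpha = 2, lag = 2),
       tp = null_trends(), B = 1900, max_age = 80)
}

# mildly supercritical clones, short run to first transformation
desk_params_b <- function() {
  list(bio = biological_params(nu0 = 0.05, mu1 = 1.0, mu2 = 0.05, g0 = 0.2,
                               alpha = 3, lag = 1),
       tp = null_trends(), B = 1900, max_age = 60)
}

# age/period-modulated field-defect rate (kinks at s0 and y0 - B)
desk_params_c <- function() {
  list(bio = biological_params(nu0 = 0.08, mu1 = 0.4, mu2 = 0.08, g0 = 0.1,
                               alpha = 2.5, lag = 3),
       tp = trend_params(y0 = 1950, s0 = 2, w1 = -0.001, w2 = 0.01,
                         b1 = -5e-4, b2 = 0, log_attenuation = TRUE),
       B = 1910, max_age = 90)
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.xmin)

# person-time-weighted bin averages of an analytic hazard curve, for
# comparison with empirical events / person-time per bin
bin_average_hazard <- function(bp, tp, B, breaks, step = 0.25) {
  grid <- seq(0, max(breaks), by = step)
  h <- convolved_hazard(grid, bp, tp, B)
  ch <- c(0, cumsum(diff(grid) * (head(h, -1) + h[-1]) / 2))
  S <- exp(-ch)
  vapply(seq_len(length(breaks) - 1L), function(i) {
    k <- grid > breaks[i] & grid <= breaks[i + 1L]
    sum(h[k] * S[k]) / sum(S[k])
  }, numeric(1))
}

# small aligned-grid synthetic table: ages and years on a common step so
# birth cohorts repeat across strata (fast per-cohort hazard evaluation)
toy_schedule <- function(base_py = 1e6)
  make_py_schedule(seq(1980, 2012, 4), seq(32, 80, 4), base_py = base_py)
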
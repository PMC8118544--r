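# msceapc

Multistage clonal expansion (MSCE) models of cancer incidence with
regularized age-period-cohort (APC) trends, built for esophageal squamous
cell carcinoma (ESCC) but applicable to any cancer whose registry incidence
is tabulated by single year of age and calendar year.

## The scientific problem

ESCC incidence in the US shows strong, disparate secular trends by sex and
race that a pure age effect cannot explain.  `msceapc` models the
age-specific incidence `h(a)` as the hazard of a biologically structured
stochastic process:

1. a **premalignant field-defect** arises in the esophagus as the first
   event of a non-homogeneous Poisson process with rate `nu_FD(s; B)`
   depending on age `s`, birth cohort `B` and calendar year `y = B + s`;
2. within the field, dysplastic clones initiate at rate `mu1` (per field,
   per year), expand as a linear birth-death process with cell division
   rate `alpha` and death rate `beta`, and transform at rate `mu2` per cell
   (net clonal growth `g = alpha - beta - mu2`);
3. a fixed lag (5 years) separates the first malignant cell from clinical
   detection.

The hazard is the convolution of the (possibly improper) field-defect onset
density with the classical two-stage clonal expansion kernel

    h2(u) = (mu1/alpha) p q (e^{-qu} - e^{-pu}) / (q e^{-pu} - p e^{-qu}),
    S2(u) = [(q - p) / (q e^{-pu} - p e^{-qu})]^{mu1/alpha},

where `p <= 0 <= q` solve `p + q = -g`, `p q = -alpha mu2`, conditioned on
no prior cancer.  Because `alpha` is not identifiable from incidence data
it is fixed at 17.4/yr (the esophageal stem-cell division rate).

Secular trends enter the biology directly, not as proportional-hazards
multipliers: for years before a reference year `y0` the field-defect rate
is modulated by `exp(w1 (y - y0)^2 (1 + w2 (y - y0)))`, birth cohorts
before `B0 = y0` by `exp(b1 (B - B0)^2 (1 + b2 (B - B0)))`, and an
age-attenuation `log(s/s0)` (zero below `s0`) concentrates field-defect
onset after early childhood.  Promotion follows
`g(B) = g0 exp(g1 (B - 1800)(1 + g2 (B - 1800)))`.

The package provides, per module:

- `two_stage_roots()`, `two_stage_hazard()`, `two_stage_survival()`,
  `fd_density()`, `convolved_hazard()`, `two_hit_hazard()` — the analytic
  kernel (compiled fast path + adaptive-quadrature reference path);
- `period_factor()`, `cohort_factor()`, `fd_rate()`, `fd_prevalence()`,
  `promotion_g()` — the regularized APC trends;
- `incidence_table()`, `read_incidence_table()`, `poisson_loglik()`,
  `poisson_deviance()`, `lr_test()` — Poisson likelihood on age-by-year
  strata (`lambda = h(age + 1/2) x person-years`, cohorts after 1960
  excluded);
- `fit_mle()`, `run_mcmc()`, `mh_sample()`, `posterior_summary()` — bounded
  quasi-Newton MLE and adaptive random-walk Metropolis-Hastings;
- `simulate_cohort()`, `empirical_hazard()` — an exact individual-level
  (Gillespie) simulator used as an independent oracle for the analytic
  hazard;
- `make_py_schedule()`, `generate_incidence_table()` — synthetic SEER-like
  tables with known ground truth;
- `fd_profile_table()`, `fd_prevalence_table()`, `predicted_incidence()`,
  `compare_models()` — text-table result surfaces.

## Worked example

```r
library(msceapc)

p <- escc_params("white_males")        # reference posterior-median estimates
convolved_hazard(c(50, 60, 70, 80), p$bio, p$trend, B = 1930) * 1e5
#> [1]  2.025  7.334 12.040 13.810
100 * fd_prevalence(100, 1920, p$bio$nu0, p$trend)
#> [1] 0.455
```

The hazard for the 1930 white-male cohort rises from about 2 to about 14
cases per 100,000 person-years between ages 50 and 80, and about 0.45% of
the 1920 cohort ever acquires the predisposing field-defect.

Fitting a synthetic table generated under a known constant field-defect
rate recovers it:

```r
tp0  <- null_trends()
sched <- make_py_schedule(seq(1980, 2012, 4), seq(32, 80, 4), base_py = 1e6)
tbl  <- generate_incidence_table(p$bio, tp0, sched, seed = 1)
tbl
#> incidence table: 102 strata, ages 32-80, years 1980-2012, 1533 cases

pri <- prior_spec("nu0", p$bio$nu0 / 100, p$bio$nu0 * 100, "log")
fit_mle(tbl, p$bio, tp0, pri, init = c(nu0 = 3 * p$bio$nu0), pre_nm = FALSE)
#> MSCE-APC fd-model fit: loglik = -226.542, deviance = 80.687 (df 101)
#>   converged
#>        nu0
#> 5.5963e-05
```

The estimate 5.60e-5/yr sits within 1.5% of the generating value
5.52e-5/yr.

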
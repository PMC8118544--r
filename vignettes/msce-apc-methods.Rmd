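---
title: "Field-defect MSCE models with regularized age-period-cohort trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-defect MSCE models with regularized age-period-cohort trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msceapc)
```

## The model

`msceapc` describes age-specific cancer incidence as the hazard of a
multistage stochastic process with a tissue-level first event.  An
individual of birth cohort $B$ acquires a premalignant *field-defect* as
the first event of a non-homogeneous Poisson process with rate
$\nu_{FD}(s; B)$, giving the (possibly improper) onset density

$$f_{FD}(s) = \nu_{FD}(s)\, e^{-\int_0^s \nu_{FD}(v)\,dv}.$$

If $\nu_{FD}$ vanishes at some age the total onset probability is below
one — not everyone ever develops the field — and the density is used as
is, never renormalized.  Conditional on a field at age $s$, dysplastic
clones initiate at rate $\mu_1$ (per field, per year); each clone is a
linear birth-death process with cell division rate $\alpha$ and death rate
$\beta$ whose cells transform at rate $\mu_2$, producing one malignant and
one dysplastic daughter.  The time from field onset to the first malignant
cell follows the two-stage clonal expansion law with hazard and survival

$$h_2(u) = \frac{\mu_1}{\alpha}\,
  \frac{pq\,(e^{-qu} - e^{-pu})}{q e^{-pu} - p e^{-qu}}, \qquad
  S_2(u) = \left[\frac{q - p}{q e^{-pu} - p e^{-qu}}\right]^{\mu_1/\alpha},$$

where $p \le 0 \le q$ are the roots determined by $p + q = -g$ and
$pq = -\alpha\mu_2$, with $g = \alpha - \beta - \mu_2$ the net clonal
growth (promotion) rate.  Three useful identities anchor the numerics and
the test suite: $h_2(0) = 0$; $S_2 = \exp(-\int_0^u h_2)$; and
$h_2(u) \to -\mu_1 p/\alpha$ as $u \to \infty$.  The last follows directly
from the backward Kolmogorov equation: the normalized hazard
$z = h_2/\mu_1$ solves the Riccati equation
$z' = \mu_2 + g z - \alpha z^2$, whose stable fixed point is $-p/\alpha$.
The test suite integrates this equation with a stiff solver as an
independent oracle for the closed form.

The population hazard at age $a$ convolves onset with progression and
conditions on no prior cancer,

$$h(t) = \frac{\int_0^t f_{FD}(s)\, h_2(t-s) S_2(t-s)\, ds}
              {1 - \int_0^t f_{FD}(s)\,\bigl(1 - S_2(t-s)\bigr)\, ds},
  \qquad t = a - \mathrm{lag},$$

with a fixed clinical lag (default 5 years) applied as a hard shift of the
whole hazard argument — including inside the conditioning term, a choice
the model leaves open; we apply one consistent shift so that `h(a) = 0`
for `a` at or below the lag.  Tumor-size-dependent detection is out of
scope.

A competing *two-hit* parameterization replaces the multicellular field
with independent normal stem cells: the first event is a driver mutation
at tissue rate $n_{stem}\mu_0$ (default $n_{stem} = 10^6$).  Structurally
the convolution is identical, so `two_hit_hazard()` with
$n_{stem}\mu_0 = \nu_0$ reproduces `convolved_hazard()` exactly; the two
models are compared by deviance, not nested.  The three-stage clonal
expansion variant is intentionally not implemented.

## Regularized period and cohort trends

Secular trends act directly on the biology along historical time rather
than multiplying the hazard by diagnosis-year constants.  For calendar
years $y = B + s$ before a reference year $y_0$,

$$\nu_{FD}(s; B) = \nu_0 \,
  e^{w_1 (y - y_0)^2 (1 + w_2 (y - y_0))}\,
  e^{b_1 (B - B_0)^2 (1 + b_2 (B - B_0))}\, A(s),$$

with $A(s) = \max(0, \log(s/s_0))$ when the age attenuation is on.  The
quadratic-times-linear exponent is the printed form of the cohort factor;
we adopt the same algebraic shape for the period factor, which matches the
stated units of $w_1$ (1/yr$^2$) and $w_2$ (1/yr) and approaches 1 with
zero slope at $y_0$, so $\nu_{FD}$ reaches the background rate smoothly.
Both factors are *exactly* 1 on their right-of-reference half-lines.  The
cohort reference is tied to the period reference, $B_0 = y_0$, and when
both $y \ge y_0$ and $B \ge y_0$ the rate is exactly $\nu_0$ with the
attenuation dropped.  For cohorts born before $y_0$ observed after $y_0$,
only the period factor switches off; the cohort factor and attenuation
continue to apply, and the possible kink at the $y_0$ crossing within a
cohort's lifetime is accepted and handled explicitly by the quadrature.
The attenuation is unbounded above by default (no saturation cap); a
`cap_attenuation` flag clips it at 1 for sensitivity analysis.  Promotion
is cohort-adjusted as $g(B) = g_0 e^{g_1 (B - 1800)(1 + g_2 (B - 1800))}$;
$g_1 = g_2 = 0$ recovers cohort-independent promotion, the null model of
the promotion-trend likelihood-ratio test.

Ages and calendar years are treated as continuous reals with $y = B + s$;
tabulated strata are evaluated at their midpoints (age $+ 1/2$ for the row
cohort $B = \mathrm{year} - \mathrm{age}$).

With the reference posterior-median estimates shipped in `escc_params()`,
the white-male configuration places field-defect onset for the 1920 cohort
between roughly ages 2 and 15 (peak near age 4) with a lifetime prevalence
just under half a percent.  The black-male cohort factor
$e^{b_1 (B-B_0)^2(1+b_2 (B-B_0))}$ evaluates to about $10^{-11}$ at
$B = 1920$, so under these printed coefficients the model attributes
essentially zero lifetime prevalence to that cohort; prevalence
concentrates instead in cohorts born after about 1935.  Users exploring
historical cohorts should be aware that the cubic term makes the cohort
factor collapse very rapidly below $B_0 - 1/b_2$.

## Numerics

- **Roots.**  $p$ and $q$ are computed from $(g, \mu_2)$ with the
  conjugate-product form $q = 2\alpha\mu_2/(g + \sqrt{g^2 + 4\alpha\mu_2})$
  to avoid cancellation when $\mu_2$ is tiny (realistic values are
  $10^{-9}$–$10^{-7}$/yr).  The degenerate case $p = q$ (only possible
  when $\mu_2 = 0$ and $\alpha = \beta$) raises a documented error; it
  lies outside the biologically fitted domain.
- **Overflow.**  $h_2$ and $\log S_2$ are evaluated after factoring
  $e^{-pu}$ out of numerator and denominator, so every exponential has a
  non-positive argument; hazards remain finite at arbitrarily old ages and
  for strongly promoted cohorts.
- **Convolution.**  The fast path (`engine = "kernel"`, compiled) first
  tabulates the cumulative onset hazard $\Lambda(s)$ by composite Simpson
  integration on a dense grid (default 2000 points) with segments split at
  the kinks of $\nu_{FD}$ (the attenuation threshold $s_0$ and the
  crossing $y_0 - B$), interpolating between grid points with a cubic
  Hermite scheme that uses the exactly known derivative
  $\Lambda' = \nu_{FD}$.  The outer integrals use fixed-order
  Gauss-Legendre panels (default 32 nodes) split at the same kinks and
  capped at 15-year lengths.  A pure-R reference path
  (`engine = "quadrature"`) composes `fd_density()` and the two-stage
  functions through adaptive quadrature; the two paths agree to better
  than $10^{-6}$ relative in the test suite, and the coarse settings used
  inside iterative fitting (`ngrid = 400`, `ngauss = 16`) stay within
  about $10^{-6}$ of the reference.
- **Degenerate inputs.**  Parameter combinations with
  $\alpha - g(B) - \mu_2 \le 0$ for any cohort in the data, or whose
  cumulative cancer probability reaches 1 (denominator underflow), raise a
  classed condition that the likelihood converts to $-\infty$; nothing is
  silently clipped.

## Likelihood and estimation

Case counts are modelled as independent Poisson draws with mean
$\lambda_i = h(a_i + \tfrac12; B_i)\,PY_i$.  The deviance against the
saturated model uses the convention $0\log 0 = 0$; zero person-year strata
are dropped with a warning by the table constructor, and birth cohorts
after 1960 are excluded by default.  Optional minimum/maximum age filters
are exposed but unconstrained by default.

`fit_mle()` maximizes the likelihood with bounded L-BFGS-B on a
transformed scale — logarithmic for the strictly positive rates
($\nu_0, \mu_1, \mu_2, g_0, s_0, \mu_0$), identity for trend coefficients
and $y_0$ — with finite-difference steps of $10^{-5}$.  Two robustness
devices matter in practice and are on by default: an optional
derivative-free Nelder-Mead warm start (the likelihood is $-\infty$ in
parts of any reasonable prior box, which breaks quasi-Newton line searches
started far away), and up to `max_rounds` successive L-BFGS-B restarts,
because near-product parameter combinations ($\nu_0\mu_1$, $w_1 w_2$,
$g_1 g_2$) create strongly curved ridges on which a single quasi-Newton
run stalls with a stale Hessian approximation.  Non-convergence is always
reported via the convergence flag and a warning.

The curvature has a structural cure.  The trend exponents are linear in
the coefficient pairs $(w_1, w_1 w_2)$, $(b_1, b_1 b_2)$ and
$(g_1, g_1 g_2)$ — e.g. the period exponent is
$w_1 (y-y_0)^2 + (w_1 w_2)(y-y_0)^3$ — so the prior table accepts the
curvature aliases `wq`, `bq`, `gq` for the products.  Fitting and sampling
in these coordinates (with the second factors reconstructed as
$w_2 = \mathrm{wq}/w_1$, etc.) turns the banana-shaped ridges into nearly
Gaussian contours; the full-model recovery check in the acceptance suite
uses exactly this basis and converts draws back to the printed
parameterization for reporting.  The printed basis remains the default
everywhere else.

`run_mcmc()` targets likelihood $\times$ uniform prior over the
transformed prior box with a multivariate Gaussian random walk.  Sampling
positive rates on the log scale makes the effective prior log-uniform,
appropriate for parameters spanning orders of magnitude.  During burn-in
(default 20% of the chain) the proposal covariance is adapted to
$2.38^2/d$ times the empirical chain covariance plus a ridge, and the
overall scale is additionally tuned toward the canonical 0.234 acceptance
rate; both are frozen afterwards so the retained draws satisfy detailed
balance.  Two helpers seed the proposal covariance:
`proposal_from_hessian()` inverts the MLE Hessian, and
`fisher_proposal()` inverts the expected Fisher information
$J^\top \mathrm{diag}(1/\lambda) J$ with its near-null eigenvalues floored
— unlike the numeric Hessian the expected information is positive
semi-definite by construction, and the flooring assigns large proposal
variance to the weakly identified directions so the chain can traverse
them.  For simulation-based coverage checks the chain is initialized at
the generating configuration (a draw from the data-generating region, the
standard calibration protocol); at the short chain lengths the validation
suite uses, a chain started elsewhere mostly measures its own mixing time
rather than the posterior.  Burn-in length and thinning are
configuration, not estimates;
posterior summaries are empirical marginal medians and central 95%
intervals and require at least 100 retained draws.

Prior boxes default to two decades either side of the current value for
rates, one decade for $s_0$, $\pm 50$ calendar years for $y_0$, and
symmetric boxes for trend coefficients with a smaller floor for the
quadratic-in-years coefficients $w_1, b_1$ (they multiply
$(y - y_0)^2 \sim 5\times 10^3$, so equal-width boxes would be absurdly
permissive).  All bounds are configurable; they are bookkeeping for the
uniform prior, not substantive constraints.

The promotion-trend test compares nested models by deviance with an
upper-tail $\chi^2$ probability.  One caution discovered during
calibration and reflected in the test suite: the printed trend
parameterization $g_1(1 + g_2 x)x$ is singular at the null ($g_1 = 0$
leaves $g_2$ unidentified), so a bounded two-parameter alternative cannot
reach the full quadratic family near the null and the 2-df test is
conservative.  The calibration test therefore uses the regular 1-df
nested pair ($g_1$ free, $g_2$ fixed), which is correctly calibrated.

## The stochastic oracle

`simulate_cohort()` is an independent check of the analytic hazard, not a
fitting tool.  Field-defect onset is drawn by thinning against a
piecewise-constant yearly majorant (finely sampled maximum times a 1.05
safety factor); clone dynamics use an exact event-driven (Gillespie)
simulation with integer cell counts, and the first transformation time
plus lag gives the cancer age.  A configurable clone-size cap (default
$10^6$) guards against runaway supercritical clones; validation regimes
use inflated $\mu_2$ and deflated $\alpha$ so the cap never triggers, and
any capped subject raises a warning.  Reproducibility is per root seed
through R's RNG in a single stream; subjects are simulated sequentially,
so identical seeds give identical cohorts on any platform, at the price
of not being order-independent under hypothetical parallel execution.
`empirical_hazard()` bins events over person-time at risk with exact
(Garwood) Poisson intervals; the acceptance suite requires the analytic
curve, averaged over each bin with survival weights, to fall inside the
95% intervals in at least 90% of informative bins across three desk-scale
parameter sets.

## Synthetic data

`make_py_schedule()` and `generate_incidence_table()` emulate the
registry tabulation format the likelihood consumes: single-year
age-by-diagnosis-year strata over a 1975–2016-style window, person-year
surfaces optionally scaled by birth cohort, Poisson case counts at the
analytic hazard, and the cohorts-after-1960 exclusion.  Person-year
magnitudes are order-of-magnitude stand-ins (default $10^5$ per stratum),
not fits to any registry.  What passing tests on these tables shows is
internal consistency — generation, likelihood and estimation agree —
not that real registry data satisfy the model: real tables carry registry
coverage changes, race/ethnicity coding shifts, reporting delays and
overdispersion, all deliberately out of scope (the likelihood is strictly
Poisson).

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to keep the whole
run in the tens of minutes on one core: oracle validation with
30–40 thousand subjects per parameter set; parameter recovery on a
973-stratum table (diagnosis years 1976–2016 in 2-year steps, ages
30–84, $2\times10^5$ person-years per stratum — about ten times a
realistic single-registry stratum) with a 26,000-draw chain; and a
1000-replicate null calibration on 102-stratum tables.  These are the
package's own validation conditions; larger problems simply take
proportionally longer.

## Known limitations

- The three-stage clonal expansion kernel and tumor-size-based detection
  are not implemented.
- The likelihood has no overdispersion; registry artifacts must be
  handled upstream.
- The 2-df promotion-trend test inherits the singular parameterization
  discussed above; prefer the 1-df version near the null.
- MCMC convergence diagnostics beyond acceptance rates and seed-to-seed
  comparison (e.g. split-$\hat R$) are not built in.
- The cohort factor's cubic term can drive the field-defect rate to
  numerically zero for cohorts far below $B_0$; interpret historical-cohort
  prevalences from fitted coefficients with care.
- The period/cohort decomposition is only weakly identified: because
  $y = B + s$, the period polynomial in $(y - y_0)$ contains a pure-cohort
  component that trades off against the cohort factor, with the split pinned
  down only by post-$y_0$ exposure; likewise $g_0$ is the promotion curve
  extrapolated ninety-odd years before the earliest observable cohort.  The
  likelihood is near-flat along these trade-offs, so individual coefficient
  estimates from a global search can wander substantially at little
  likelihood cost; treat fitted values as local refinements of a plausible
  configuration and lean on the posterior intervals, not point estimates.
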
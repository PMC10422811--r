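---
title: "Methods: non-inferiority on CV-adjusted means in three-arm trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-inferiority on CV-adjusted means in three-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimand

A gold-standard non-inferiority trial carries three arms: an experimental
treatment (E), an active reference (R) and a placebo (P), with outcomes
modelled as mutually independent draws,
$X_{i} \sim N(\mu_i, \sigma_i^2)$, $i \in \{E, R, P\}$. The design assumes
$\sigma_E^2 = \sigma_R^2$ — the reference sets the benchmark, so the new
treatment is held to the same dispersion — while the placebo arm may be
heteroscedastic.

Instead of raw means, each arm's effect is measured by the Searls
CV-adjusted mean
$$\theta_i = \frac{n_i \mu_i}{n_i + \sigma_i^2/\mu_i^2},$$
the mean shrunk by its squared coefficient of variation. With a known CV
this is the minimum-MSE linear estimator of the mean; used as the effect
measure it damps the distortion that unequal dispersions inject into a
ratio of mean differences. Note $\theta_i$ depends on $n_i$: the estimand
itself is design-dependent, and $\theta_i \to \mu_i$ as $n_i \to \infty$
with error $O(1/n_i)$. `searls_theta()` computes $\theta$ from either
population values or plug-ins — the estimator and estimand share one
formula by construction.

Non-inferiority is formulated on the effect-retention ratio
$$\xi = \frac{\theta_E - \theta_P}{\theta_R - \theta_P}, \qquad
H_0: \xi \le \xi_0 \;\text{ vs }\; H_1: \xi > \xi_0,$$
with $\xi_0 \in (0,1)$ (0.8 by convention). The reversed direction
(`direction = "less"`) covers safety applications, where a dose is "safe"
when its gain over vehicle control is demonstrably *less* than a fraction
(typically 0.5) of a positive control's gain. The denominator
$\theta_R - \theta_P$ is positive by design: a reference that does not beat
placebo invalidates the trial, not the arithmetic.

## The GPV test

Exact pivots for $\xi$ do not exist under heteroscedasticity, so the
headline test builds a generalized pivotal quantity (GPQ) and estimates the
generalized p-value (GPV) by Monte Carlo. Writing $s^2_{pooled}$ for the
pooled E/R variance, each draw takes independent $Z_i \sim N(0,1)$ and
$U_i \sim \chi^2(n_i - 1)$ and forms

$$R_{\mu_i} = \bar{x}_i - Z_i\sqrt{\frac{(n_i-1)\,s_i^2}{n_i\,U_i}},\qquad
R_{\sigma_i^2} = \frac{(n_i-1)\,s_i^2}{U_i},$$

with $s_i^2 = s^2_{pooled}$ for $i \in \{E, R\}$ and the placebo arm's own
$s_P^2$ otherwise, then substitutes into the Searls form,
$R_{\theta_i} = n_i R_{\mu_i} / (n_i + R_{\sigma_i^2}/R_{\mu_i}^2)$, and
finally
$$R_\xi = \frac{R_{\theta_E} - R_{\theta_P}}{R_{\theta_R} - R_{\theta_P}}.$$

The generalized test variable is $T_\xi = R_\xi - \xi$, whose observed
value is 0; the p-value for $H_1: \xi > \xi_0$ is the indicator proportion
$\hat p = \sum_h I(R_{\xi,h} \le \xi_0)/H$ (ties inclusive), and one-sided
generalized confidence limits are empirical quantiles of the draws.

### Conditioning on the positive denominator

A design choice that matters: with small reference or placebo arms the
denominator pivot $R_{\theta_R} - R_{\theta_P}$ has non-trivial mass below
zero even though the estimand's denominator is positive by design. A
negative-denominator draw flips the sign of the ratio, so *every* such draw
lands on the acceptance side of the indicator no matter how strong the
evidence — left in place, these draws make the ratio test severely
conservative, with empirical size far below the nominal 0.05 at the
moderate sample sizes the design targets. Because the design constrains
$\theta_R - \theta_P > 0$, the package conditions the GPQ draw set on
$R_{\theta_R} - R_{\theta_P} > 0$: draws violating the constraint are
excluded and tallied (`n_nonpos_denom`, reported in `glance()` and
`print()`), as are literal NaN/Inf draws (`n_nonfinite`). With this
conditioning the test is calibrated: empirical size sits inside the
binomial band around 0.05 across the scenarios in the test suite, and the
two-sided 95% draw interval covers the true ratio at the nominal rate.
Retained finite draws are never truncated or winsorized; indicator
proportions and order statistics are robust to the heavy tails the Searls
substitution can produce when $R_{\mu_P}$ passes near zero.

### Monte-Carlo sizes and the quantile rule

Defaults: $H = 10{,}000$ draws for data analysis, $H = 5{,}000$ inside
simulation cells, $B = 1{,}000$ bootstrap replicates. All quantiles — GPV
limits, bootstrap limits, two-sided intervals — use one rule: the
inverse-empirical-CDF (ceiling-index order statistic) quantile,
$\hat Q(p) = x_{(\lceil np \rceil)}$, matching the $1/H$ granularity of the
indicator p-value so that "reject at $\alpha$" and "limit beyond $\xi_0$"
agree up to that granularity. A $10^{-9}$ guard absorbs floating-point
noise in $np$. Monte-Carlo draws are seeded explicitly; identical seeds
give bit-identical results.

## The Delta-method competitor

With $\hat\xi_1 = \hat\theta_E - \hat\theta_P$ and
$\hat\xi_2 = \hat\theta_R - \hat\theta_P$ (Searls plug-ins, each arm's own
variance), the ratio $\hat\xi = \hat\xi_1/\hat\xi_2$ is treated as
asymptotically normal with
$E(\hat\xi) \approx \mu_{\xi_1}/\mu_{\xi_2}$ and
$$\mathrm{Var}(\hat\xi) \approx
\Big(\tfrac{\mu_{\xi_1}}{\mu_{\xi_2}}\Big)^2
\Big(\tfrac{V_1}{\mu_{\xi_1}^2} + \tfrac{V_2}{\mu_{\xi_2}^2}
- 2\tfrac{C}{\mu_{\xi_1}\mu_{\xi_2}}\Big),$$
where $C = \mathrm{Var}(\hat\theta_P)$ because the placebo arm is shared
and the arms are independent. The per-arm moments of
$\hat\theta = g(\bar X, S^2)$, $g(m, v) = nm^3/(nm^2+v)$, are first-order
Taylor moments under normal sampling:
$E(\hat\theta) \approx g(\mu, \sigma^2)$,
$\mathrm{Var}(\hat\theta) \approx g_m^2\,\sigma^2/n + g_v^2\,2\sigma^4/(n-1)$,
with analytic partials and $\mathrm{Cov}(\bar X, S^2) = 0$. The test suite
validates these moments against a $10^6$-draw brute-force oracle (3 MC SEs)
and at the $n \to \infty$ limits. No second-order ratio correction is
applied. The rejection region is
$\hat\xi - z_\alpha\sqrt{\mathrm{Var}(\hat\xi)} > \xi_0$. In calibration
runs this test is severely conservative (size $\sim 10^{-3}$ or below where
the GPV test sits at 0.05) — it is provided as the comparator it is, not as
a recommendation.

## The residual-bootstrap competitor

The basic bootstrap: resample each arm independently with replacement at
its own size (stratified — the design fixes $n_E$, $n_R$, $n_P$), compute
the Searls plug-in ratio $\hat\xi^{*b}$ and residual
$e^{*b} = \hat\xi^{*b} - \hat\xi$ over $B$ replicates, and set the
one-sided limit $L = \hat\xi - e^*_{(1-\alpha)}$; claim non-inferiority
when $L > \xi_0$. The reported p-value is the proportion of
residual-centred replicates $\hat\xi - e^{*b}$ on the null side of $\xi_0$
— a documented convention; the decision follows the limit. Raw
observations are required; a summary table cannot be resampled. Constant
resamples are legitimate ($S^{2*} = 0$ gives $\hat\theta^* = \bar x^*$);
only zero-mean or zero-denominator replicates are dropped, with a tally.
For two-point arms the whole bootstrap distribution is enumerable ($4^3$
equally likely joint resamples), and the test suite checks the limit
against that enumeration exactly.

## The simulation engine and what it emulates

`scenario_config()` fixes one cell of the study design the package is
calibrated against: placebo mean $\mu_P = 16.5$ and SD $\sigma_P = 7.5$;
reference gain $\Delta = \mu_R - \mu_P \in \{9, 15, 20\}$; variance ratios
$\tau_R = \sigma_R^2/\sigma_E^2 = 1$ (asserted, overridable) and
$\tau_P = \sigma_P^2/\sigma_E^2 \in \{0.5, 1, 2\}$ with
$\sigma_E = \sigma_R = \sigma_P/\sqrt{\tau_P}$; total $n$ allocated
3:2:1 to E:R:P; $\xi_0 = 0.8$; $\alpha = 0.05$; 10,000 replications by
default. Null cells use the construction $\mu_E = \xi_0\Delta + \mu_P$
verbatim, even though the induced $\theta$-ratio differs slightly from
$\xi_0$ at finite $n$ (the induced true ratio is reported per cell as
`xi_true`; at $\Delta = 9$, $\tau_P = 0.5$, $n = 60$ it is 0.8093). Power
cells specify the true ratio `xi_target` directly and solve for $\mu_E$ by
root-finding on the monotone map $\mu_E \mapsto \theta_E$ (tolerance
$10^{-10}$) — only $\mu_E$ is free once $\Delta$, the variances and the
allocation are pinned.

Non-normal cells draw log-normal or gamma outcomes moment-matched to
$(\mu_i, \sigma_i^2)$: log-normal with log-variance
$\log(\sigma^2/\mu^2 + 1)$, gamma with shape $\mu^2/\sigma^2$ and scale
$\sigma^2/\mu$. The generator emulates independent, identically
distributed within-arm outcomes with exactly the designed first two
moments; it does not emulate dropout, covariates, measurement error,
clustering, or integer-valued endpoints (the worked example's micronucleus
counts are analysed through their summary statistics, not re-simulated as
counts). Calibration results under these generators therefore speak to
moment structure and skewness, not to every feature of real trial data.

Per-replication RNG streams are derived from (seed, cell index,
replication index) by an integer hash, so cell results are independent of
scheduling order and bit-reproducible; the nested Monte Carlo inside a
replication (GPQ draws, bootstrap resamples) consumes that replication's
stream.

`estimator_properties()` reports bias, MSE and coverage of the ratio. The
point estimators are a design choice the source material leaves open: the
median of the retained GPQ draws (robust to the heavy tails of the ratio),
the Searls plug-in $\hat\xi$ for the Delta method, and the mean of the
bootstrap replicates. Coverage uses equal-tailed two-sided 95% intervals
for every method — the draw quantiles, the normal interval, and the basic
bootstrap interval respectively.

## Problem sizes in the shipped tests

The packaged calibration checks run at 2,000 replications with $H = 2,000$
draws per replication — sizes chosen so the full suite completes in a few
minutes while leaving the binomial Monte-Carlo bands tight enough to be
informative (3 joint MC SEs around a size of 0.05 is roughly $\pm 0.015$).
The worked example runs at $H = 100{,}000$, where the p-value's binomial SE
is below $10^{-3}$.

## Known limitations

* The equal-variance assumption between E and R is structural: both pivots
  use the pooled variance with their own chi-square draws, as the method
  prescribes, although the resulting marginal pivots are not classical
  t-pivots.
* Arms with mean zero (or data driving $\hat\theta_R = \hat\theta_P$) are
  rejected, not regularized — the CV, and hence the estimand, is undefined
  there.
* Each experimental arm is tested marginally; no multiplicity adjustment
  is applied across doses (the worked example's "maximal safe dose" is a
  step-down annotation, not an adjusted procedure).
* Only one-sided tests are provided; the two-sided interval appears only in
  the estimator-property study.
* Published p-values for the worked example's data set are not reproduced
  by this construction (the package's values are internally consistent
  with its confidence limits, which do reproduce); see the test suite's
  acceptance file for the exact comparisons asserted.
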
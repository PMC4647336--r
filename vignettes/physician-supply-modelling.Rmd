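---
title: "Modelling regional differences in outpatient physician supply"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling regional differences in outpatient physician supply}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physupply)
```

`physupply` studies why physician-to-population ratios differ so much
between urban and rural areas. It couples a stylized two-region economic
model of practice location with an empirical pipeline for district-level
count data: a seeded synthetic district generator, a zero-truncated
negative-binomial (ZTNB) GLM with a log population offset and regional
(ASHIP) intercepts, a cross-model backward stepwise selection, and the
back-transformation of coefficients into physician densities per
10 000 inhabitants.

## 1. The two-region model

Two regions hold the same population $n$ but differ in size,
$m_u < m_r$, so population density is higher in the urban region. A
representative consumer demands GP services $A$, specialist services $S$
and other consumption $Z$, maximizing a Cobb-Douglas utility
$U = A^a S^s Z^z$ with $s > a$ (specialist services are preferred but the
two are only partial substitutes). Money and time budgets merge into one
constraint through the opportunity cost of time $\varrho$; out-of-pocket
payment is the co-insurance share $\acute a$ of the service price. The
optimum has the closed form

$$A = \frac{a\,(y(1-b) + \varrho l)}{(\acute a p_A + \varrho t_A)(a+z+s)},
\qquad
S = \frac{s\,(y(1-b) + \varrho l)}{(\acute a p_S + \varrho t_S)(a+z+s)},$$

i.e. each service's preference share of full income divided by its
*effective visit cost* (out-of-pocket price plus valued time). The
per-visit time cost falls with regional physician density,
$t_j = (\text{count}_j/m)^{-q_j}$ with $0 < q_j < 1$ and $q_S > q_A$:
finding the right specialist takes relatively more search and travel
time. Physician income is the margin times demand served,
$Y_{A_i} = (p_A - c_A) A_i n / \mathrm{GP}_i$, and physicians relocate
until rural income equals $w \ge 1$ times urban income — $w$ is the
income premium demanded for rural practice. With $\acute a = 0$ the
equilibrium allocation is closed-form:

$$\frac{\mathrm{GP}_u}{\mathrm{GP}_r} =
  \left(\frac{m_r}{m_u}\right)^{\frac{q_A}{1-q_A}} w^{\frac{1}{1-q_A}},$$

and analogously for specialists with $q_S$.

### Testable propositions

1. Urban preference ($w > 1$) raises the urban/rural ratio of both types.
2. A larger rural area (lower rural density) does the same.
3. The specialist mix is more urban than the GP mix whenever $q_S > q_A$.
4. More insurance coverage (lower $\acute a$) raises regional inequality:
   out-of-pocket price dilutes the time-cost channel through which
   density drives demand.

All four are exercised by `comparative_statics()` on documented default
grids.

### Numerical and design choices

* **Physician counts are continuous** in this module; the equilibrium is
  a continuum argument. Integer counts appear only in the empirical
  modules.
* **Only the merged budget is enforced.** Goods spending $Y$ and leisure
  $L$ are reported as accounting decompositions of $Z = Y + \varrho L$;
  $L$ may come out negative because the optimization never imposes
  $L \ge 0$ separately.
* **General co-insurance is solved numerically.** `solve_equilibrium()`
  root-finds on the *log urban/rural ratio* (not the urban share): the
  income gap $Y_{j,r} - w Y_{j,u}$ is strictly increasing in that
  variable, so the root is unique, and the log parameterization keeps
  full relative precision even when the ratio is of order $10^5$ or
  larger. Brent's method (`uniroot`, tolerance $10^{-13}$) is followed by
  a short secant polish; relative income residuals land at machine
  precision, far below the $10^{-10}$ requirement.
* **The ratio-of-ratios multiplier carries the preference weight.**
  Dividing the two closed forms gives
  $((m_r/m_u)\,w)^{(q_S-q_A)/((1-q_A)(1-q_S))}$. The published form of
  this identity omits $w$ and is exact only for $w = 1$;
  `sp_gp_ratio_multiplier()` therefore takes `w` with default 1, and the
  identity test uses the actual weight.
* **The utility-maximization oracle** (`oracle_max_utility()`) maximizes
  $a\log A + s\log S + z\log Z$ with $Z$ eliminated through the budget,
  by Nelder-Mead plus a BFGS polish on $(\log A, \log S)$ from a neutral
  equal-thirds start. It shares no algebra with the closed form and must
  agree with it to $10^{-5}$ relative over seeded random parameter
  sweeps.
* **One preference weight for both types** by default, mirroring the
  equilibrium conditions; `supply_side_params(preference_weight_sp =)`
  exposes a specialist-specific weight as an extension.
* Elasticities are validated on the open interval $(0,1)$; boundary
  behavior is only probed at offsets in tests, never at the boundary.
* Proposition 4 has no closed form for $\acute a > 0$; it is verified
  numerically on the default grid rather than asserted globally.

### Default parameters

The documented baseline (`default_equilibrium_params()`) is a stylized
German-flavored month: income 2000 (currency), payroll tax 0.15,
co-insurance 0.10, prices 30/45 per GP/specialist service unit, time
valued at 10 per hour over a 160-hour budget, preferences
$(a, s, z) = (1, 1.2, 3)$, urban 100 km² vs rural 400 km² with 100 000
inhabitants each, elasticities $(q_A, q_S) = (0.3, 0.5)$, margins 20/30,
$w = 1.1$, 100 GPs and 60 specialists. With these numbers a visit's time
cost sits near one hour in the urban region — the plausible order of
magnitude. None of these values is estimated; they exist to make the
comparative statics concrete and reproducible.

## 2. The synthetic district generator

The real inputs of the empirical analysis (federal ASHIP physician
counts, official population figures, INKAR indicators for 412 districts
in 17 ASHIP regions) are not publicly deposited. The generator
(`simulate_districts()`) emulates what their published summary table
states, so the pipeline can be tested end to end against known truth:

* **Metric covariates** are drawn from normal distributions truncated to
  the published `[min, max]`, with the published mean/SD as *parent*
  parameters (exact inverse-CDF sampling). Tests compare sample moments
  against the analytic truncated-normal moments, not the parent ones.
* **Covariates are independent by default.** The source reports no
  correlation matrix and we do not invent one silently; a Gaussian-copula
  mode accepts a user-supplied correlation for stress tests.
* **Inhabitants** are log-normal (median 150 000, log-SD 0.8, truncated
  to 35 000–3 500 000) — a synthetic choice, flagged as such, since no
  inhabitants-per-district distribution is published. The district area
  is *derived* as inhabitants/density so the density column is exact by
  construction.
* **Counts** come from the ZTNB model itself:
  $\mu = \exp(\alpha_k + X\beta + \log(\text{inhabitants}/10^4))$,
  negative-binomial draws with variance $\mu + \sigma\mu^2$, zeros
  rejected and redrawn (exact truncation; rejections are vanishingly
  rare at the $\mu$ of interest, which is of order 100).
* **True coefficients** default to the published final-model estimates
  for both count models — using the printed table as the stated world —
  and region intercepts are equally spaced on $[0, 0.25]$, echoing the
  published all-positive pattern against the reference region.
* **Dispersion defaults to $\sigma = 0.05$ for both models.** The
  published table's "Sigma (global deviance)" rows are ambiguous (they
  conflate a dispersion coefficient with a deviance label), and reading
  them as $\log\sigma$ would make the GP model essentially Poisson,
  which is degenerate for dispersion-recovery testing. A single moderate
  value was chosen once and documented; it is config-exposed.
* Variables that dropped out of the published final models (morbidity
  proxies, GDP, nursing beds, several travel times, ...) are generated
  with their published distributions but carry **no effect** in the
  default simulation.

A green test on generated data therefore establishes that the estimation
and selection machinery recovers a *known* ZTNB world with realistic
marginals — not that real German districts satisfy the model: real data
carry spatial autocorrelation, covariate correlation, and non-linear
saturation effects that the generator deliberately does not emulate.

## 3. The zero-truncated negative-binomial engine

Districts with zero physicians do not occur, so the likelihood must
normalize over positive counts:
$\log P(Y = y \mid Y \ge 1) = \log f(y) - \log(1 - f(0))$ with $f$ the
NB pmf in mean-dispersion form (variance $\mu + \sigma\mu^2$). The pmf is
computed through `lbeta`, which stays accurate for $1/\sigma$ up to
$10^5$; base R's `dnbinom` serves as an independent oracle in the tests,
never as the implementation.

* **Two-SD standardization**: metric covariates are centered and divided
  by *two* standard deviations, so a coefficient is the effect of a
  two-SD increase and is directly comparable to a 0/1 binary
  coefficient. Binaries, dummies and interactions are never scaled; an
  interaction column is the product of the transformed parents (scaled
  metric × raw binary), which is what makes "main + interaction"
  coefficient sums meaningful.
* **Region intercepts are fixed dummies** against a configurable
  reference (default: the region with the lowest observed mean density,
  matching how the published reference was chosen). Whether the original
  analysis shrank them is not stated; what it reports — per-region
  coefficients, significance, a named reference — is fixed-effect
  behavior, so fixed dummies were chosen, and random slopes are
  explicitly out of scope.
* **Estimation**: L-BFGS-B on $(\beta, \log\sigma)$ with *analytic*
  gradients (cross-checked against central differences in the suite),
  a deterministic start ($\beta = 0$ except the intercept at the log
  mean density, $\log\sigma = 0$), three seeded jittered restarts
  (SD 0.1), then a Newton polish using the finite-difference Hessian of
  the analytic gradient until the gradient max-norm is below $10^{-6}$.
  $\log\sigma$ is boxed to $[-12, 5]$; the lower bound is the effective
  Poisson limit, and a fit ending there is flagged (`sigma_at_bound`)
  rather than failing the gradient test on a boundary solution.
* **Inference**: covariance is the inverse Hessian; p-values are
  two-sided Wald against the standard normal, with no multiplicity
  correction (matching the original analysis);
  $\mathrm{BIC} = -2\ell + k\log n$ with $k$ counting $\log\sigma$.
* **Back-transformation** uses the *untruncated* mean $e^\eta$, which is
  what reproduces the published arithmetic (log density 1.919 →
  6.81 per 10 000); the truncated mean $\mu/(1 - P_0)$ is available via
  `predicted_density(..., truncated = TRUE)`.

## 4. Cross-model selection

Three models share one term list: GP density and specialist density
(log population offset) and the GP/specialist ratio. The ratio model is
realized as GP counts with offset $\log(\text{SP count})$, so
$e^\eta$ *is* the GP/SP ratio — consistent with the published
back-transformation $e^{-0.178} = 0.837$; the original offset wording
for this model is ambiguous.

Backward stepwise proceeds under the comparability rule: a term
significant at 0.05 in *any* model is kept in *all* models. "Remove the
least significant variable" is operationalized as: among terms
non-significant in all three models, drop the one with the largest
minimum p-value (any other reading contradicts the keep rule), refit,
repeat. Ties break toward the later-entered term; the intercept and
region dummies are never candidates; and a main effect is never removed
while its interaction survives (hierarchy — an implementation guarantee,
not a claim about the original analysis). The union keep rule inflates
null retention to roughly $1 - 0.95^3 \approx 14\%$; the suite asserts
it stays below 25% over seeded replicates.

## 5. What the tests establish

* Closed-form demand equals independent numeric utility maximization to
  $10^{-5}$ relative over 50 seeded draws; the equilibrium solver equals
  the closed forms to $10^{-8}$ at zero co-insurance and satisfies the
  income condition to $10^{-8}$ otherwise.
* The truncated pmf normalizes to $10^{-10}$; fits on near-Poisson
  truncated data agree with an independent truncated-Poisson MLE.
* At $n = 5000$ (seed 1) every true generator coefficient is recovered
  within 3 estimated SEs; over 200 seeded replicates at $n = 2000$ the
  95% Wald intervals cover each true coefficient at 93.5–96.5%.
* On the same seeded world, selection removes a deliberately null
  covariate, keeps all true ones, improves BIC, and reproduces its drop
  path exactly.

Known limitations: no referral linkage between the GP and specialist
markets, no physician-induced demand, no morbidity or quality
heterogeneity, no spatial adjacency in the generator, fixed rather than
random region effects, and linear (post-transformation) covariate
effects throughout.
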
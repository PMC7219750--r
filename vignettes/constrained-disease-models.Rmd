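---
title: "Qualitatively constrained disease-probability models and burden scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitatively constrained disease-probability models and burden scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qihb)
```

## The problem

National health policy needs local, individual-level estimates of what a
behavior change — more exercise, no smoking, better diet — would do to the
prevalence and burden (disability-adjusted life years, DALYs) of chronic
diseases such as ischemic heart disease (IHD) and diabetes. Survey
microdata supply the local joint distribution of behaviors, demographics
and socioeconomics, and a logistic regression on the survey outcomes gives
local relative risks. But unregularized survey regressions routinely
produce effects with the "wrong" sign or non-monotone age profiles,
contradicting the consensus encoded in global meta-analyses of relative
risks (RR). `qihb` implements the middle road: a hierarchical Bayes (HB)
logistic model whose coefficients are *qualitatively* informed — restricted
by sign and monotonicity inequalities extracted from a global RR table —
while the numbers themselves are estimated from the local data.

## The disease probability model

For individual $i$ and disease $d$, the outcome $y_{d,i}$ is Bernoulli with
probability $\theta_{d,i}$ and

$$\operatorname{logit}(\theta_{d,i}) =
\alpha^{demog}_{a[i],g[i]} + \beta^{BMI}_{a[i]} BMI'_i +
\alpha^{phys}_{\cdot} + \beta^{smoke}_{\cdot}\,Smoke_i +
\alpha^{alc}_{g[i],c[i]} + \alpha^{veg}_{v[i]} + \alpha^{fruit}_{f[i]} +
\beta^{secsmoke} SecSmoke_i + \alpha^{trust}_{t[i]} +
\beta^{edu} Edu_i + \beta^{inc} Inc_i + \beta^{meth} Meth_i +
\alpha^{region}_{r[i]},$$

where $BMI' = \max(0, BMI - 22.55)$ is the excess-BMI hinge and $a, g, m,
c, v, f, t, r$ index age bucket (7), gender (2), activity level (4),
alcohol (5), vegetable (5), fruit (5), trusted-individuals (4) and region
(12) categories. The two diseases differ structurally where the global
evidence differs: the IHD activity block varies by age
($\alpha^{phys}_{a,m}$, 21 free coefficients) and its smoking block by age
and gender ($\beta^{smoke}_{a,g}$, 14), while the diabetes model uses a
single activity profile ($\alpha^{phys}_m$, 3) and per-gender smoking
($\beta^{smoke}_g$, 2). In total: 90 free coefficients for IHD, 60 for
diabetes.

**Identifiability.** The age–gender cells $\alpha^{demog}_{a,g}$ act as
per-cell intercepts; there is no separate global intercept. Every other
categorical block drops its first level (Inactive, alcohol "never",
vegetable/fruit "none", trust "0", region 1), whose coefficient is fixed
at 0. The model states references explicitly only for the behavior blocks
(Inactive, Non-smoking, Un-exposed); choosing the first level for the
remaining blocks is the conventional completion.

One structural caveat found while validating on synthetic data: in a
*single-wave* survey the methodology indicator is constant and exactly
collinear with the 14 demographic cells, so $\beta^{meth}$ is unidentified
and the intercept ridge drifts. Multi-wave data (where the indicator
varies) resolve it; any experiment that interprets coefficient recovery
should generate several waves (see `generator_config(years = ...)`).

## Priors and the three flavors

All coefficients have independent normal priors with mean 0. The
hierarchical flavors share one variance per coefficient block (demog, BMI,
phys, smoke, alc, veg, fruit, trust, region, plus one for the scalar
slopes secsmoke/edu/inc/meth), each with an Inverse-Gamma(5, 50)
hyper-prior (prior mean variance 12.5 — weakly informative on the log-odds
scale).

* `prior_qualitative()` — the headline model: the priors are *truncated*
  to the region defined by the compiled inequality constraints (below).
  No numeric external information enters.
* `prior_numerical()` — the traditional benchmark: coefficients matched by
  the RR table get fixed normal priors with mean $\ln(RR)$ and standard
  deviation $(\ln RR_{high} - \ln RR_{low}) / (2 \times 1.959964)$ (the log
  RR and log odds ratio are nearly equal for rare outcomes). Degenerate
  intervals pin the coefficient.
* `prior_noninformative()` — fixed wide normals ($\sigma = 10$), no
  constraints.

## From RR tables to inequality constraints

`extract_patterns()` reduces an RR table to qualitative patterns: a *sign*
pattern when every mean RR for a factor sits on one side of 1, and a
*shape* pattern when the mean RR is monotone (with at least one strict
step) along exposure level or age, checked slice-by-slice so a single
discordant profile suppresses the pattern. `compile_constraints()` turns
patterns into non-strict linear inequalities on named coefficients: signs
constrain every free coefficient of the block; level shapes chain
consecutive non-reference levels (the first non-reference level versus the
reference is already the sign constraint); age shapes chain consecutive
age buckets within each gender or activity level. For IHD the canonical
pattern set compiles to 105 inequalities; for diabetes, whose smoking and
activity blocks carry no age profile, 33.

Two deliberate choices here. First, all inequalities are non-strict and
anchored at zero, so the all-zero vector is always feasible — this is the
sampler's initialization guarantee. Second, the direction of the
smoking-age constraint follows the tabulated pattern (RR *decreasing* with
age, which the reported age profiles corroborate); a
`constraint_direction_override` switch compiles the opposite reading,
which appears in one displayed inequality of the source material's model
description, for sensitivity analysis.

## The sampler

`fit_model()` runs Metropolis-within-Gibbs written in C++ (RcppArmadillo):
random-walk proposals per update unit, accepted with the Metropolis ratio
of Bernoulli-logit likelihood times truncated-normal prior. A proposal
violating any inequality has zero prior density and is rejected — this is
exactly truncation-by-rejection, so *every retained draw is feasible* by
construction. Block variances are refreshed by conjugate inverse-gamma
draws; the conjugacy survives the truncation because the constrained
priors are mean-zero and the feasible region is a cone, whose Gaussian
measure is invariant to the scale $\sigma$.

Two numerical choices matter:

* **Update granularity.** Coefficients belonging to any constraint are
  updated one at a time; unconstrained blocks are proposed jointly. A
  joint perturbation of an order-constrained chain is rejected almost
  surely (measured acceptance ~0 on the 21-coefficient IHD activity
  block), while single-coordinate moves inside the cone accept at normal
  rates.
* **Adaptation.** Proposal scales adapt toward ~30% acceptance during
  burn-in only and are frozen afterwards, preserving detailed balance
  over the retained draws.

Chains start at the zero vector; defaults are 3 chains of 5000 retained
iterations after 1000 burn-in. `gelman_rubin()` reports split-$\hat R$ per
coefficient; the package's working convergence threshold is
$\hat R < 1.1$ (the method description itself states only that convergence
was reached, without a numeric criterion).

## Evaluation and benchmarks

`split_train_holdout()` makes a 70/30 split stratified by survey year
(per-stratum `round(0.7 n)`, R's round-half-to-even; seeded shuffle).
Predictive accuracy uses two measures: `predicted_prevalent_cases()`
(the expected prevalent count $\sum_i \theta_i$ per posterior draw — 1000
draws, or 100 bootstrap refits for the non-Bayesian benchmark via
`fit_logistic_mle_bootstrap()` — summarized as mean and 5th/95th
percentiles) and `auc()` (Mann–Whitney with half-credit ties, verified
against an exhaustive pairwise oracle). `compliance_report()` evaluates
each qualitative pattern on point estimates (posterior means, or MLE) with
non-strict inequalities — a qualitative-flavor fit is compliant on every
row by construction; rows whose shape dimension does not exist for a
disease are excluded from that disease's grid.

## The DALY simulator

A scenario is a record-wise level map (`scenario_increase_activity()`
moves everyone with known activity level up one level,
`scenario_eliminate_smoking()` zeroes smoking and second-hand exposure,
`scenario_increase_fruit_veg()` moves both consumption levels up one);
individuals already at the most desirable level stay unchanged. For each
posterior draw the simulator recomputes every record's disease probability
under base-case and counterfactual covariates — a single joint
counterfactual vector per record, which is what prevents double counting
across behaviors — converts to expected DALYs via the
DALY-per-prevalent-case (DPP) table, $DALY_{d,i,s} = \theta_{d,i|x_{i,s}}
\cdot DPP_{d,a[i],g[i]}$, totals over the population and takes

$$\%\Delta DALY_{d,s} = 100 \cdot
\frac{\sum_i DALY_{d,i,s} - \sum_i DALY_{d,i,base}}
     {\sum_i DALY_{d,i,base}},$$

with the same formula on $\sum_i \theta$ for prevalence. Means and
5th/95th percentiles over (by default) 1000 draws give the 90% interval.
Draws are consumed in stored order, so results are reproducible without a
seed. Because only percent changes are reported, any common multiplier on
the DPP values — sampling rate, self-report bias — cancels exactly (a
tested invariant). Following the weight of cohort evidence against a
protective fruit effect on diabetes, the diabetes fruit coefficients are
zeroed before prediction (`mask_fruit_diabetes = TRUE`, configurable);
this is a scenario-evaluation rule only and never touches fitting or
evaluation.

## The synthetic survey generator

The real microdata are restricted, so `generate_survey()` emulates them.
Behavior marginals default to the published base-case distribution
(activity 18/45/10/27%, smokers 44%, exposed to second-hand smoke 26%,
and the five-level fruit and vegetable frequencies — the printed fruit and
vegetable columns each total 101% from rounding and are normalized).
Fruit–vegetable and smoking–second-hand-smoke dependence is induced by a
two-block latent-Gaussian copula discretized at the marginal quantiles;
the latent correlations are calibrated by bisection on the simulated
sample correlation (n = 10^5, fixed internal seed, common random numbers,
memoized) against the targets 0.49 and 0.14. Demographic and
socioeconomic marginals are package choices plausible for a national
adult survey: a gently declining adult age pyramid, 50/50 gender,
attainment-bucket education years, a standardized log-normal income index
(household equivalization is not modelled — income enters only as a
continuous control), BMI ~ N(26.5, 4.5²) hinged at 22.55, and a 12-region
split. Alcohol is concentrated in the lowest bucket, mirroring the
population in which alcohol RRs were deliberately not used. Activity
missingness is available (`activity_missing`), default 0.

Ground truth for recovery experiments comes from `make_true_params()`:
normal draws projected onto the constraint cone (signed absolute values;
order chains re-sorted along the constraint graph). Two realism choices:
the demographic cells are shifted by −2.2 after ordering so prevalences
sit near 10% rather than 50% (order constraints are shift-invariant), and
the slopes on wide-ranging continuous covariates (BMI excess, education
years, income) are drawn at one tenth the categorical scale — a per-unit
slope of ±0.5 on a 15-unit covariate is not a plausible disease model.

What the generator does *not* emulate: real surveys have complex sampling
designs (strata, clusters, weights), item nonresponse beyond activity,
measurement error, and behavior–demographic dependence beyond the two
calibrated correlations. Passing tests on synthetic data therefore
demonstrate the *algorithms* (constraint enforcement, calibration,
uncertainty propagation), not the substantive conclusions one would draw
from the real survey.

## Test scales and experimental designs

The shipped test suite runs everything at sizes chosen to make each
property measurable on a single CPU: constraint enforcement and
compliance on an n = 5000 fit with 3×1500 retained iterations; point
recovery on n = 20,000 (3×1200); interval calibration over 20 replicates
of n = 5000 with 2×1500 iterations each; generator fidelity at n = 10^5.
Two experimental-design points deserve note. Recovery experiments use a
*multi-wave* generator configuration (three survey years) because of the
single-wave collinearity described above. The interval-calibration
replicates additionally use *balanced* uniform marginals: under the
skewed base-case marginals the fruit/vegetable reference categories
contain 1–2% of records, leaving near-intercept ridges whose
prior-versus-truth split no feasible test size resolves — a property of
the design, not of the sampler being calibrated. The base-case
configuration remains the study condition everywhere it is the object
under test (marginal fidelity, correlations, scenarios).

## Known limitations

* Random-walk Metropolis mixes slowly on strongly correlated blocks;
  badly separated chains show up in split-$\hat R$, which should be
  checked on every fit (no NUTS/HMC here by design).
* The compliance grid is evaluated on point estimates, mirroring the
  single verdict per model of the published comparison; per-draw
  compliance is only guaranteed (and asserted) for the qualitative
  flavor.
* Records with any missing model covariate are dropped from fitting with
  a logged count — no imputation. The simulator keeps such records and
  leaves them untouched by the activity transform.
* Fitting assumes the survey is a representative simple sample; no
  design weights.
* Cross-disease DALY totals are deliberately not produced: they would
  require per-disease self-report bias measurements, which cancel only
  within a disease's percent change.
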
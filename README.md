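# qihb — qualitative informative hierarchical Bayes disease models

`qihb` estimates the impact of population-wide behavior changes — more
physical activity, eliminating smoking and second-hand smoke, higher fruit
and vegetable consumption — on the prevalence and burden
(disability-adjusted life years, DALYs) of chronic diseases such as
ischemic heart disease (IHD) and diabetes, from individual-level health
survey data. It is aimed at epidemiologists and health-policy analysts who
have local survey microdata and want local effect estimates that remain in
*qualitative* agreement with the global relative-risk evidence.

## The method

Each disease gets a hierarchical Bayes logistic regression: for individual
*i*, the outcome is Bernoulli(θᵢ) with

    logit(θᵢ) = α_demog[a,g] + β_BMI[a]·BMI′ + α_phys + β_smoke·Smoke
              + α_alc[g,c] + α_veg[v] + α_fruit[f] + β_secsmoke·SecSmoke
              + α_trust[t] + β_edu·Edu + β_inc·Inc + β_meth·Meth + α_region[r]

with BMI′ = max(0, BMI − 22.55). Coefficients live on the log
relative-risk scale. Priors are mean-zero normals with Inverse-Gamma(5, 50)
block variances, and — this is the contribution — the prior support is
*truncated* to inequality constraints compiled from sign and monotonicity
patterns extracted from a global relative-risk table (e.g., "smoking is
harmful", "its relative risk decreases with age"): 105 inequalities for
the IHD model, 33 for diabetes. A Metropolis-within-Gibbs sampler (C++
core) rejects any proposal outside the feasible cone, so *every* retained
posterior draw satisfies every constraint. Benchmarks (non-informative HB,
numerically informative HB, bootstrapped logistic MLE), holdout
calibration, AUC and a pattern-compliance report are included.

The DALY simulator applies a counterfactual behavior scenario record-wise,
recomputes each individual's disease probability per posterior draw,
converts to expected burden through a DALY-per-prevalent-case (DPP) table,
and reports population-level percent changes in prevalence and DALYs with
90% uncertainty intervals:

    %ΔDALY = 100 · (Σᵢ θᵢ|scenario · DPPᵢ − Σᵢ θᵢ|base · DPPᵢ) / Σᵢ θᵢ|base · DPPᵢ

Because the real survey microdata are restricted, the package ships a
seeded synthetic-survey generator reproducing the published base-case
behavior marginals (44% smokers, …) and behavior correlations
(fruit–vegetable 0.49, smoking–second-hand smoke 0.14) through a
latent-Gaussian copula, plus synthetic stand-ins for the relative-risk and
DPP tables.

## Worked example

```r
library(qihb)

# 1. synthetic base-case survey with known, constraint-feasible truth
spec  <- model_spec("IHD")
cons  <- compile_constraints(default_patterns("IHD"), spec)
truth <- make_true_params(cons, scale = 0.5, seed = 11)
survey <- generate_survey(5000, seed = 21)
survey <- generate_outcomes(survey, true_model(IHD = truth), seed = 22)
mean(survey$IHD)
#> [1] 0.0552

# 2. qualitative-informative fit
fit <- fit_model(survey, spec, prior_qualitative(spec, cons),
                 mcmc = mcmc_config(chains = 2, iterations = 1000,
                                    burn_in = 500, seed = 31))
fit
#> <qihb_posterior> IHD (qualitative): 2000 draws x 90 coefficients, 2 chain(s)
#> max split-Rhat 1.510 (34 coefficient(s) above 1.1)

# every retained draw respects the 105 compiled inequalities
all(apply(fit$draws, 1, check_constraints, constraints = cons))
#> [1] TRUE

# 3. the fit complies with every qualitative pattern (by construction)
all(compliance_report(list(`Qualitative HB` = fit))$pass)
#> [1] TRUE

# 4. posterior-mean smoking coefficient, youngest women -> implied RR
round(coefficient_to_rr(mean(fit$draws[, "smoke[1,F]"])), 2)
#> [1] 2.94

# 5. scenario: everyone with known activity moves up one level
simulate_scenario(survey, scenario_increase_activity(),
                  list(IHD = fit), dpp_table_synthetic(), n_draws = 1000)
#>                     scenario disease    measure  mean    p5   p95
#> 1 Increase Physical Activity     IHD       DALY -24.2 -29.3 -19.1
#> 2 Increase Physical Activity     IHD prevalence -21.7 -26.9 -16.5
```

Reading the output: the synthetic population would see a mean 24.2%
reduction in expected IHD DALYs (90% interval 19.1–29.3%) if everyone
moved up one activity level — large because this particular synthetic
ground truth carries strong activity effects; the constraints guarantee
the reduction is non-positive in every single posterior draw. The example
prints a short diagnostic line with the fit: at these deliberately short
chain lengths some split-R̂ values sit above 1.1, so a production run
should use the defaults (3 × 5000 after 1000 burn-in).

A command-line pipeline (`generate` / `fit` / `simulate`) is available
via `inst/cli/qihb`; see `?qihb_cli`.

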
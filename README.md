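# airwtp

Bayesian multilevel ordinal models of self-rated happiness, and the
life-satisfaction approach to valuing air quality, for two-level urban
surveys (respondents nested in cities).

Surveys of subjective well-being are a standard instrument for valuing
non-market goods: if air pollution lowers reported happiness and income
raises it, the ratio of the two effects prices pollution in currency.
`airwtp` implements that pipeline end to end for ordinal 5-point happiness
data collected across many cities — the default calibration reflects a
43-city urban survey of China's Bohai Rim region — where respondents share
city-level exposures (annual polluted days, climate, economic structure) and
the nesting demands a multilevel model.

## The model

The core is a multilevel cumulative-logit (proportional-odds) regression
with a city random intercept,

    logit P(y_ik <= j) = alpha_j - X_ik' beta - Z_k' gamma - u_k,
    u_k ~ N(0, sigma_u^2),

estimated by Metropolis-within-Gibbs MCMC (adaptive single-site random-walk
updates; conjugate inverse-gamma draw for `sigma_u^2`).  A positive
coefficient raises the odds of reporting higher happiness.  On top of a fit,
the valuation layer computes

* `odds_effect()` — percent change in the odds of higher happiness for a
  reduction in polluted days;
* `marginal_wtp()` — marginal willingness to pay,
  `WTP = (-beta_pollution / gamma_income) * income`, RMB per one-polluted-day
  reduction (income enters the model as a natural log, which is what makes
  this a marginal rate of substitution);
* `compensating_surplus()` —
  `CS = income * (1 - exp((beta_pollution / gamma_income) * delta))` for a
  discrete reduction of `delta` days;
* `per_city_wtp()` / `valuation_report()` — the per-city breakdown and the
  assembled report with draw-wise uncertainty.

Model comparison uses DIC, between-city heterogeneity is summarised by the
variance partitioning coefficient `vpc()`, and convergence by split-chain
Gelman–Rubin.  A calibrated synthetic-survey generator
(`default_scenario()`, `simulate_survey()`) reproduces the survey's
covariate structure so the whole pipeline is testable without microdata.
See `vignette("airwtp-methods")` for the full methods account.

## Worked example

```r
library(airwtp)

survey <- simulate_survey(default_scenario(seed = 1))
survey
#> Synthetic two-level survey: 6285 respondents in 43 cities (seed 1)

fit <- run_mcmc(survey$individuals, survey$cities, spec_model_ladder()$model3,
                config = mcmc_config(n_chains = 2, n_iterations = 5000,
                                     burn_in = 2000, thin = 5, seed = 1))
posterior_summary(fit)[c(5, 16, 65), ]
#>              parameter   median     q2.5    q97.5 signif
#> 5      beta_log_income  0.27182  0.20773 0.330322    ***
#> 16 gamma_polluted_days -0.00133 -0.00333 0.000817
#> 65            sigma_u2  0.12101  0.07142 0.226665    ***

valuation_report(fit, survey$individuals, survey$cities)
#> Willingness to pay for air-quality improvement
#>   coefficients (posterior medians): pollution -0.0013, log-income 0.272
#>   regional mean monthly income: 7120 RMB
#>   marginal WTP: 34.8 RMB per polluted-day reduction (0.49% of monthly income)
#>   95% draw-wise WTP interval: [-21.5, 91.4] RMB
#>   compensating surplus for a 69-day reduction: 2040 RMB (2.39% of annual income)
#>   per-city WTP range: 29.5-39.2 RMB across 43 cities
```

The generating truths here are a log-income coefficient of 0.28 and a
pollution coefficient of −0.003 per polluted day.  The income effect is
recovered tightly; the pollution effect — identified from only 43 city-level
exposures — carries wide uncertainty, which the draw-wise WTP interval makes
visible (this seed's interval spans zero).  `worked_examples()` prints the
package's desk-scale checks against published reference values:

```r
worked_examples()
#>                            check   computed reference pass
#>  odds_effect_69day_reduction_pct  14.797555     15.00 TRUE
#>  wtp_share_of_monthly_income_pct   1.417064      1.42 TRUE
#>        mean_respondents_per_city 152.372093    152.00 TRUE
#>           polluted_day_share_pct  41.917808     42.00 TRUE
#>          low_happiness_share_pct   4.350000      4.30 TRUE
```

A thin command-line wrapper ships in `inst/cli/airwtp.R`
(`simulate` / `fit` / `valuate` / `robustness` / `worked-examples`).

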
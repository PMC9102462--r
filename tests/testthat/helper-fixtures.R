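# Shared fixtures: scaled-down scenarios and MCMC configs for fast tests.

# Default-calibrated scenario with a reduced two-level size.
make_scenario <- function(seed = 1L, n_cities = 6L, size = c(30L, 40L),
                          sigma_u2 = 0.1) {
  cfg <- default_scenario(seed = seed)
  cfg$n_cities <- as.integer(n_cities)
  cfg$city_size_range <- as.integer(size)
  cfg$true_parameters$sigma_u2 <- sigma_u2
  cfg
}

quick_mcmc <- function(seed = 1L, n_chains = 1L, n_iterations = 800L,
                       burn_in = 300L, thin = 5L) {
  mcmc_config(n_chains = n_chains, n_iterations = n_iterations,
              burn_in = burn_in, thin = thin, seed = seed)
}

# Minimal posterior_draws object built from a raw draws matrix, for testing
# summary/diagnostic/DIC code paths without running the sampler.
fake_draws <- function(draws, chain = rep(1L, nrow(draws)), spec = NULL) {
  structure(list(draws = draws, chain = chain,
                 config = list(n_chains = length(unique(chain))),
                 spec = spec),
            class = "posterior_draws")
}

# Degenerate scenario: every covariate is constant, sigma_u2 = 0, so the
# latent linear predictor is a known scalar and closed-form category
# probabilities are exact.  Thresholds are placed at eta + logit(cumprobs),
# giving the requested marginal category distribution.
constant_covariate_scenario <- function(seed = 1L, n_cities = 2L,
                                        per_city = 25000L,
                                        target = rep(0.2, 5)) {
  beta <- c(log_income = 0.28, commodity = -0.05, owner = 0.40, male = -0.15,
            age_band = -0.02, college = 0.13, married = 0.30,
            health2 = 0.60, health3 = 1.20, health4 = 1.80, health5 = 2.20)
  gamma <- c(polluted_days = -0.003, wind = 0.30, temperature = 0.03,
             industry_share = 0.01, gdp_pc_10k = 0.01, precipitation = 2e-4)
  city_means <- c(polluted_days = 153, wind = 2.40, temperature = 12,
                  precipitation = 594, gdp_pc = 60217, industry_share = 46.69)
  eta <- 0.28 * log(5000) + 0.40 + (-0.15) + 0.30 + (-0.02) * 2 + 1.80 +
    (-0.003) * 153 + 0.30 * 2.40 + 0.03 * 12 + 0.01 * 46.69 +
    0.01 * 60217 / 1e4 + 2e-4 * 594
  alpha <- eta + qlogis(cumsum(target)[-length(target)])
  truth <- model_parameters(alpha, beta, gamma, sigma_u2 = 0)
  names(truth$beta) <- names(beta); names(truth$gamma) <- names(gamma)
  scenario_config(
    n_cities = n_cities, city_size_range = c(per_city, per_city),
    city_means = city_means,
    city_sds = c(polluted_days = 0, wind = 0, temperature = 0,
                 precipitation = 0, gdp_pc = 0, industry_share = 0),
    gdp_industry_corr = 0.5,
    income_log_mean = log(5000), income_log_sd = 0,
    income_bands = default_income_bands(),
    proportions = c(male = 1, college = 0, married = 1, owner = 1,
                    commodity = 0, local_hukou = 1),
    age_probs = c(0, 1, 0, 0, 0), health_probs = c(0, 0, 0, 1, 0),
    true_parameters = truth, seed = seed)
}
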
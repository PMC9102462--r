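test_that("vpc follows the logistic variance partition formula", {
  expect_equal(vpc(0), 0)
  expect_equal(vpc(pi^2 / 3), 0.5)
  expect_equal(round(vpc(0.113), 4), 0.0332)
  expect_equal(vpc(0.113), 0.113 / (0.113 + pi^2 / 3), tolerance = 1e-15)
  expect_error(vpc(-0.1), "non-negative")
})

test_that("posterior summary uses type-7 quantiles and interval-based stars", {
  m <- cbind(theta = as.numeric(1:100))
  s <- posterior_summary(m)
  expect_equal(s$median, 50.5)
  expect_equal(s$q2.5, 3.475)
  expect_equal(s$q97.5, 97.525)
  expect_equal(s$signif, "***")     # all draws positive
  # degenerate sample: median = c, CI = [c, c]
  s2 <- posterior_summary(cbind(c = rep(3.2, 50)))
  expect_equal(unlist(s2[, c("median", "q2.5", "q97.5")],
                      use.names = FALSE), rep(3.2, 3))
  # a parameter significant at 90% but not 95%: build draws whose 5% quantile
  # is above 0 but whose 2.5% quantile is below 0
  set.seed(1)
  x <- qnorm(ppoints(4000), mean = 1.8, sd = 1)   # z = 1.8: in (1.645, 1.96)
  expect_equal(posterior_summary(cbind(x = x))$signif, "*")
})

test_that("split Gelman-Rubin matches the textbook formula and edge cases", {
  spec <- NULL
  # hand-computed two-chain example, each chain length 4
  x <- c(1, 2, 3, 4, 1, 3, 5, 7)
  fd <- fake_draws(cbind(theta = x), chain = rep(1:2, each = 4))
  halves <- list(c(1, 2), c(3, 4), c(1, 3), c(5, 7))
  W <- mean(vapply(halves, var, numeric(1)))
  B <- 2 * var(vapply(halves, mean, numeric(1)))
  expected <- sqrt(((2 - 1) / 2 * W + B / 2) / W)
  expect_equal(unname(gelman_rubin(fd)["theta"]), expected, tolerance = 1e-12)
  # identical chains -> 1 on a long run
  z <- rep(sin(1:500), 2)
  fd2 <- fake_draws(cbind(theta = z), chain = rep(1:2, each = 500))
  expect_equal(unname(gelman_rubin(fd2)["theta"]), 1, tolerance = 1e-2)
  # chains offset by a large constant -> far above 1
  fd3 <- fake_draws(cbind(theta = c(rnorm(200), rnorm(200) + 50)),
                    chain = rep(1:2, each = 200))
  expect_gt(gelman_rubin(fd3)["theta"], 3)
  fd1 <- fake_draws(cbind(theta = rnorm(10)), chain = rep(1L, 10))
  expect_error(gelman_rubin(fd1), "2 chains")
})

test_that("the sampler is deterministic given the seed and keeps draws valid", {
  sv <- simulate_survey(make_scenario(seed = 6))
  spec <- spec_model_ladder()$model1
  cfg <- quick_mcmc(seed = 31, n_chains = 2L)
  f1 <- run_mcmc(sv$individuals, sv$cities, spec, config = cfg)
  f2 <- run_mcmc(sv$individuals, sv$cities, spec, config = cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- run_mcmc(sv$individuals, sv$cities, spec,
                 config = quick_mcmc(seed = 32, n_chains = 2L))
  expect_false(identical(f1$draws, f3$draws))
  # retained-draw invariants: strictly ordered thresholds, positive variance
  a <- f1$draws[, paste0("alpha", 1:4)]
  expect_true(all(apply(a, 1, function(r) all(diff(r) > 0))))
  expect_true(all(f1$draws[, "sigma_u2"] > 0))
  expect_equal(nrow(f1$draws),
               2 * (cfg$n_iterations - cfg$burn_in) %/% cfg$thin)
})

test_that("post-adaptation acceptance rates stay in a sane band", {
  sv <- simulate_survey(make_scenario(seed = 14, n_cities = 8L,
                                      size = c(60L, 80L)))
  fit <- run_mcmc(sv$individuals, sv$cities, spec_model_ladder()$model2,
                  config = quick_mcmc(seed = 3, n_iterations = 1500L,
                                      burn_in = 600L))
  expect_true(all(fit$acceptance >= 0.1 & fit$acceptance <= 0.6))
})

test_that("an empty response category triggers a warning, not an error", {
  sv <- simulate_survey(make_scenario(seed = 2, n_cities = 3L,
                                      size = c(12L, 15L)))
  sv$individuals$happiness[sv$individuals$happiness == 1] <- 2L
  expect_warning(
    run_mcmc(sv$individuals, sv$cities, spec_model_ladder()$model1,
             config = quick_mcmc(seed = 5, n_iterations = 400L,
                                 burn_in = 150L, thin = 2L)),
    "empty categories")
})

test_that("DIC reduces to the plug-in deviance for degenerate draws and matches a loop oracle", {
  sv <- simulate_survey(make_scenario(seed = 8, n_cities = 5L,
                                      size = c(10L, 10L)))
  spec <- spec_model_ladder()$model1
  des <- build_design(sv$individuals, sv$cities, spec)
  p <- ncol(des$X); q <- ncol(des$Z)
  nm <- c(paste0("alpha", 1:4), paste0("beta_", colnames(des$X)),
          paste0("gamma_", colnames(des$Z)),
          paste0("u[", sv$cities$city_id, "]"), "sigma_u2")
  theta <- c(sort(rnorm(4, 0, 1.5)), rnorm(p, 0, 0.2), rnorm(q, 0, 0.01),
             rnorm(des$K, 0, 0.2), 0.1)
  const <- matrix(theta, nrow = 40, ncol = length(theta), byrow = TRUE,
                  dimnames = list(NULL, nm))
  dic0 <- compute_dic(fake_draws(const, spec = spec), sv$individuals,
                      sv$cities)
  params <- model_parameters(theta[1:4], theta[4 + seq_len(p)],
                             theta[4 + p + seq_len(q)],
                             theta[4 + p + q + seq_len(des$K)], 0.1)
  dev_star <- -2 * log_likelihood(sv$individuals, sv$cities, spec, params)
  expect_equal(dic0$pD, 0, tolerance = 1e-8)
  expect_equal(dic0$dic, dev_star, tolerance = 1e-8)
  # random draws: brute-force loop over draws and respondents
  set.seed(17)
  draws <- t(replicate(30, c(sort(rnorm(4, 0, 1.5)), rnorm(p, 0, 0.2),
                             rnorm(q, 0, 0.01), rnorm(des$K, 0, 0.2),
                             exp(rnorm(1, -2, 0.3)))))
  colnames(draws) <- nm
  dic <- compute_dic(fake_draws(draws, spec = spec), sv$individuals,
                     sv$cities)
  devs <- numeric(30)
  for (s in 1:30) {
    ll <- 0
    for (i in seq_along(des$y)) {
      eta <- sum(des$X[i, ] * draws[s, 4 + seq_len(p)]) +
        sum(des$Z[i, ] * draws[s, 4 + p + seq_len(q)]) +
        draws[s, 4 + p + q + des$city_index[i]]
      probs <- diff(c(0, plogis(draws[s, 1:4] - eta), 1))
      ll <- ll + log(probs[des$y[i]])
    }
    devs[s] <- -2 * ll
  }
  tb <- colMeans(draws)
  ll_hat <- 0
  for (i in seq_along(des$y)) {
    eta <- sum(des$X[i, ] * tb[4 + seq_len(p)]) +
      sum(des$Z[i, ] * tb[4 + p + seq_len(q)]) +
      tb[4 + p + q + des$city_index[i]]
    probs <- diff(c(0, plogis(tb[1:4] - eta), 1))
    ll_hat <- ll_hat + log(probs[des$y[i]])
  }
  Dbar <- mean(devs); pD <- unname(Dbar - (-2 * ll_hat))
  expect_equal(dic$Dbar, Dbar, tolerance = 1e-8)
  expect_equal(dic$pD, pD, tolerance = 1e-8)
  expect_equal(dic$dic, Dbar + pD, tolerance = 1e-8)
})

test_that("the posterior concentrates near the maximum-likelihood fit", {
  skip_if_not_installed("MASS")
  cfg <- make_scenario(seed = 33, n_cities = 10L, size = c(190L, 210L),
                       sigma_u2 = 0)
  sv <- simulate_survey(cfg)
  spec <- spec_model_ladder()$model2
  fit <- run_mcmc(sv$individuals, sv$cities, spec,
                  config = quick_mcmc(seed = 12, n_iterations = 3000L,
                                      burn_in = 1200L))
  s <- posterior_summary(fit)
  pf <- prepare_model_frame(sv$individuals, sv$cities)
  dat <- merge(pf$individuals, pf$cities, by = "city_id")
  dat$happiness <- factor(dat$happiness, levels = 1:5, ordered = TRUE)
  ml <- MASS::polr(happiness ~ log_income + commodity + owner + male +
                     age_band + college + married + polluted_days + wind +
                     temperature + industry_share + gdp_pc_10k +
                     precipitation, data = dat, method = "logistic")
  for (nm in c("log_income", "polluted_days", "owner", "married")) {
    row <- s[s$parameter %in% paste0(c("beta_", "gamma_"), nm), ]
    post_sd <- (row$q97.5 - row$q2.5) / (2 * qnorm(0.975))
    expect_lt(abs(row$median - unname(coef(ml)[nm])), 2 * post_sd)
  }
})

test_that("draws export includes chain ids and parameter labels", {
  sv <- simulate_survey(make_scenario(seed = 4, n_cities = 3L,
                                      size = c(12L, 15L)))
  fit <- suppressWarnings(
    run_mcmc(sv$individuals, sv$cities, spec_model_ladder()$model1,
             config = quick_mcmc(seed = 1, n_chains = 2L,
                                 n_iterations = 300L, burn_in = 100L,
                                 thin = 2L)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read.csv(path, check.names = FALSE)
  expect_identical(names(back), c("chain", colnames(fit$draws)))
  expect_equal(sort(unique(back$chain)), 1:2)
  expect_equal(nrow(back), nrow(fit$draws))
})
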
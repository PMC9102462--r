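make_one_row <- function(income_band = 4L, city_id = "c1") {
  list(
    individuals = data.frame(
      city_id = city_id, happiness = 3L, income_band = income_band,
      income_rmb = 5000, male = 0L, college = 0L, married = 0L, owner = 0L,
      commodity = 0L, local_hukou = 1L, age_band = 1L, health = 1L),
    cities = data.frame(
      city_id = "c1", polluted_days = 0L, wind = 1, temperature = 0,
      precipitation = 0, gdp_pc = 1, industry_share = 0, mean_income = 5000))
}

test_that("income band conversion uses midpoints and the 1.5x top-band rule", {
  expect_equal(income_to_continuous(1), 1000)    # [0, 2000)
  expect_equal(income_to_continuous(3), 5000)    # [4000, 6000)
  expect_equal(income_to_continuous(7), 30000)   # open top band, 1.5 x 20000
  expect_equal(income_to_continuous(c(2, 5, 6)), c(3000, 10000, 16000))
  expect_error(income_to_continuous(8), "out of range")
  expect_error(income_to_continuous(0), "out of range")
  expect_identical(income_to_band(c(1999, 2000, 25000)), c(1L, 2L, 7L))
})

test_that("category collapsing merges the extremes and conserves counts", {
  expect_identical(collapse_categories(1:5), c(1L, 1L, 2L, 3L, 3L))
  # the reported happiness distribution, collapsed: low share ~4.35%,
  # high share ~68.9%
  pct <- c(1.11, 3.24, 26.76, 51.18, 17.72)
  collapsed <- as.numeric(tapply(pct, collapse_categories(1:5), sum))
  expect_equal(collapsed, c(4.35, 26.76, 68.90), tolerance = 1e-12)
  expect_equal(sum(collapsed), sum(pct))
  set.seed(1)
  y <- sample(1:5, 500, replace = TRUE)
  expect_equal(length(collapse_categories(y)), length(y))
  expect_error(collapse_categories(c(1L, 6L)), "outside 1..5")
})

test_that("linear predictor is the dot product plus the city effect", {
  d <- make_one_row()
  spec0 <- model_spec(individual = "male", city = "polluted_days")
  # all coefficients and effects zero -> eta = 0
  expect_equal(linear_predictor(d$individuals, d$cities, spec0,
                                model_parameters(0, 0, 0, 0, 0)), 0)
  # single predictor x = 2, beta = 0.5, u = 0.1 -> eta = 1.1
  d2 <- make_one_row()
  d2$individuals$age_band <- 2L
  spec1 <- model_spec(individual = "age_band", city = character())
  expect_equal(linear_predictor(d2$individuals, d2$cities, spec1,
                                model_parameters(0, beta = 0.5,
                                                 u = 0.1)), 1.1)
  # log-income transform at gamma_income = 0.284 and income 6704 RMB:
  # eta = 0.284 * ln(6704) ~ 2.503
  spec2 <- model_spec(individual = "log_income", city = character())
  d3 <- make_one_row()
  pf <- prepare_model_frame(d3$individuals, d3$cities)
  pf$individuals$log_income <- log(6704)
  eta <- drop(as.matrix(pf$individuals[, "log_income", drop = FALSE]) %*%
                0.284)
  expect_equal(eta, 0.284 * log(6704), tolerance = 1e-15)
  expect_equal(0.284 * log(6704), 2.503, tolerance = 1e-3)
  # via the prepared frame: band 5 is [8000, 12000) with midpoint 10000
  d4 <- make_one_row(income_band = 5L)
  eta4 <- linear_predictor(d4$individuals, d4$cities, spec2,
                           model_parameters(0, beta = 0.284, u = 0))
  expect_equal(eta4, 0.284 * log(10000), tolerance = 1e-12)
  expect_error(
    linear_predictor(d$individuals, d$cities,
                     model_spec(individual = "no_such_col", city = character()),
                     model_parameters(0, beta = 1)),
    "no_such_col")
})

test_that("category probabilities are logistic-CDF differences", {
  expect_equal(as.numeric(category_probabilities(0, 0)), c(0.5, 0.5))
  p <- as.numeric(category_probabilities(0, c(-1, 1)))
  expect_equal(p, c(plogis(-1), plogis(1) - plogis(-1), 1 - plogis(1)),
               tolerance = 1e-15)
  expect_equal(round(p, 5), c(0.26894, 0.46212, 0.26894))
  p2 <- as.numeric(category_probabilities(0.5, c(-1, 1)))
  expect_equal(round(p2, 5), c(0.18243, 0.44003, 0.37754))
  expect_error(category_probabilities(0, c(1, -1)), "strictly increasing")
  # oracle: direct logistic-CDF differences across random cases, to 1e-12
  set.seed(42)
  for (rep in 1:25) {
    alpha <- sort(rnorm(4, 0, 2))
    eta <- rnorm(7, 0, 3)
    p <- category_probabilities(eta, alpha)
    oracle <- t(vapply(eta, function(e) {
      cum <- c(plogis(alpha - e), 1)
      diff(c(0, cum))
    }, numeric(5)))
    expect_equal(p, oracle, tolerance = 1e-12)
    expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("larger eta shifts mass toward higher categories", {
  alpha <- c(-1.5, 0, 1.5, 3)
  etas <- seq(-4, 4, by = 0.5)
  cum <- t(vapply(etas, function(e) {
    cumsum(as.numeric(category_probabilities(e, alpha)))[1:4]
  }, numeric(4)))
  for (j in 1:4) expect_true(all(diff(cum[, j]) < 0))
})

test_that("collapsed thresholds reproduce summed 5-category probabilities", {
  alpha <- c(-2, -0.7, 0.8, 2.1)
  for (eta in c(-1, 0, 0.6, 2)) {
    p5 <- as.numeric(category_probabilities(eta, alpha))
    p3 <- as.numeric(category_probabilities(eta, alpha[2:3]))
    expect_equal(p3, as.numeric(tapply(p5, collapse_categories(1:5), sum)),
                 tolerance = 1e-12)
  }
})

test_that("log-likelihood matches a brute-force per-respondent oracle", {
  # uniform-probability parameterization over 5 categories: ln(0.2)
  d <- make_one_row()
  spec <- model_spec(individual = character(), city = character())
  alpha_unif <- qlogis(c(0.2, 0.4, 0.6, 0.8))
  expect_equal(log_likelihood(d$individuals, d$cities, spec,
                              model_parameters(alpha_unif, u = 0)),
               log(0.2), tolerance = 1e-12)
  # 50-respondent synthetic dataset, 100 random parameter draws
  sv <- simulate_survey(make_scenario(seed = 8, n_cities = 5L,
                                      size = c(10L, 10L)))
  spec2 <- spec_model_ladder()$model2
  des <- build_design(sv$individuals, sv$cities, spec2)
  set.seed(99)
  for (rep in 1:100) {
    params <- model_parameters(sort(rnorm(4, 0, 2)),
                               beta = rnorm(ncol(des$X), 0, 0.3),
                               gamma = rnorm(ncol(des$Z), 0, 0.02),
                               u = rnorm(des$K, 0, 0.3),
                               sigma_u2 = 0.1)
    ll <- log_likelihood(sv$individuals, sv$cities, spec2, params)
    # oracle: enumerate each respondent's full probability vector and pick
    # the observed entry
    eta <- drop(des$X %*% params$beta) + drop(des$Z %*% params$gamma) +
      params$u[des$city_index]
    oracle <- 0
    for (i in seq_along(des$y)) {
      cum <- c(plogis(params$alpha - eta[i]), 1)
      probs <- diff(c(0, cum))
      oracle <- oracle + log(probs[des$y[i]])
    }
    expect_equal(ll, oracle, tolerance = 1e-10)
  }
  expect_error(
    log_likelihood(transform(d$individuals, happiness = 9L), d$cities, spec,
                   model_parameters(alpha_unif, u = 0)),
    "outside")
})

test_that("a positive coefficient raises the odds of higher happiness", {
  d <- make_one_row()
  spec <- model_spec(individual = "male", city = character())
  d$individuals$male <- 1L
  p_base <- category_probabilities(
    linear_predictor(d$individuals, d$cities, spec,
                     model_parameters(c(-1, 0, 1, 2), beta = 0, u = 0)),
    c(-1, 0, 1, 2))
  p_up <- category_probabilities(
    linear_predictor(d$individuals, d$cities, spec,
                     model_parameters(c(-1, 0, 1, 2), beta = 0.8, u = 0)),
    c(-1, 0, 1, 2))
  expect_gt(p_up[5], p_base[5])
  expect_lt(p_up[1], p_base[1])
})
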
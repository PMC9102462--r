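#' Default monthly income bands (RMB)
#'
#' Seven ordered, disjoint bands covering (0, Inf) with an open-ended top
#' band, encoded as the vector of band boundaries.  Band `b` is the interval
#' `[bounds[b], bounds[b + 1])`.  The defaults bracket a survey mean monthly
#' household income of roughly 6,900 RMB with a standard deviation of roughly
#' 5,300 RMB.
#'
#' @return Numeric vector of length 8: lower bounds of the 7 bands plus `Inf`.
#' @export
default_income_bands <- function() {
  c(0, 2000, 4000, 6000, 8000, 12000, 20000, Inf)
}

#' Convert an ordinal income band to a continuous monthly income
#'
#' Closed bands map to their midpoint; the open-ended top band maps to 1.5
#' times its lower bound (a simple, documented extrapolation rule for the
#' right tail).
#'
#' @param band Integer vector of band indices in `1..(length(bounds) - 1)`.
#' @param bounds Band boundaries as in [default_income_bands()].
#' @return Numeric vector of RMB/month values, one per element of `band`.
#' @examples
#' income_to_continuous(3)            # [4000, 6000) -> 5000
#' income_to_continuous(7)            # >= 20000     -> 30000
#' @export
income_to_continuous <- function(band, bounds = default_income_bands()) {
  n_bands <- length(bounds) - 1L
  if (!all(is.finite(band) | is.na(band))) stop("income band must be finite")
  band <- as.integer(band)
  if (any(band < 1L | band > n_bands, na.rm = TRUE)) {
    stop(sprintf("income band out of range 1..%d", n_bands))
  }
  mid <- (bounds[-length(bounds)] + bounds[-1]) / 2
  mid[n_bands] <- 1.5 * bounds[n_bands]
  mid[band]
}

#' Map an income in RMB to its band index
#' @param income_rmb Positive numeric vector.
#' @inheritParams income_to_continuous
#' @return Integer band indices.
#' @export
income_to_band <- function(income_rmb, bounds = default_income_bands()) {
  findInterval(income_rmb, bounds, rightmost.closed = FALSE)
}

#' Collapse a 5-point happiness rating to 3 categories
#'
#' Combines the two lowest ratings ("very unhappy", "unhappy") into one
#' category and the two highest ("happy", "very happy") into another, leaving
#' the middle rating as its own category: `{1,2} -> 1`, `{3} -> 2`,
#' `{4,5} -> 3`.  Counts are conserved.
#'
#' @param y Integer vector with values in `1..5`.
#' @return Integer vector with values in `1..3`.
#' @export
collapse_categories <- function(y) {
  if (any(!y %in% 1:5)) stop("happiness rating outside 1..5")
  c(1L, 1L, 2L, 3L, 3L)[y]
}

#' Specify a multilevel cumulative-logit happiness model
#'
#' A model specification names the ordinal response, the individual-level
#' design columns (entering \eqn{X'\beta}) and the city-level design columns
#' (entering \eqn{Z'\gamma}).  Columns are taken from the prepared model
#' frame (see [prepare_model_frame()]), where income already appears as the
#' natural log of the band-midpoint monthly income and per-capita GDP in
#' 10,000-RMB units.
#'
#' @param response Response column name (ordinal, coded `1..n_categories`).
#' @param individual Character vector of individual-level predictor columns.
#' @param city Character vector of city-level predictor columns.
#' @param n_categories Number of ordinal categories `J >= 2`.
#' @param income_column Name of the (log) income predictor used by the
#'   valuation layer; must be listed in `individual` when valuation is wanted.
#' @param transforms Named character vector recording, per raw variable, the
#'   transform applied during preparation (`"identity"` or `"log"`).
#'   Metadata only; the transforms themselves are applied by
#'   [prepare_model_frame()].
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(response = "happiness",
                       individual = character(),
                       city = character(),
                       n_categories = 5L,
                       income_column = "log_income",
                       transforms = c(log_income = "log")) {
  n_categories <- as.integer(n_categories)
  if (n_categories < 2L) stop("n_categories must be at least 2")
  if (length(intersect(individual, city)) > 0) {
    stop("individual and city predictor lists must be disjoint")
  }
  structure(
    list(response = response,
         individual = individual,
         city = city,
         n_categories = n_categories,
         income_column = income_column,
         transforms = transforms),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Multilevel cumulative-logit model spec\n")
  cat("  response:   ", x$response, " (", x$n_categories, " categories)\n", sep = "")
  cat("  individual: ", paste(x$individual, collapse = ", "), "\n", sep = "")
  cat("  city:       ", paste(x$city, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Model parameters for the multilevel cumulative-logit model
#'
#' @param alpha Strictly increasing vector of `J - 1` thresholds on the
#'   latent-happiness scale.
#' @param beta Coefficients for the individual-level design columns.
#' @param gamma Coefficients for the city-level design columns.
#' @param u City random intercepts (one per city, mean-zero on the latent
#'   scale).
#' @param sigma_u2 Between-city variance, `>= 0`.
#' @return An object of class `"model_parameters"`.
#' @export
model_parameters <- function(alpha, beta = numeric(), gamma = numeric(),
                             u = numeric(), sigma_u2 = 0) {
  if (length(alpha) > 1L && any(diff(alpha) <= 0)) {
    stop("thresholds alpha must be strictly increasing")
  }
  if (sigma_u2 < 0) stop("sigma_u2 must be non-negative")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), u = as.numeric(u),
                 sigma_u2 = as.numeric(sigma_u2)),
            class = "model_parameters")
}

#' Prior specification
#'
#' Independent mean-zero normal priors with a large common variance for every
#' threshold and regression coefficient, and an inverse-gamma prior for the
#' between-city variance.
#'
#' @param coef_prior_variance Prior variance for thresholds and coefficients
#'   (default `1e6`, effectively diffuse).
#' @param ig_shape,ig_scale Inverse-gamma hyperparameters for `sigma_u2`
#'   (default `0.001, 0.001`).
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(coef_prior_variance = 1e6, ig_shape = 0.001,
                       ig_scale = 0.001) {
  if (coef_prior_variance <= 0 || ig_shape <= 0 || ig_scale <= 0) {
    stop("all prior hyperparameters must be strictly positive")
  }
  structure(list(coef_prior_variance = coef_prior_variance,
                 ig_shape = ig_shape, ig_scale = ig_scale),
            class = "prior_spec")
}

#' Prepare the model frame from raw individual and city tables
#'
#' Derives the design columns used by the standard model ladder:
#' * `income_mid` — band-midpoint monthly income (RMB), via
#'   [income_to_continuous()];
#' * `log_income` — its natural log (the valuation layer requires the log
#'   form so that the coefficient ratio is a marginal rate of substitution);
#' * `health2`..`health5` — self-rated health dummies against the lowest
#'   ("very bad") reference category;
#' * `gdp_pc_10k` — per-capita GDP rescaled to 10,000-RMB units to keep its
#'   coefficient away from machine precision.
#'
#' @param individuals Individual-level data frame (see [simulate_survey()]
#'   for the column schema).
#' @param cities City-level data frame.
#' @param bounds Income-band boundaries.
#' @return List with prepared `individuals` and `cities` data frames.
#' @export
prepare_model_frame <- function(individuals, cities,
                                bounds = default_income_bands()) {
  ind <- as.data.frame(individuals)
  cty <- as.data.frame(cities)
  if ("income_band" %in% names(ind)) {
    ind$income_mid <- income_to_continuous(ind$income_band, bounds)
    ind$log_income <- log(ind$income_mid)
  }
  if ("health" %in% names(ind)) {
    for (h in 2:5) ind[[paste0("health", h)]] <- as.integer(ind$health == h)
  }
  if ("gdp_pc" %in% names(cty)) cty$gdp_pc_10k <- cty$gdp_pc / 1e4
  list(individuals = ind, cities = cty)
}

design_matrix <- function(df, cols, level) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("missing %s-level covariate column(s): %s", level,
                 paste(missing, collapse = ", ")))
  }
  if (length(cols) == 0L) {
    return(matrix(0, nrow = nrow(df), ncol = 0))
  }
  as.matrix(df[, cols, drop = FALSE])
}

#' Build the numerical design for a model specification
#'
#' @inheritParams linear_predictor
#' @return List with response `y`, individual design `X`, per-observation
#'   city design `Z`, the 1-based `city_index` into the city table, and the
#'   city count `K`.
#' @export
build_design <- function(individuals, cities, spec) {
  pf <- prepare_model_frame(individuals, cities)
  ind <- pf$individuals
  cty <- pf$cities
  city_index <- match(ind$city_id, cty$city_id)
  if (any(is.na(city_index))) {
    bad <- which(is.na(city_index))[1]
    stop(sprintf("row %d cites unknown city_id '%s'", bad, ind$city_id[bad]))
  }
  y <- as.integer(ind[[spec$response]])
  if (any(!y %in% seq_len(spec$n_categories))) {
    stop(sprintf("response '%s' outside 1..%d", spec$response,
                 spec$n_categories))
  }
  X <- design_matrix(ind, spec$individual, "individual")
  Zc <- design_matrix(cty, spec$city, "city")
  Z <- Zc[city_index, , drop = FALSE]
  list(y = y, X = X, Z = Z, city_index = city_index, K = nrow(cty))
}

#' Latent-scale linear predictor
#'
#' Computes \eqn{\eta_{ik} = X_{ik}'\beta + Z_k'\gamma + u_k} for every
#' respondent, applying the declared income transform through the prepared
#' model frame.  Under the threshold link
#' \eqn{\mathrm{logit}\,P(y \le j) = \alpha_j - \eta}, a positive coefficient
#' raises the odds of reporting a higher happiness category.
#'
#' @param individuals Individual-level data frame.
#' @param cities City-level data frame.
#' @param spec A [model_spec()].
#' @param params A [model_parameters()]; `beta`, `gamma` and `u` must match
#'   the design dimensions (`u` may be empty, read as all-zero).
#' @return Numeric vector of latent-scale linear predictors.
#' @export
linear_predictor <- function(individuals, cities, spec, params) {
  d <- build_design(individuals, cities, spec)
  if (length(params$beta) != ncol(d$X)) {
    stop("beta length does not match the individual-level design")
  }
  if (length(params$gamma) != ncol(d$Z)) {
    stop("gamma length does not match the city-level design")
  }
  u <- params$u
  if (length(u) == 0L) u <- rep(0, d$K)
  if (length(u) != d$K) stop("u must have one entry per city")
  eta <- drop(d$X %*% params$beta) + drop(d$Z %*% params$gamma) +
    u[d$city_index]
  as.numeric(eta)
}

#' Category probabilities under the cumulative-logit link
#'
#' For thresholds \eqn{\alpha_1 < \dots < \alpha_{J-1}} and linear predictor
#' \eqn{\eta}, \eqn{P(y \le j) = \mathrm{logistic}(\alpha_j - \eta)} and
#' category probabilities are successive differences of the cumulative
#' probabilities.
#'
#' @param eta Numeric vector of linear predictors.
#' @param alpha Strictly increasing threshold vector (length `J - 1`).
#' @return Matrix `length(eta)` by `J`; rows sum to 1.
#' @export
category_probabilities <- function(eta, alpha) {
  if (length(alpha) > 1L && any(diff(alpha) <= 0)) {
    stop("thresholds alpha must be strictly increasing")
  }
  cum <- plogis(outer(-eta, alpha, `+`))       # P(y <= j), n x (J-1)
  p <- cbind(cum, 1) - cbind(0, cum)
  dimnames(p) <- NULL
  p
}

log_catprob <- function(y, eta, alpha) {
  p <- category_probabilities(eta, alpha)
  log(p[cbind(seq_along(y), y)])
}

#' Log-likelihood of the multilevel cumulative-logit model
#'
#' Sum over respondents of the log probability of the observed happiness
#' category, given thresholds, coefficients and city effects.
#'
#' @inheritParams linear_predictor
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(individuals, cities, spec, params) {
  d <- build_design(individuals, cities, spec)
  eta <- linear_predictor(individuals, cities, spec, params)
  if (length(params$alpha) != spec$n_categories - 1L) {
    stop("alpha must have n_categories - 1 thresholds")
  }
  sum(log_catprob(d$y, eta, params$alpha))
}
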
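#' Odds-scale effect of a reduction in polluted days
#'
#' Percent change in the odds of reporting a higher happiness category for a
#' decrease of `delta_days` polluted days:
#' `100 * (exp(-beta_pollution * delta_days) - 1)`.  A negative pollution
#' coefficient and a positive `delta_days` give a positive result (higher
#' odds of greater happiness).
#'
#' @param beta_pollution Pollution coefficient (latent units per polluted
#'   day).
#' @param delta_days Size of the reduction in polluted days.
#' @return Percent change in the odds.
#' @examples
#' odds_effect(-0.002, 69)  # ~ +14.8%
#' @export
odds_effect <- function(beta_pollution, delta_days) {
  100 * (exp(-beta_pollution * delta_days) - 1)
}

check_income_coef <- function(gamma_income) {
  if (any(gamma_income <= 0)) {
    stop("income coefficient must be positive: valuation is undefined when income does not raise happiness")
  }
}

#' Marginal willingness to pay for one fewer polluted day
#'
#' The marginal rate of substitution between income and air pollution under
#' the log-income cumulative-logit model:
#' `WTP = (-beta_pollution / gamma_income) * income`, in RMB per
#' one-polluted-day reduction.  Positive when pollution harms happiness; a
#' positive pollution coefficient yields a negative WTP, which is surfaced as
#' a warning, never clipped.
#'
#' @inheritParams odds_effect
#' @param gamma_income Income coefficient (latent units per log-RMB), `> 0`.
#' @param income Monthly income base (RMB/month).
#' @return WTP in RMB per month per one-day reduction.
#' @export
marginal_wtp <- function(beta_pollution, gamma_income, income) {
  check_income_coef(gamma_income)
  wtp <- (-beta_pollution / gamma_income) * income
  if (any(wtp < 0)) {
    warning("positive pollution coefficient yields negative WTP")
  }
  wtp
}

#' WTP as a percentage of monthly income
#'
#' @param wtp WTP in RMB.
#' @param income Monthly income in RMB, `> 0`.
#' @return `100 * wtp / income`.
#' @examples
#' wtp_percent(95, 6704)  # ~ 1.42
#' @export
wtp_percent <- function(wtp, income) {
  if (any(income <= 0)) stop("income must be positive")
  100 * wtp / income
}

#' Per-city willingness to pay
#'
#' Applies [marginal_wtp()] and [wtp_percent()] city by city using each
#' city's mean monthly income, and ranks cities by WTP in RMB.  Because WTP
#' is linear in income while its percentage is income-free, spatial
#' variability in the RMB figures mirrors the income distribution.
#'
#' @inheritParams marginal_wtp
#' @param city_incomes Data frame with columns `city_id` and `mean_income`
#'   (RMB/month, all positive).
#' @return Data frame `city_id`, `mean_income`, `wtp_rmb`, `wtp_pct`, sorted
#'   by decreasing `wtp_rmb`.
#' @export
per_city_wtp <- function(beta_pollution, gamma_income, city_incomes) {
  if (nrow(city_incomes) == 0L) stop("city income table is empty")
  if (any(city_incomes$mean_income <= 0)) stop("city mean incomes must be positive")
  out <- data.frame(
    city_id = city_incomes$city_id,
    mean_income = city_incomes$mean_income,
    wtp_rmb = marginal_wtp(beta_pollution, gamma_income,
                           city_incomes$mean_income))
  out$wtp_pct <- wtp_percent(out$wtp_rmb, out$mean_income)
  out[order(-out$wtp_rmb), , drop = FALSE]
}

#' Compensating surplus of a discrete pollution reduction
#'
#' Income change equivalent, at constant latent happiness, to a discrete
#' reduction of `delta_days` polluted days:
#' `CS = income * (1 - exp((beta_pollution / gamma_income) * delta_days))`.
#' Non-negative when the pollution coefficient is non-positive, bounded above
#' by income, and tangent to `marginal_wtp * delta` at zero.
#'
#' @inheritParams marginal_wtp
#' @param delta_days Non-negative size of the reduction, in days.
#' @return CS in RMB.
#' @export
compensating_surplus <- function(beta_pollution, gamma_income, income,
                                 delta_days) {
  check_income_coef(gamma_income)
  if (any(delta_days < 0)) stop("delta_days must be non-negative")
  income * (1 - exp((beta_pollution / gamma_income) * delta_days))
}

find_param <- function(draws, pattern, what) {
  hit <- grep(pattern, colnames(draws$draws), value = TRUE)
  if (length(hit) != 1L) {
    stop(sprintf("fitted model must include exactly one %s term (looked for '%s')",
                 what, pattern))
  }
  hit
}

#' Full valuation report from a fitted model
#'
#' Point estimates use the posterior medians of the pollution and income
#' coefficients (the same convention as the summary tables); uncertainty is
#' additionally propagated by applying the WTP formula draw-wise and taking
#' equal-tailed quantiles.  Per-city WTP uses each city's mean band-midpoint
#' monthly income computed from the individual table.
#'
#' @param draws A `"posterior_draws"` object whose model includes the
#'   pollution (`gamma_polluted_days`) and income (`beta_log_income`) terms.
#' @param individuals,cities The data the model was fitted to.
#' @param delta_days Discrete reduction used for the compensating surplus
#'   (default 69 days, one between-city standard deviation of annual
#'   polluted days).
#' @return An object of class `"valuation_result"`: regional `wtp_rmb` and
#'   `wtp_pct`, a draw-wise 95% interval `wtp_ci`, the `per_city` table,
#'   `cs_rmb`, `cs_pct_annual` and `delta_days`.
#' @export
valuation_report <- function(draws, individuals, cities, delta_days = 69) {
  stopifnot(inherits(draws, "posterior_draws"))
  poll_col <- find_param(draws, "^gamma_polluted_days$", "pollution")
  inc_col <- find_param(draws, "^beta_log_income$", "income")
  b_poll <- median(draws$draws[, poll_col])
  g_inc <- median(draws$draws[, inc_col])
  pf <- prepare_model_frame(individuals, cities)
  inc_by_city <- tapply(pf$individuals$income_mid,
                        factor(pf$individuals$city_id,
                               levels = cities$city_id), mean)
  city_incomes <- data.frame(city_id = cities$city_id,
                             mean_income = as.numeric(inc_by_city))
  mean_income <- mean(pf$individuals$income_mid)
  wtp <- marginal_wtp(b_poll, g_inc, mean_income)
  g_draws <- draws$draws[, inc_col]
  wtp_ci <- if (all(g_draws > 0)) {
    wtp_draws <- (-draws$draws[, poll_col] / g_draws) * mean_income
    quantile(wtp_draws, c(0.025, 0.975), names = FALSE)
  } else {
    warning("some income-coefficient draws are non-positive; draw-wise WTP interval not computed")
    c(NA_real_, NA_real_)
  }
  cs <- compensating_surplus(b_poll, g_inc, mean_income, delta_days)
  structure(
    list(beta_pollution = b_poll, gamma_income = g_inc,
         mean_income = mean_income,
         wtp_rmb = wtp, wtp_pct = wtp_percent(wtp, mean_income),
         wtp_ci = wtp_ci,
         per_city = per_city_wtp(b_poll, g_inc, city_incomes),
         cs_rmb = cs, cs_pct_annual = 100 * cs / (12 * mean_income),
         delta_days = delta_days),
    class = "valuation_result")
}

#' @export
print.valuation_result <- function(x, ...) {
  cat("Willingness to pay for air-quality improvement\n")
  cat(sprintf("  coefficients (posterior medians): pollution %.4f, log-income %.3f\n",
              x$beta_pollution, x$gamma_income))
  cat(sprintf("  regional mean monthly income: %.0f RMB\n", x$mean_income))
  cat(sprintf("  marginal WTP: %.1f RMB per polluted-day reduction (%.2f%% of monthly income)\n",
              x$wtp_rmb, x$wtp_pct))
  cat(sprintf("  95%% draw-wise WTP interval: [%.1f, %.1f] RMB\n",
              x$wtp_ci[1], x$wtp_ci[2]))
  cat(sprintf("  compensating surplus for a %g-day reduction: %.0f RMB (%.2f%% of annual income)\n",
              x$delta_days, x$cs_rmb, x$cs_pct_annual))
  cat(sprintf("  per-city WTP range: %.1f-%.1f RMB across %d cities\n",
              min(x$per_city$wtp_rmb), max(x$per_city$wtp_rmb),
              nrow(x$per_city)))
  invisible(x)
}

#' Export a valuation result
#'
#' Writes the per-city table as CSV and the scalar summary block as JSON.
#'
#' @param result A `"valuation_result"`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_valuation <- function(result, dir) {
  stopifnot(inherits(result, "valuation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("wtp_per_city.csv", "valuation.json"))
  write.csv(result$per_city, paths[1], row.names = FALSE)
  scalars <- result[c("beta_pollution", "gamma_income", "mean_income",
                      "wtp_rmb", "wtp_pct", "wtp_ci", "cs_rmb",
                      "cs_pct_annual", "delta_days")]
  jsonlite::write_json(scalars, paths[2], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
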
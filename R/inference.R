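#' MCMC configuration
#'
#' Defaults follow the protocol used for the survey analysis: three chains of
#' 50,000 iterations, a 30,000-iteration burn-in, and retention of every
#' tenth post-burn-in sample.  Proposal scales adapt toward
#' `target_acceptance` during burn-in only, so retained draws come from a
#' fixed kernel.
#'
#' @param n_chains Number of chains (default 3).
#' @param n_iterations Iterations per chain (default 50,000).
#' @param burn_in Discarded initial iterations (default 30,000).
#' @param thin Retain every `thin`-th post-burn-in draw (default 10).
#' @param seed Integer seed; chain `c` uses `seed + 1000 * c`.
#' @param target_acceptance Robbins-Monro target acceptance rate for the
#'   single-site random-walk updates (default 0.44).
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iterations = 50000L,
                        burn_in = 30000L, thin = 10L, seed = 1L,
                        target_acceptance = 0.44) {
  if (burn_in >= n_iterations) stop("burn_in must be smaller than n_iterations")
  if (thin < 1L) stop("thin must be >= 1")
  if (target_acceptance <= 0 || target_acceptance >= 1) {
    stop("target_acceptance must lie in (0, 1)")
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 target_acceptance = target_acceptance),
            class = "mcmc_config")
}

init_thresholds <- function(y, J) {
  n <- length(y)
  counts <- tabulate(y, J)
  cum <- cumsum(counts)[seq_len(J - 1L)] / n
  cum <- pmin(pmax(cum, 0.5 / n), 1 - 0.5 / n)
  a <- qlogis(cum)
  # enforce strict ordering when some categories are empty
  for (j in seq_along(a)[-1]) {
    if (a[j] <= a[j - 1]) a[j] <- a[j - 1] + 1e-3
  }
  a
}

#' Fit the multilevel cumulative-logit model by Metropolis-within-Gibbs MCMC
#'
#' Single-site adaptive random-walk Metropolis updates for each threshold
#' (ordering-violating proposals are rejected), each regression coefficient
#' and each city effect, with a conjugate inverse-gamma Gibbs draw for the
#' between-city variance.  Thresholds are initialised at the empirical
#' cumulative logits of the response, coefficients and city effects at zero,
#' and `sigma_u2` at 0.1.  Runs are deterministic given `config$seed`.
#'
#' @inheritParams linear_predictor
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @return An object of class `"posterior_draws"`: list with the pooled
#'   `draws` matrix (retained samples by named parameters), per-draw
#'   `chain` ids, per-chain Metropolis `acceptance` rates, and the spec,
#'   config and design metadata.
#' @export
run_mcmc <- function(individuals, cities, spec, priors = prior_spec(),
                     config = mcmc_config()) {
  if (nrow(individuals) == 0L) stop("no respondents to fit")
  d <- build_design(individuals, cities, spec)
  J <- spec$n_categories
  counts <- tabulate(d$y, J)
  if (any(counts == 0L)) {
    warning("response has empty categories; thresholds weakly identified")
  }
  n <- length(d$y)
  alpha0 <- init_thresholds(d$y, J)
  p <- ncol(d$X); q <- ncol(d$Z)
  params <- c(paste0("alpha", seq_len(J - 1L)),
              if (p) paste0("beta_", colnames(d$X)),
              if (q) paste0("gamma_", colnames(d$Z)),
              paste0("u[", cities$city_id, "]"),
              "sigma_u2")
  col_sd <- function(M) apply(M, 2, sd)
  sd_or_1 <- function(s) ifelse(is.finite(s) & s > 0, s, 1)
  prop_sd0 <- c(rep(2.4 / sqrt(n), J - 1L),
                if (p) 2.4 / (sd_or_1(col_sd(d$X)) * sqrt(n)),
                if (q) 2.4 / (sd_or_1(col_sd(d$Z)) * sqrt(n)),
                2.4 / sqrt(pmax(tabulate(d$city_index, d$K), 1)))

  # An exclusive block of 0/1 dummies covering almost every respondent (e.g.
  # health categories against a rare reference level) is nearly collinear
  # with the thresholds; give the sampler a joint translation move for it.
  shift_cols <- integer()
  if (p > 1) {
    bin <- which(apply(d$X, 2, function(x) all(x %in% c(0, 1))))
    if (length(bin) > 1) {
      co <- crossprod(d$X[, bin, drop = FALSE]) > 0
      blocks <- list()
      for (j in seq_along(bin)) {
        placed <- FALSE
        for (b in seq_along(blocks)) {
          if (!any(co[j, blocks[[b]]])) {
            blocks[[b]] <- c(blocks[[b]], j); placed <- TRUE; break
          }
        }
        if (!placed) blocks[[length(blocks) + 1L]] <- j
      }
      blocks <- Filter(function(b) length(b) > 1L, blocks)
      if (length(blocks)) {
        coverage <- vapply(blocks, function(b) {
          mean(rowSums(d$X[, bin[b], drop = FALSE]))
        }, numeric(1))
        if (max(coverage) > 0.8) {
          best <- blocks[[which.max(coverage)]]
          shift_cols <- bin[best] - 1L   # 0-based for the sampler
          n_ref <- round(n * (1 - max(coverage)))
          prop_sd0 <- c(prop_sd0, 2.4 / sqrt(max(n_ref, 1)))
        }
      }
    }
  }
  sigma0 <- 0.1
  beta0 <- rep(0, p); gamma0 <- rep(0, q); u0 <- rep(0, d$K)

  # Sample with mean-centered design columns (thresholds and coefficients are
  # near-collinear otherwise, which stalls single-site updates), then shift
  # the retained threshold draws back to the raw-covariate scale:
  # alpha = alpha_centered + xbar' beta + zbar' gamma.
  # 0/1 dummies stay raw: their means are small and the sampler exploits
  # their sparsity for subset likelihood updates.
  center_cols <- function(M) {
    ctr <- rep(0, ncol(M))
    for (j in seq_len(ncol(M))) {
      if (!all(M[, j] %in% c(0, 1))) ctr[j] <- mean(M[, j])
    }
    list(M = sweep(M, 2, ctr), center = ctr)
  }
  cx <- center_cols(d$X); cz <- center_cols(d$Z)
  Xc <- cx$M; Zc <- cz$M
  xbar <- cx$center; zbar <- cz$center

  run_chain <- function(chain) {
    set.seed(config$seed + 1000L * chain)
    for (try in 1:5) {
      eta0 <- drop(Xc %*% beta0) + drop(Zc %*% gamma0) + u0[d$city_index]
      ll0 <- sum(log_catprob(d$y, eta0, alpha0))
      if (is.finite(ll0)) break
      alpha0 <- sort(alpha0 + rnorm(length(alpha0), 0, 0.01))
      if (try == 5) stop("non-finite likelihood at initialization")
    }
    .mwg_chain(d$y, Xc, Zc, d$city_index, d$K, J,
               alpha0, beta0, gamma0, u0, sigma0,
               priors$coef_prior_variance, priors$ig_shape, priors$ig_scale,
               config$n_iterations, config$burn_in, config$thin,
               config$target_acceptance, prop_sd0, shift_cols)
  }
  chains <- lapply(seq_len(config$n_chains), run_chain)
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- params
  if (p + q > 0) {
    coef_cols <- (J - 1L) + seq_len(p + q)
    shift <- drop(draws[, coef_cols, drop = FALSE] %*% c(xbar, zbar))
    for (j in seq_len(J - 1L)) draws[, j] <- draws[, j] + shift
  }
  chain_id <- rep(seq_len(config$n_chains),
                  each = nrow(chains[[1]]$draws))
  acceptance <- do.call(rbind, lapply(chains, `[[`, "acceptance"))
  n_base <- ncol(acceptance) - (length(shift_cols) > 0)
  colnames(acceptance) <- c(params[seq_len(n_base)],
                            if (length(shift_cols)) "shift_move")
  structure(list(draws = draws, chain = chain_id, acceptance = acceptance,
                 spec = spec, config = config, priors = priors,
                 n = n, K = d$K, J = J, city_ids = cities$city_id),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d retained samples (%d chains) for %d parameters\n",
              nrow(x$draws), x$config$n_chains, ncol(x$draws)))
  invisible(x)
}

#' @export
as.matrix.posterior_draws <- function(x, ...) x$draws

#' Posterior summary table
#'
#' Per-parameter posterior median and equal-tailed 95% credible interval,
#' pooled across chains, with a significance marker: `***`, `**`, `*` when
#' the 99%, 95%, 90% equal-tailed interval excludes zero.  Quantiles use the
#' linear-interpolation (type-7) convention.
#'
#' @param draws A `"posterior_draws"` object (or a draws matrix with named
#'   columns).
#' @return Data frame with columns `parameter`, `median`, `q2.5`, `q97.5`,
#'   `signif`.
#' @export
posterior_summary <- function(draws) {
  m <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  qs <- t(apply(m, 2, quantile,
                probs = c(0.005, 0.025, 0.05, 0.5, 0.95, 0.975, 0.995),
                type = 7, names = FALSE))
  excl <- function(lo, hi) qs[, lo] > 0 | qs[, hi] < 0
  stars <- ifelse(excl(1, 7), "***", ifelse(excl(2, 6), "**",
                                            ifelse(excl(3, 5), "*", "")))
  data.frame(parameter = colnames(m), median = qs[, 4], q2.5 = qs[, 2],
             q97.5 = qs[, 6], signif = stars, row.names = NULL)
}

#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Each chain is split in half; the potential scale reduction factor
#' \eqn{\hat{R} = \sqrt{((n-1)/n\, W + B/n) / W}} is computed over the split
#' sequences.  Values near 1 indicate convergence; the pipeline warns above
#' 1.05.
#'
#' @param draws A `"posterior_draws"` object with at least 2 chains.
#' @return Named numeric vector of split-\eqn{\hat{R}} per parameter.
#' @export
gelman_rubin <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$config$n_chains < 2L) stop("need at least 2 chains")
  m <- draws$draws
  halves <- lapply(unique(draws$chain), function(cid) {
    rows <- which(draws$chain == cid)
    nh <- floor(length(rows) / 2)
    list(rows[seq_len(nh)], rows[nh + seq_len(nh)])
  })
  seqs <- unlist(halves, recursive = FALSE)
  nh <- length(seqs[[1]])
  apply(m, 2, function(x) {
    xs <- vapply(seqs, function(r) x[r], numeric(nh))
    W <- mean(apply(xs, 2, var))
    B <- nh * var(colMeans(xs))
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((nh - 1) / nh * W + B / nh) / W)
  })
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean of the deviance `-2 log L`; `pD` is
#' `Dbar - D(theta_bar)` with the deviance evaluated at the posterior mean of
#' the parameters (Spiegelhalter plug-in form); `DIC = Dbar + pD`.
#'
#' @param draws A `"posterior_draws"` object.
#' @inheritParams linear_predictor
#' @return List with `dic`, `pD` and `Dbar`.
#' @export
compute_dic <- function(draws, individuals, cities, spec = draws$spec) {
  stopifnot(inherits(draws, "posterior_draws"))
  d <- build_design(individuals, cities, spec)
  J <- spec$n_categories
  m <- draws$draws
  nA <- J - 1L
  p <- ncol(d$X); q <- ncol(d$Z)
  idx_alpha <- seq_len(nA)
  idx_beta <- nA + seq_len(p)
  idx_gamma <- nA + p + seq_len(q)
  idx_u <- nA + p + q + seq_len(d$K)
  dev_at <- function(th) {
    eta <- drop(d$X %*% th[idx_beta]) + drop(d$Z %*% th[idx_gamma]) +
      th[idx_u][d$city_index]
    -2 * sum(log_catprob(d$y, eta, th[idx_alpha]))
  }
  devs <- apply(m, 1, dev_at)
  Dbar <- mean(devs)
  Dhat <- dev_at(colMeans(m))
  pD <- Dbar - Dhat
  list(dic = Dbar + pD, pD = pD, Dbar = Dbar)
}

#' Variance partitioning coefficient
#'
#' Share of latent-scale variance attributable to the city level:
#' \eqn{\sigma_u^2 / (\sigma_u^2 + \pi^2/3)}, where \eqn{\pi^2/3} is the
#' standard-logistic residual variance.
#'
#' @param sigma_u2 Non-negative between-city variance (vectorised).
#' @return Proportion(s) in `[0, 1)`.
#' @export
vpc <- function(sigma_u2) {
  if (any(sigma_u2 < 0)) stop("sigma_u2 must be non-negative")
  sigma_u2 / (sigma_u2 + pi^2 / 3)
}

#' Write retained draws to CSV
#'
#' One row per retained draw with its chain id and labeled parameter columns.
#'
#' @param draws A `"posterior_draws"` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  out <- data.frame(chain = draws$chain, draws$draws, check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
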
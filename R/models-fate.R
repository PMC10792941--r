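# numerically stable log(1 + exp(x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

bernoulli_ll <- function(y, eta) sum(y * eta - softplus(eta))

#' Probability of direction
#'
#' The posterior probability that a parameter is strictly positive or
#' strictly negative, whichever is larger; exact zeros are split evenly
#' between the two directions. Ranges over \[0.5, 1\].
#'
#' @param draws numeric vector of posterior draws.
#' @return pd in \[0.5, 1\].
#' @export
probability_of_direction <- function(draws) {
  if (length(draws) == 0L) stop("no posterior draws", call. = FALSE)
  p_pos <- (sum(draws > 0) + 0.5 * sum(draws == 0)) / length(draws)
  max(p_pos, 1 - p_pos)
}

#' Split potential scale reduction factor (R-hat)
#'
#' Each chain is split in half; R-hat compares between- and within-sequence
#' variance across the split halves. Values near 1 indicate convergence;
#' the conventional cutoff is 1.1.
#'
#' @param chains matrix (iterations x chains) or list of equal-length
#'   numeric vectors; at least 2 chains of length at least 4.
#' @return R-hat statistic.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("R-hat needs at least 2 chains", call. = FALSE)
  if (nrow(chains) < 4L) stop("chains must have length >= 4", call. = FALSE)
  half <- nrow(chains) %/% 2L
  splits <- cbind(chains[seq_len(half), , drop = FALSE],
                  chains[half + seq_len(half), , drop = FALSE])
  n <- nrow(splits)
  W <- mean(apply(splits, 2L, stats::var))
  B <- n * stats::var(colMeans(splits))
  if (W == 0) return(if (B == 0) 1 else Inf)
  vhat <- (n - 1) / n * W + B / n
  sqrt(vhat / W)
}

# one adaptive random-walk Metropolis-within-Gibbs chain for the
# random-intercept logistic model
run_fate_chain <- function(y, X, f_idx, nf, iterations, burn_in,
                           prior_sd_coef, prior_sd_sigma, seed) {
  set.seed(seed)
  p <- ncol(X)
  beta <- stats::rnorm(p, 0, 0.5)
  b <- stats::rnorm(nf, 0, 0.5)
  log_sig <- stats::rnorm(1, 0, 0.3)
  sig <- exp(log_sig)
  eta <- as.numeric(X %*% beta) + b[f_idx]
  s_beta <- rep(0.3, p); s_b <- 0.6; s_sig <- 0.3; s_scale <- 0.2
  acc_beta <- numeric(p); acc_b <- 0; acc_sig <- 0; acc_scale <- 0
  batch <- 0L
  n_keep <- iterations - burn_in
  draws_beta <- matrix(NA_real_, n_keep, p)
  draws_sig <- numeric(n_keep)
  b_sum <- numeric(nf)
  fg <- factor(f_idx, levels = seq_len(nf))
  for (it in seq_len(iterations)) {
    # fixed effects, one at a time
    for (j in seq_len(p)) {
      prop <- beta[j] + stats::rnorm(1) * s_beta[j]
      deta <- X[, j] * (prop - beta[j])
      eta_new <- eta + deta
      dlp <- bernoulli_ll(y, eta_new) - bernoulli_ll(y, eta) +
        stats::dnorm(prop, 0, prior_sd_coef, log = TRUE) -
        stats::dnorm(beta[j], 0, prior_sd_coef, log = TRUE)
      if (log(stats::runif(1)) < dlp) {
        beta[j] <- prop; eta <- eta_new; acc_beta[j] <- acc_beta[j] + 1
      }
    }
    # random intercepts, element-wise in one vectorised sweep
    prop_b <- b + stats::rnorm(nf) * s_b
    eta_new <- eta + (prop_b - b)[f_idx]
    dll_row <- y * (eta_new - eta) - softplus(eta_new) + softplus(eta)
    dll_f <- as.numeric(rowsum(dll_row, fg))
    dlp_f <- dll_f +
      stats::dnorm(prop_b, 0, sig, log = TRUE) -
      stats::dnorm(b, 0, sig, log = TRUE)
    acc <- log(stats::runif(nf)) < dlp_f
    if (any(acc)) {
      b_new <- ifelse(acc, prop_b, b)
      eta <- eta + (b_new - b)[f_idx]
      b <- b_new
    }
    acc_b <- acc_b + mean(acc)
    # random-intercept SD on the log scale (half-normal prior + Jacobian)
    prop_ls <- log_sig + stats::rnorm(1) * s_sig
    prop_sig <- exp(prop_ls)
    dlp <- sum(stats::dnorm(b, 0, prop_sig, log = TRUE)) -
      sum(stats::dnorm(b, 0, sig, log = TRUE)) +
      stats::dnorm(prop_sig, 0, prior_sd_sigma, log = TRUE) -
      stats::dnorm(sig, 0, prior_sd_sigma, log = TRUE) +
      (prop_ls - log_sig)
    if (log(stats::runif(1)) < dlp) {
      log_sig <- prop_ls; sig <- prop_sig; acc_sig <- acc_sig + 1
    }
    # joint scaling move along the (b, sigma) funnel: rescale every random
    # intercept together with sigma; the normal-prior terms cancel exactly
    # against the b-Jacobian, leaving the likelihood, the sigma prior, and
    # the log-sigma Jacobian
    eps <- stats::rnorm(1) * s_scale
    prop_b <- b * exp(eps)
    prop_sig <- exp(log_sig + eps)
    eta_new <- eta + (prop_b - b)[f_idx]
    dlp <- bernoulli_ll(y, eta_new) - bernoulli_ll(y, eta) +
      stats::dnorm(prop_sig, 0, prior_sd_sigma, log = TRUE) -
      stats::dnorm(sig, 0, prior_sd_sigma, log = TRUE) + eps
    if (log(stats::runif(1)) < dlp) {
      b <- prop_b; eta <- eta_new
      log_sig <- log_sig + eps; sig <- prop_sig
      acc_scale <- acc_scale + 1
    }
    batch <- batch + 1L
    if (it <= burn_in && batch == 50L) {
      s_beta <- s_beta * exp(0.3 * (acc_beta / 50 - 0.44))
      s_b <- s_b * exp(0.3 * (acc_b / 50 - 0.44))
      s_sig <- s_sig * exp(0.3 * (acc_sig / 50 - 0.44))
      s_scale <- s_scale * exp(0.3 * (acc_scale / 50 - 0.44))
      acc_beta[] <- 0; acc_b <- 0; acc_sig <- 0; acc_scale <- 0; batch <- 0L
    }
    if (it > burn_in) {
      k <- it - burn_in
      draws_beta[k, ] <- beta
      draws_sig[k] <- sig
      b_sum <- b_sum + b
    }
  }
  list(beta = draws_beta, sigma = draws_sig, b_mean = b_sum / n_keep)
}

#' Fit the Bayesian random-intercept nest-fate model
#'
#' Hierarchical logistic regression of nest fate: `fate_i ~
#' Bernoulli(plogis(alpha + beta . z_i + b_f(i)))`, with `b_f ~ Normal(0,
#' sigma_b^2)` per female. Covariates are standardised (centred, divided by
#' the sample SD) before fitting. Posterior sampling uses an adaptive
#' random-walk Metropolis-within-Gibbs scheme with weakly informative priors
#' (Normal(0, 2.5^2) on coefficients, half-Normal(0, 2^2) on sigma_b);
#' proposal scales adapt toward 44% acceptance during burn-in only. Burn-in
#' is discarded per chain. Non-convergence (any R-hat at or above 1.1)
#' produces a warning and `convergence = FALSE`, not an error.
#'
#' @param fate 0/1 vector or `"success"`/`"fail"` labels.
#' @param covariates data.frame or matrix of fixed-effect covariates (e.g.
#'   proportion of recesses to CLPs and number of CLPs visited).
#' @param female_id factor/character of female identifiers (at least 2).
#' @param chains number of MCMC chains (default 4).
#' @param iterations iterations per chain (default 8000).
#' @param burn_in discarded initial iterations per chain (default 1000).
#' @param seed master seed; chain seeds derive from it.
#' @param prior_sd_coef,prior_sd_sigma prior scales.
#' @return `nest_fate_fit` list: `summary` data.frame (mean, 95% credible
#'   interval, pd, R-hat per parameter), `draws` (per-chain matrices),
#'   `scales` (covariate centring/scaling), `b_mean` (posterior-mean random
#'   intercepts), `convergence` flag, and the model data.
#' @export
fit_nest_fate <- function(fate, covariates, female_id, chains = 4L,
                          iterations = 8000L, burn_in = 1000L, seed = 1L,
                          prior_sd_coef = 2.5, prior_sd_sigma = 2) {
  y <- if (is.character(fate) || is.factor(fate)) {
    as.integer(as.character(fate) == "success")
  } else as.integer(fate)
  covariates <- as.data.frame(covariates)
  females <- unique(as.character(female_id))
  if (length(females) < 2L) stop("need at least 2 females", call. = FALSE)
  f_idx <- match(as.character(female_id), females)
  scales <- lapply(covariates, function(col) {
    c(center = mean(col), scale = stats::sd(col))
  })
  Z <- vapply(names(covariates), function(nm) {
    standardize(covariates[[nm]], mode = "z", name = nm)
  }, numeric(nrow(covariates)))
  X <- cbind(`(Intercept)` = 1, Z)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  runs <- lapply(chain_seeds, function(cs) {
    run_fate_chain(y, X, f_idx, length(females), iterations, burn_in,
                   prior_sd_coef, prior_sd_sigma, cs)
  })
  param_names <- c(colnames(X), "sigma_female")
  draw_mat <- function(j) {
    vapply(runs, function(r) {
      if (j <= ncol(X)) r$beta[, j] else r$sigma
    }, numeric(iterations - burn_in))
  }
  summ <- do.call(rbind, lapply(seq_along(param_names), function(j) {
    m <- draw_mat(j)
    pooled <- as.vector(m)
    data.frame(
      parameter = param_names[j],
      mean = mean(pooled),
      ci_lower = unname(stats::quantile(pooled, 0.025)),
      ci_upper = unname(stats::quantile(pooled, 0.975)),
      pd = probability_of_direction(pooled),
      rhat = rhat(m),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  converged <- all(summ$rhat < 1.1)
  if (!converged) {
    warning("MCMC did not converge: max R-hat = ",
            sprintf("%.3f", max(summ$rhat)))
  }
  b_mean <- Reduce(`+`, lapply(runs, `[[`, "b_mean")) / length(runs)
  structure(list(summary = summ, draws = runs, scales = scales,
                 b_mean = b_mean, convergence = converged,
                 data = list(y = y, X = X, f_idx = f_idx,
                             females = females),
                 chains = chains, iterations = iterations,
                 burn_in = burn_in),
            class = "nest_fate_fit")
}

#' @export
print.nest_fate_fit <- function(x, ...) {
  cat(sprintf("<nest_fate_fit> %d chains x %d iterations (%d burn-in)%s\n",
              x$chains, x$iterations, x$burn_in,
              if (x$convergence) "" else "  [NOT CONVERGED]"))
  print(x$summary, digits = 3)
  invisible(x)
}

# pooled posterior draws of one parameter
fate_draws <- function(fit, parameter) {
  j <- match(parameter, c(colnames(fit$data$X), "sigma_female"))
  if (is.na(j)) stop("unknown parameter: ", parameter, call. = FALSE)
  unlist(lapply(fit$draws, function(r) {
    if (j <= ncol(fit$data$X)) r$beta[, j] else r$sigma
  }))
}

#' Average marginal effect of a covariate on nest success
#'
#' Computes, per posterior draw and observed row, the change in success
#' probability when the covariate increases by `delta` on its original scale
#' (converted internally to standardised units), averaged over rows and
#' draws. Row linear predictors include each female's posterior-mean random
#' intercept.
#'
#' @param fit `nest_fate_fit`.
#' @param covariate covariate name (e.g. `"n_clp_visited"`).
#' @param delta original-scale step (default 1, e.g. one extra patch).
#' @param max_draws posterior draws used (subsampled evenly; default 2000).
#' @return average marginal effect in percentage points, with a
#'   `draws` attribute carrying the per-draw effects.
#' @export
marginal_effect <- function(fit, covariate, delta = 1, max_draws = 2000L) {
  sc <- fit$scales[[covariate]]
  if (is.null(sc)) stop("unknown covariate: ", covariate, call. = FALSE)
  delta_std <- delta / sc[["scale"]]
  X <- fit$data$X
  j <- match(covariate, colnames(X))
  b_row <- fit$b_mean[fit$data$f_idx]
  beta_all <- do.call(rbind, lapply(fit$draws, `[[`, "beta"))
  if (nrow(beta_all) > max_draws) {
    beta_all <- beta_all[round(seq(1, nrow(beta_all),
                                   length.out = max_draws)), , drop = FALSE]
  }
  eta <- X %*% t(beta_all) + b_row           # rows x draws
  shift <- matrix(beta_all[, j] * delta_std, nrow(X), nrow(beta_all),
                  byrow = TRUE)
  per_draw <- colMeans(stats::plogis(eta + shift) - stats::plogis(eta))
  structure(100 * mean(per_draw), draws = 100 * per_draw)
}
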
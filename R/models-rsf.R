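#' Standardize a covariate
#'
#' Mode `"z"` centres and divides by one sample SD (used by the nest-fate
#' model); mode `"2sd"` divides by two sample SDs (used by the RSF so binary
#' and continuous effects are comparable).
#'
#' @param x numeric vector with positive SD.
#' @param mode `"z"` or `"2sd"`.
#' @param name covariate name used in error messages.
#' @return standardised vector with attributes `center` and `scale` (the
#'   divisor actually applied).
#' @export
standardize <- function(x, mode = c("z", "2sd"), name = deparse(substitute(x))) {
  mode <- match.arg(mode)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("covariate '", name, "' has zero standard deviation", call. = FALSE)
  }
  div <- if (mode == "z") s else 2 * s
  structure((x - mean(x)) / div, center = mean(x), scale = div)
}

#' Screen covariates for collinearity
#'
#' Greedy removal: while any absolute pairwise Pearson correlation exceeds
#' `r_max`, drop the covariate with the largest mean absolute correlation
#' with the others. Constant covariates are dropped first with a warning
#' (their correlation is undefined).
#'
#' @param covariates data.frame or matrix of numeric covariates (>= 2
#'   columns, >= 3 rows).
#' @param r_max correlation threshold (default 0.60; strict inequality).
#' @return character vector of retained covariate names; dropped names in
#'   attribute `dropped`.
#' @export
screen_collinearity <- function(covariates, r_max = 0.60) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2L || nrow(covariates) < 3L) {
    stop("need at least 2 covariates and 3 rows", call. = FALSE)
  }
  dropped <- character()
  constant <- vapply(covariates, function(x) stats::sd(x) == 0 ||
                       !is.finite(stats::sd(x)), logical(1))
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[constant], collapse = ", "))
    dropped <- names(covariates)[constant]
    covariates <- covariates[, !constant, drop = FALSE]
  }
  kept <- names(covariates)
  repeat {
    if (length(kept) < 2L) break
    cm <- abs(stats::cor(covariates[, kept, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= r_max) break
    worst <- which.max(colMeans(cm))
    dropped <- c(dropped, kept[worst])
    kept <- kept[-worst]
  }
  structure(kept, dropped = dropped)
}

#' Assemble a used/available table
#'
#' Binds used points (coded 1) and available points (coded 0) with their
#' covariates and the owning female/attempt.
#'
#' @param used,available covariate data.frames (see
#'   [extract_covariates()]).
#' @param female_id female identifier (scalar).
#' @param attempt_id attempt identifier (scalar).
#' @return data.frame with `used`, `female_id`, `attempt_id` and covariates.
#' @export
bind_used_available <- function(used, available, female_id, attempt_id = 1L) {
  used$used <- 1L; available$used <- 0L
  out <- rbind(used, available)
  out$female_id <- female_id
  out$attempt_id <- attempt_id
  out
}

#' Fit the used/available resource-selection GLMM
#'
#' Third-order selection: a binomial-logit generalized linear mixed model of
#' used (1) versus available (0) points within individual incubation ranges,
#' with a random intercept per female, fitted by maximum likelihood
#' (Laplace) via lme4. Covariates pass the collinearity screen and are then
#' rescaled by two standard deviations. All covariates are distances, so a
#' negative coefficient means selection for proximity to the feature.
#'
#' @param data used/available table (see [bind_used_available()]): columns
#'   `used`, `female_id`, and covariates.
#' @param covariates covariate names; defaults to every numeric column
#'   except `used` and identifiers.
#' @param r_max collinearity threshold (default 0.60).
#' @param screen apply the collinearity screen (default TRUE).
#' @param random_by `"female_id"` (default) or `"attempt_id"` for the random
#'   intercept grouping.
#' @return `rsf_fit` list: `coefficients` data.frame (term, beta, se,
#'   ci_lower, ci_upper on the 2-SD scale), `ranef_var`, `n_used`,
#'   `n_available`, `kept`, `dropped`, `scales`, and the lme4 `model`.
#' @export
fit_rsf <- function(data, covariates = NULL, r_max = 0.60, screen = TRUE,
                    random_by = c("female_id", "attempt_id")) {
  random_by <- match.arg(random_by)
  if (is.null(covariates)) {
    skip <- c("used", "female_id", "attempt_id", "x", "y")
    covariates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          skip)
  }
  dropped <- character()
  if (screen && length(covariates) >= 2L) {
    kept <- screen_collinearity(data[, covariates, drop = FALSE],
                                r_max = r_max)
    dropped <- attr(kept, "dropped")
    covariates <- as.character(kept)
  }
  scales <- list()
  md <- data.frame(used = data$used, grp = factor(data[[random_by]]))
  for (nm in covariates) {
    z <- standardize(data[[nm]], mode = "2sd", name = nm)
    scales[[nm]] <- c(center = attr(z, "center"), scale = attr(z, "scale"))
    md[[nm]] <- as.numeric(z)
  }
  form <- stats::as.formula(paste("used ~",
                                  paste(covariates, collapse = " + "),
                                  "+ (1 | grp)"))
  model <- lme4::glmer(form, data = md, family = stats::binomial())
  fe <- lme4::fixef(model)
  if (any(abs(fe[-1L]) > 15)) {
    stop("complete separation suspected for covariate(s): ",
         paste(names(fe[-1L])[abs(fe[-1L]) > 15], collapse = ", "),
         call. = FALSE)
  }
  if (lme4::isSingular(model)) {
    warning("singular random-effect fit; variance reported as 0")
  }
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  coefs <- data.frame(term = names(fe), beta = unname(fe), se = unname(se),
                      stringsAsFactors = FALSE)
  coefs$ci_lower <- coefs$beta - 1.96 * coefs$se
  coefs$ci_upper <- coefs$beta + 1.96 * coefs$se
  structure(list(model = model, coefficients = coefs,
                 ranef_var = unname(lme4::VarCorr(model)$grp[1L]),
                 n_used = sum(data$used == 1L),
                 n_available = sum(data$used == 0L),
                 kept = covariates, dropped = dropped, scales = scales),
            class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> %d used / %d available; random-intercept var %.3f\n",
              x$n_used, x$n_available, x$ranef_var))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Simulate a used/available population with known selection
#'
#' For each range, available points fall uniformly in a disc around a random
#' nest; used points are drawn from a dense candidate set with probability
#' proportional to `exp(X beta)` on 2-SD-rescaled covariates, plus a
#' per-female intercept. Supports recovery tests of [fit_rsf()] with known
#' coefficients.
#'
#' @param landscape `np_landscape`.
#' @param surfaces covariate surfaces (see [covariate_surfaces()]).
#' @param n_ranges number of ranges (females).
#' @param n_used,n_available points per range.
#' @param betas named selection coefficients on the 2-SD scale; names must
#'   match covariate columns (`dist_nest`, `dist_water`, ...). Covariates
#'   missing from `betas` have zero effect.
#' @param sigma_b SD of the per-female selection intercept.
#' @param radius_m disc radius emulating an incubation range (default 600).
#' @param seed integer seed.
#' @return used/available data.frame (see [bind_used_available()]).
#' @export
simulate_rsf_points <- function(landscape, surfaces, n_ranges = 20L,
                                n_used = 30L, n_available = 500L,
                                betas = c(dist_water = -1),
                                sigma_b = 0, radius_m = 600, seed = 1L) {
  set.seed(seed)
  r <- landscape$raster
  extent <- c(ncol(r$codes), nrow(r$codes)) * r$cellsize
  lo <- r$origin + radius_m + r$cellsize
  hi <- r$origin + extent - radius_m - r$cellsize
  nests <- cbind(stats::runif(n_ranges, lo[1L], hi[1L]),
                 stats::runif(n_ranges, lo[2L], hi[2L]))
  avail_cov <- list(); cand_cov <- list(); cand_pts <- list()
  for (g in seq_len(n_ranges)) {
    da <- runif_disc(n_available, radius_m)
    avail <- data.frame(x = nests[g, 1L] + da[, 1L],
                        y = nests[g, 2L] + da[, 2L])
    dc <- runif_disc(2000L, radius_m)
    cand <- data.frame(x = nests[g, 1L] + dc[, 1L],
                       y = nests[g, 2L] + dc[, 2L])
    avail_cov[[g]] <- extract_covariates(avail, surfaces, nests[g, ])
    cand_cov[[g]] <- extract_covariates(cand, surfaces, nests[g, ])
    cand_pts[[g]] <- cand
  }
  # selection operates on the 2-SD scale of the pooled availability sample
  # so generative coefficients live on the same scale the fit reports
  pooled <- do.call(rbind, avail_cov)
  centers <- vapply(pooled, mean, numeric(1))
  scales2 <- vapply(pooled, function(v) 2 * stats::sd(v), numeric(1))
  out <- list()
  for (g in seq_len(n_ranges)) {
    eta <- rep(stats::rnorm(1, 0, sigma_b), nrow(cand_cov[[g]]))
    for (nm in names(betas)) {
      if (!nm %in% names(cand_cov[[g]]) || scales2[[nm]] == 0) next
      eta <- eta + betas[[nm]] *
        (cand_cov[[g]][[nm]] - centers[[nm]]) / scales2[[nm]]
    }
    pick <- sample.int(length(eta), n_used, replace = TRUE,
                       prob = exp(eta - max(eta)))
    cov_used <- cand_cov[[g]][pick, , drop = FALSE]
    out[[g]] <- bind_used_available(cov_used, avail_cov[[g]],
                                    female_id = sprintf("F%03d", g),
                                    attempt_id = 1L)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
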
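test_that("standardize centres and scales as documented", {
  z <- standardize(c(1, 2, 3), "z")
  expect_equal(as.numeric(z), c(-1, 0, 1))   # sample sd of (1,2,3) is 1
  expect_equal(attr(z, "scale"), 1)
  set.seed(1); x <- rnorm(50, 10, 3)
  expect_lt(abs(mean(standardize(x, "z"))), 1e-12)
  expect_equal(sd(standardize(x, "2sd")), 0.5, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5), "z", name = "dist_pine"), "dist_pine")
})

test_that("standardize matches the documented hand computation", {
  z <- standardize(c(1, 2, 3) * 10, "z")
  expect_equal(as.numeric(z), c(-1, 0, 1))
  # (1, 2, 3) under 2-SD rescaling
  z2 <- standardize(c(1, 2, 3), "2sd")
  expect_equal(as.numeric(z2), c(-0.5, 0, 0.5))
})

test_that("collinearity screen keeps orthogonal sets and drops duplicates", {
  set.seed(3)
  x <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  expect_equal(sort(as.character(screen_collinearity(x))), c("a", "b", "c"))
  x$d <- x$a
  kept <- screen_collinearity(x)
  expect_equal(length(kept), 3L)
  expect_true(xor("a" %in% kept, "d" %in% kept))
})

test_that("collinearity screen drops one of a correlated pair on a
           5-covariate fixture", {
  set.seed(5)
  n <- 200
  a <- rnorm(n)
  x <- data.frame(a = a, b = 0.8 * scale(a)[, 1] + 0.6 * rnorm(n),
                  c = rnorm(n), d = rnorm(n), e = rnorm(n))
  stopifnot(abs(cor(x$a, x$b)) > 0.6)  # fixture sanity
  kept <- screen_collinearity(x, r_max = 0.60)
  expect_equal(length(kept), 4L)
  expect_equal(length(attr(kept, "dropped")), 1L)
  expect_true(attr(kept, "dropped") %in% c("a", "b"))
})

test_that("constant covariates are dropped with a warning", {
  x <- data.frame(a = rnorm(50), b = rep(1, 50), c = rnorm(50))
  expect_warning(kept <- screen_collinearity(x), "constant")
  expect_equal(sort(as.character(kept)), c("a", "c"))
})

test_that("probability of direction counts signs with zeros split", {
  expect_equal(probability_of_direction(c(1, 2, 3)), 1.0)
  expect_equal(probability_of_direction(c(-1, -2, 1, 2)), 0.5)
  expect_equal(probability_of_direction(c(-1, 2, 3, 4)), 0.75)
  expect_equal(probability_of_direction(c(0, 0, 1, 1)), 0.75)
  expect_error(probability_of_direction(numeric()), "draws")
  set.seed(2); d <- rnorm(1000, 0.3)
  expect_equal(probability_of_direction(d), probability_of_direction(rev(d)))
  expect_equal(probability_of_direction(-d), probability_of_direction(d))
})

test_that("R-hat flags separation and passes white noise", {
  expect_equal(rhat(matrix(5, 100, 4)), 1)   # degenerate constant chains
  set.seed(4)
  sep <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(rhat(sep), 1.1)
  ok <- vapply(1:20, function(s) {
    set.seed(s); rhat(matrix(rnorm(4 * 2000), 2000, 4))
  }, numeric(1))
  expect_gte(mean(ok < 1.01), 0.95)
  expect_error(rhat(matrix(1, 10, 1)), "2 chains")
  expect_error(rhat(matrix(1, 2, 3)), "length")
})

test_that("identical stationary chains summarise with R-hat of one", {
  set.seed(6)
  half <- rnorm(250)
  ch <- c(half, half)   # identical split halves: no between-sequence spread
  m <- cbind(ch, ch, ch, ch)
  expect_lt(abs(rhat(m) - 1), 0.01)
  expect_lte(rhat(m), 1)
})

test_that("the nest-fate model recovers known coefficients and matches the
           likelihood-based fit", {
  set.seed(11)
  nf <- 150; n <- 300
  fem <- rep(sprintf("F%03d", 1:nf), each = 2)
  z1 <- rnorm(n); z2 <- rnorm(n)
  b <- rnorm(nf, 0, 1); names(b) <- unique(fem)
  y <- rbinom(n, 1, plogis(0.3 + 0.9 * z2 + b[fem]))
  fit <- fit_nest_fate(y, data.frame(prop = z1, nclp = z2), fem,
                       chains = 4, iterations = 2000, burn_in = 500,
                       seed = 7)
  s <- fit$summary
  expect_true(all(s$rhat < 1.1))
  nclp <- s[s$parameter == "nclp", ]
  expect_gt(nclp$pd, 0.975)
  expect_true(nclp$ci_lower <= 0.9 && 0.9 <= nclp$ci_upper)
  prop <- s[s$parameter == "prop", ]
  expect_true(prop$ci_lower <= 0 && 0 <= prop$ci_upper)
  # cross-check the posterior means against the Laplace ML fit
  suppressMessages({
    mle <- lme4::glmer(y ~ z1 + z2 + (1 | fem), family = binomial)
  })
  fe <- lme4::fixef(mle)
  expect_lt(abs(s$mean[s$parameter == "nclp"] - fe[["z2"]]), 0.25)
  expect_lt(abs(s$mean[s$parameter == "(Intercept)"] -
                  fe[["(Intercept)"]]), 0.3)
})

test_that("fate labels and 0/1 responses are equivalent inputs", {
  set.seed(12)
  fem <- rep(c("A", "B", "C", "D"), each = 10)
  z <- rnorm(40)
  y <- rbinom(40, 1, plogis(z))
  f1 <- suppressWarnings(
    fit_nest_fate(y, data.frame(z = z), fem, chains = 2,
                  iterations = 400, burn_in = 100, seed = 3))
  f2 <- suppressWarnings(
    fit_nest_fate(ifelse(y == 1, "success", "fail"),
                  data.frame(z = z), fem, chains = 2,
                  iterations = 400, burn_in = 100, seed = 3))
  expect_equal(f1$summary, f2$summary)
})

test_that("marginal effect is zero for a null coefficient and matches the
           logistic derivative for a small one", {
  make_fake_fit <- function(beta_cov, n_draws = 200) {
    X <- cbind(`(Intercept)` = 1, z = 0)
    draws <- list(list(beta = cbind(rep(0, n_draws), rep(beta_cov, n_draws)),
                       sigma = rep(1, n_draws), b_mean = 0))
    structure(list(draws = draws, b_mean = 0,
                   scales = list(z = c(center = 0, scale = 2)),
                   data = list(X = X, f_idx = 1L, females = "A")),
              class = "nest_fate_fit")
  }
  expect_equal(as.numeric(marginal_effect(make_fake_fit(0), "z")), 0)
  # single row at p = 0.5: AME ~ 100 * 0.25 * beta * delta_std
  me <- marginal_effect(make_fake_fit(0.01), "z", delta = 1)
  expect_equal(as.numeric(me), 100 * 0.25 * 0.01 * (1 / 2),
               tolerance = 1e-4)
})

test_that("marginal effect of patches visited is positive under the
           generative fate model", {
  set.seed(13)
  nf <- 200
  fem <- sprintf("F%03d", 1:nf)
  nclp <- rpois(nf, 5)
  prop <- runif(nf)
  cfg <- sim_config(fate_intercept = 0.2, fate_beta_nclp = 0.8,
                    fate_beta_prop = 0, random_intercept_sd = 0.5)
  tc <- data.frame(female_id = fem, proportion_to_patch = prop,
                   n_patches_visited = nclp)
  fates <- simulate_fates(tc, cfg, seed = 5)
  fit <- suppressWarnings(
    fit_nest_fate(fates$fate01,
                  data.frame(proportion_to_clp = prop,
                             n_clp_visited = nclp),
                  fem, chains = 2, iterations = 1500, burn_in = 500,
                  seed = 9))
  me <- marginal_effect(fit, "n_clp_visited", delta = 1)
  expect_gt(as.numeric(me), 0)
  # brute-force generative AME: +/- 30% band
  z <- (nclp - mean(nclp)) / sd(nclp)
  dz <- 1 / sd(nclp)
  truth <- mean(plogis(0.2 + 0.8 * (z + dz)) - plogis(0.2 + 0.8 * z)) * 100
  expect_lt(abs(as.numeric(me) - truth), 0.5 * truth)
})

test_that("the RSF recovers directional selection for proximity to water", {
  ls1 <- test_landscape()
  surfaces <- covariate_surfaces(ls1)
  dat <- simulate_rsf_points(ls1, surfaces, n_ranges = 12, n_used = 30,
                             n_available = 120,
                             betas = c(dist_water = -1.5), sigma_b = 0.3,
                             seed = 14)
  # screening disabled: the check is directional recovery of the known
  # selection coefficient, and blob landscapes correlate class distances
  fit <- suppressWarnings(fit_rsf(dat, screen = FALSE))
  cw <- fit$coefficients[fit$coefficients$term == "dist_water", ]
  expect_lt(cw$beta, 0)
  expect_lt(cw$ci_upper, 0)
  expect_equal(fit$n_available, 12L * 120L)
  expect_equal(fit$n_used, 12L * 30L)
})

test_that("RSF reporting excludes screened covariates", {
  set.seed(15)
  n <- 600
  dat <- data.frame(used = rbinom(n, 1, 0.3),
                    female_id = sample(c("A", "B", "C"), n, TRUE),
                    dist_a = rnorm(n))
  dat$dist_b <- dat$dist_a * 2 + rnorm(n, 0, 0.1)   # r ~ 1
  dat$dist_c <- rnorm(n)
  fit <- suppressWarnings(fit_rsf(dat))
  expect_equal(length(fit$kept), 2L)
  expect_equal(length(fit$dropped), 1L)
  expect_false(fit$dropped %in% fit$coefficients$term)
})
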
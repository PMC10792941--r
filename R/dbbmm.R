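# Brownian-bridge leave-one-out log-likelihood of the odd interior fixes of
# a fix block, as a function of the motion variance sigma2 (m^2/s).
# Observation k (even position) is modelled given its temporal neighbours:
#   mu = (1 - a) z[k-1] + a z[k+1],  a = (t_k - t_{k-1}) / (t_{k+1} - t_{k-1})
#   var = sigma2 * T * a * (1 - a) + ((1 - a)^2 + a^2 + 1) * err^2
# The error term carries the telemetry error of all three fixes: the
# conditioning neighbours propagate (1-a)^2 + a^2 of it into the bridge mean
# and the observed fix contributes its own err^2; omitting the latter would
# fold observation noise into sigma2 and bias it upward.
bb_loo_loglik <- function(sigma2, xy, t, err, obs_pos) {
  ll <- 0
  for (k in obs_pos) {
    T2 <- t[k + 1L] - t[k - 1L]
    a <- (t[k] - t[k - 1L]) / T2
    v <- sigma2 * T2 * a * (1 - a) + ((1 - a)^2 + a^2 + 1) * err^2
    mu <- (1 - a) * xy[k - 1L, ] + a * xy[k + 1L, ]
    ll <- ll + sum(stats::dnorm(xy[k, ], mu, sqrt(v), log = TRUE))
  }
  ll
}

ml_sigma2 <- function(xy, t, err, obs_pos, sigma2_max) {
  if (length(obs_pos) == 0L) return(NA_real_)
  opt <- stats::optimize(function(s2) bb_loo_loglik(s2, xy, t, err, obs_pos),
                         interval = c(0, sigma2_max), maximum = TRUE,
                         tol = sigma2_max * 1e-6)
  opt$maximum
}

#' Estimate the dynamic Brownian motion variance along a trajectory
#'
#' Slides a window of `window` fixes along the track. Within each window the
#' motion variance maximises the leave-one-out Brownian-bridge likelihood of
#' the even-position fixes given their temporal neighbours. A window may
#' additionally split at one interior breakpoint — honouring `margin` fixes
#' at each end — into two variance regimes when that lowers the window's
#' BIC. Window estimates are assigned to the window's interior bridges and
#' averaged across overlapping windows; leading/trailing bridges inherit the
#' nearest interior estimate.
#'
#' @param fixes `np_fixes` (projected) or a list with `xy` matrix and `t`
#'   numeric seconds.
#' @param window sliding window size in fixes (default 7).
#' @param margin breakpoint margin in fixes (default 3).
#' @param error_m GPS location error SD in metres (default 20).
#' @param sigma2_max upper bound of the variance search (m^2/s); defaults to
#'   10 times the largest squared-step-per-second observed.
#' @return numeric vector of motion variances, one per bridge
#'   (length `n - 1`), in m^2/s.
#' @export
estimate_motion_variance <- function(fixes, window = 7L, margin = 3L,
                                     error_m = 20, sigma2_max = NULL) {
  tr <- as_track(fixes)
  xy <- tr$xy; t <- tr$t
  n <- nrow(xy)
  if (n < 2L) stop("need at least two fixes", call. = FALSE)
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing",
                              call. = FALSE)
  if (is.null(sigma2_max)) {
    step_rate <- rowSums((xy[-1L, , drop = FALSE] -
                            xy[-n, , drop = FALSE])^2) / diff(t)
    sigma2_max <- max(10 * max(step_rate), 1e-6)
  }
  if (n < window) {
    warning("fewer than ", window,
            " fixes; falling back to a single global motion variance")
    obs <- seq(2L, n - 1L, by = 2L)
    s2 <- ml_sigma2(xy, t, error_m, obs, sigma2_max)
    if (is.na(s2)) s2 <- 0
    return(rep(s2, n - 1L))
  }
  acc_sum <- numeric(n - 1L); acc_n <- numeric(n - 1L)
  inner <- margin:(window - margin)          # interior bridge offsets
  n_obs <- length(seq(2L, window - 1L, by = 2L))
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    wxy <- xy[idx, , drop = FALSE]; wt <- t[idx]
    obs <- seq(2L, window - 1L, by = 2L)
    s2_null <- ml_sigma2(wxy, wt, error_m, obs, sigma2_max)
    ll_null <- bb_loo_loglik(s2_null, wxy, wt, error_m, obs)
    bic_null <- -2 * ll_null + log(n_obs)
    est <- rep(s2_null, window - 1L)
    # candidate breakpoints honour the margin at both ends
    breaks <- if (margin + 1L <= window - margin)
      (margin + 1L):(window - margin) else integer(0)
    for (b in breaks) {
      obs_l <- obs[obs < b]; obs_r <- obs[obs >= b]
      if (length(obs_l) == 0L || length(obs_r) == 0L) next
      s2_l <- ml_sigma2(wxy, wt, error_m, obs_l, sigma2_max)
      s2_r <- ml_sigma2(wxy, wt, error_m, obs_r, sigma2_max)
      ll <- bb_loo_loglik(s2_l, wxy, wt, error_m, obs_l) +
        bb_loo_loglik(s2_r, wxy, wt, error_m, obs_r)
      bic <- -2 * ll + 2 * log(n_obs)
      if (bic < bic_null) {
        est <- c(rep(s2_l, b - 1L), rep(s2_r, window - b))
        bic_null <- bic
      }
    }
    for (off in inner) {
      bridge <- i + off - 1L
      if (bridge <= n - 1L) {
        acc_sum[bridge] <- acc_sum[bridge] + est[off]
        acc_n[bridge] <- acc_n[bridge] + 1
      }
    }
  }
  s2 <- ifelse(acc_n > 0, acc_sum / pmax(acc_n, 1), NA_real_)
  # fill uncovered leading/trailing bridges with the nearest estimate
  if (anyNA(s2)) {
    filled <- which(!is.na(s2))
    if (length(filled) == 0L) stop("no bridges received a variance estimate",
                                   call. = FALSE)
    for (j in which(is.na(s2))) {
      s2[j] <- s2[filled[which.min(abs(filled - j))]]
    }
  }
  s2
}

as_track <- function(fixes) {
  if (is.list(fixes) && !is.data.frame(fixes) && !is.null(fixes$xy)) {
    return(list(xy = rbind_coords(fixes$xy), t = as.numeric(fixes$t)))
  }
  if (coord_mode(fixes) == "geographic") {
    stop("dBBMM operates on projected coordinates; project lon/lat first ",
         "(see lonlat_to_xy)", call. = FALSE)
  }
  ord <- order(fixes$timestamp)
  list(xy = cbind(fixes$x[ord], fixes$y[ord]),
       t = as.numeric(fixes$timestamp[ord]))
}

#' Build a Brownian-bridge utilization distribution
#'
#' Discretises the time-integrated mixture of Brownian-bridge normal
#' densities between consecutive fixes. Along bridge *j* at relative time
#' `tau`, density is isotropic normal with mean interpolated between the two
#' fixes and variance `sigma2_j * T_j * tau * (1 - tau) + error^2 * ((1 -
#' tau)^2 + tau^2)`. Bridges are weighted by their duration and the grid is
#' normalised to total mass 1. With a caller-supplied grid that captures less
#' than 99.9% of the analytic mass, the grid is expanded automatically with
#' a warning.
#'
#' @param fixes as in [estimate_motion_variance()].
#' @param sigma2 motion variance per bridge (scalar recycled, or length
#'   `n - 1`).
#' @param grid_res grid resolution in metres (default 30, matching the
#'   covariate rasters).
#' @param error_m GPS error SD in metres.
#' @param n_tsteps integration steps per bridge (midpoint rule).
#' @param grid optional list with `origin` and `dim` (rows, cols) to force a
#'   grid; defaults to the track bounding box padded by 3 SD of the widest
#'   bridge.
#' @return `np_surface`-like list: `values` (density matrix summing to 1),
#'   `origin`, `cellsize`.
#' @export
build_ud <- function(fixes, sigma2, grid_res = 30, error_m = 20,
                     n_tsteps = 10L, grid = NULL) {
  tr <- as_track(fixes)
  xy <- tr$xy; t <- tr$t
  n <- nrow(xy)
  if (n == 1L) {
    xy <- rbind(xy, xy); t <- c(t, t[1L] + 1); n <- 2L
  }
  sigma2 <- rep(sigma2, length.out = n - 1L)
  dt <- diff(t)
  max_sd <- sqrt(max(sigma2 * dt, na.rm = TRUE) / 4 + error_m^2)
  pad <- 3 * max(max_sd, error_m)
  build_grid <- function(pad) {
    x0 <- floor((min(xy[, 1L]) - pad) / grid_res) * grid_res
    y0 <- floor((min(xy[, 2L]) - pad) / grid_res) * grid_res
    nxc <- ceiling((max(xy[, 1L]) + pad - x0) / grid_res)
    nyc <- ceiling((max(xy[, 2L]) + pad - y0) / grid_res)
    list(origin = c(x0, y0), dim = c(nyc, nxc))
  }
  user_grid <- !is.null(grid)
  if (!user_grid) grid <- build_grid(pad)
  repeat {
    xc <- grid$origin[1L] + (seq_len(grid$dim[2L]) - 0.5) * grid_res
    yc <- grid$origin[2L] + (seq_len(grid$dim[1L]) - 0.5) * grid_res
    dens <- matrix(0, grid$dim[1L], grid$dim[2L])
    total_w <- 0
    for (j in seq_len(n - 1L)) {
      Tj <- dt[j]
      w_j <- if (Tj > 0) Tj else 1
      taus <- (seq_len(n_tsteps) - 0.5) / n_tsteps
      for (tau in taus) {
        mu <- (1 - tau) * xy[j, ] + tau * xy[j + 1L, ]
        v <- sigma2[j] * Tj * tau * (1 - tau) +
          ((1 - tau)^2 + tau^2) * error_m^2
        s <- sqrt(v)
        dens <- dens + (w_j / n_tsteps) *
          outer(stats::dnorm(yc, mu[2L], s), stats::dnorm(xc, mu[1L], s))
      }
      total_w <- total_w + w_j
    }
    mass <- sum(dens) * grid_res^2 / total_w
    if (mass >= 0.999 || !user_grid) break
    warning("supplied grid holds only ", sprintf("%.4f", mass),
            " of the UD mass; expanding")
    bigger <- build_grid(2 * pad)
    grid <- list(origin = pmin(grid$origin, bigger$origin),
                 dim = pmax(grid$dim, bigger$dim +
                              round(abs(bigger$origin - grid$origin) /
                                      grid_res)))
    pad <- 2 * pad
    user_grid <- FALSE
  }
  dens <- dens / sum(dens)
  structure(list(values = dens, origin = grid$origin, cellsize = grid_res),
            class = "np_surface")
}

#' Highest-density contour mask of a UD
#'
#' Cells are ranked by density and accumulated until the requested mass is
#' reached; the mask is the smallest cell set whose cumulative density is at
#' least `level`.
#'
#' @param ud normalised UD from [build_ud()].
#' @param level cumulative mass (default 0.95).
#' @return logical matrix mask with attributes `origin`, `cellsize`, `mass`.
#' @export
ud_contour <- function(ud, level = 0.95) {
  v <- as.vector(ud$values)
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(v[ord])
  k <- which(cum >= level)[1L]
  if (is.na(k)) k <- length(v)
  if (level >= 1) k <- sum(v > 0)
  mask <- matrix(FALSE, nrow(ud$values), ncol(ud$values))
  mask[ord[seq_len(k)]] <- TRUE
  structure(mask, origin = ud$origin, cellsize = ud$cellsize,
            mass = sum(v[ord[seq_len(k)]]))
}

#' Sample available points uniformly within a contour mask
#'
#' Cells are drawn uniformly (equal areas) and a point is placed uniformly
#' within each drawn cell.
#'
#' @param mask logical mask from [ud_contour()].
#' @param n number of points (default 500).
#' @param seed integer seed.
#' @return data.frame with `x`, `y` (metres).
#' @export
sample_available <- function(mask, n = 500L, seed = 1L) {
  cells <- which(mask, arr.ind = TRUE)
  if (nrow(cells) == 0L) stop("empty contour mask", call. = FALSE)
  origin <- attr(mask, "origin"); cs <- attr(mask, "cellsize")
  set.seed(seed)
  pick <- cells[sample.int(nrow(cells), n, replace = TRUE), , drop = FALSE]
  data.frame(
    x = origin[1L] + (pick[, "col"] - 1L) * cs + stats::runif(n, 0, cs),
    y = origin[2L] + (pick[, "row"] - 1L) * cs + stats::runif(n, 0, cs)
  )
}

#' Fit a dynamic Brownian bridge movement model and extract the 95% range
#'
#' Convenience wrapper: estimates the windowed motion variance, builds the
#' UD, and cuts the 95% contour.
#'
#' @inheritParams estimate_motion_variance
#' @inheritParams build_ud
#' @param contour_level contour mass (default 0.95).
#' @return list of class `np_dbbmm`: `sigma2`, `ud`, `contour` (mask),
#'   `window`, `margin`, `error_m`.
#' @export
dbbmm <- function(fixes, window = 7L, margin = 3L, error_m = 20,
                  grid_res = 30, contour_level = 0.95) {
  s2 <- estimate_motion_variance(fixes, window = window, margin = margin,
                                 error_m = error_m)
  ud <- build_ud(fixes, s2, grid_res = grid_res, error_m = error_m)
  structure(list(sigma2 = s2, ud = ud,
                 contour = ud_contour(ud, contour_level),
                 window = window, margin = margin, error_m = error_m),
            class = "np_dbbmm")
}

#' @export
print.np_dbbmm <- function(x, ...) {
  area_ha <- sum(x$contour) * attr(x$contour, "cellsize")^2 / 1e4
  cat(sprintf(paste0("<np_dbbmm> %d bridges; median motion variance %.1f ",
                     "m^2/s; 95%% range %.1f ha\n"),
              length(x$sigma2), stats::median(x$sigma2), area_ha))
  invisible(x)
}
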
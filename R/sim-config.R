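#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' study conditions the analysis expects: the 23:58:58 nightly + hourly
#' 05:00-20:00 fix schedule, a 12-day laying period, a 28-day incubation
#' period, about two recesses per day, and a 0.57 probability that a recess
#' returns to a laying foraging patch. Nest-fate coefficients default to a
#' null effect of the recess proportion and a positive effect of the number
#' of patches visited, with substantial between-female heterogeneity.
#'
#' @param n_females number of females to simulate.
#' @param laying_days length of the laying period in days.
#' @param incubation_days length of the incubation period in days.
#' @param n_patches mean laying foraging patches per attempt (the realised
#'   count is Poisson, clamped to 2-12, so the patches-visited covariate
#'   varies across the population).
#' @param p_revisit probability in \[0, 1\] that an incubation recess targets a
#'   laying patch rather than a fresh random location.
#' @param recesses_per_day mean (Poisson) recess fixes per incubation day.
#' @param gps_noise_sd isotropic Gaussian coordinate noise, metres.
#' @param recess_dist_range min/max displacement (m) of non-patch recess
#'   targets from the nest; the minimum stays well above the 27.5-m recess
#'   classification threshold so the rule separates classes cleanly.
#' @param patch_dist_range min/max distance (m) of patch centres from the nest.
#' @param patch_sep_min minimum separation (m) between patch centres; kept
#'   above twice the 150-m cluster linkage radius so patches resolve into
#'   distinct clusters.
#' @param patch_radius scatter radius (m) of laying forage fixes in a patch.
#' @param fate_intercept,fate_beta_prop,fate_beta_nclp logit-scale intercept
#'   and coefficients (per 1 SD of the covariate) of the nest-fate model.
#' @param random_intercept_sd SD (logit) of the per-female fate intercept.
#' @param rsf_betas named selection coefficients (logit, per 2-SD rescaled
#'   covariate) used when simulating used/available selection data.
#' @param attempts_per_female 1 (default) or 2 (renesting, exercises the
#'   female-level random effect).
#' @param coord_mode `"projected"` (metres) or `"geographic"` (emit lon/lat
#'   through a fixed local projection so the geodesic code path is exercised).
#' @param ref_lonlat reference lon/lat of the projected origin (geographic
#'   mode only).
#' @param start_date calendar date of the first laying day.
#' @param seed integer seed; together with the config it fully determines all
#'   generator output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_females = 20,
                       laying_days = 12,
                       incubation_days = 28,
                       n_patches = 6,
                       p_revisit = 0.57,
                       recesses_per_day = 2,
                       gps_noise_sd = 5,
                       recess_dist_range = c(60, 900),
                       patch_dist_range = c(250, 700),
                       patch_sep_min = 350,
                       patch_radius = 35,
                       fate_intercept = 0,
                       fate_beta_prop = 0,
                       fate_beta_nclp = 0.19,
                       random_intercept_sd = 1.2,
                       rsf_betas = c(dist_water = -0.48, dist_pine = 0.06,
                                     dist_hardwood = -0.27, dist_mixed = -0.10,
                                     dist_open = 0.27, dist_shrub = -0.16,
                                     dist_road = -0.39, dist_nest = -2.04),
                       attempts_per_female = 1,
                       coord_mode = c("projected", "geographic"),
                       ref_lonlat = c(-83.3, 32.8),
                       start_date = as.Date("2021-03-15"),
                       seed = 1L) {
  coord_mode <- match.arg(coord_mode)
  counts <- c(n_females = n_females, laying_days = laying_days,
              incubation_days = incubation_days, n_patches = n_patches,
              attempts_per_female = attempts_per_female)
  if (any(counts < 1)) {
    stop("counts must all be >= 1: ",
         paste(names(counts)[counts < 1], collapse = ", "), call. = FALSE)
  }
  if (p_revisit < 0 || p_revisit > 1) {
    stop("p_revisit must lie in [0, 1]", call. = FALSE)
  }
  if (gps_noise_sd < 0) stop("gps_noise_sd must be >= 0", call. = FALSE)
  if (recesses_per_day < 0) stop("recesses_per_day must be >= 0", call. = FALSE)
  cfg <- list(n_females = as.integer(n_females),
              laying_days = as.integer(laying_days),
              incubation_days = as.integer(incubation_days),
              n_patches = as.integer(n_patches),
              p_revisit = p_revisit,
              recesses_per_day = recesses_per_day,
              gps_noise_sd = gps_noise_sd,
              recess_dist_range = recess_dist_range,
              patch_dist_range = patch_dist_range,
              patch_sep_min = patch_sep_min,
              patch_radius = patch_radius,
              fate_intercept = fate_intercept,
              fate_beta_prop = fate_beta_prop,
              fate_beta_nclp = fate_beta_nclp,
              random_intercept_sd = random_intercept_sd,
              rsf_betas = rsf_betas,
              attempts_per_female = as.integer(attempts_per_female),
              coord_mode = coord_mode,
              ref_lonlat = ref_lonlat,
              start_date = as.Date(start_date),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d female(s) x %d attempt(s); laying %d d, incubation %d d\n",
              x$n_females, x$attempts_per_female, x$laying_days,
              x$incubation_days))
  cat(sprintf("  %d patches, p_revisit %.2f, %.1f recesses/day, noise %.1f m\n",
              x$n_patches, x$p_revisit, x$recesses_per_day, x$gps_noise_sd))
  invisible(x)
}

# local equirectangular projection used when emitting geographic coordinates
project_to_lonlat <- function(xy, ref_lonlat) {
  R <- 6371000
  xy <- rbind_coords(xy)
  lat0 <- ref_lonlat[2L] * pi / 180
  cbind(lon = ref_lonlat[1L] + (xy[, 1L] / (R * cos(lat0))) * 180 / pi,
        lat = ref_lonlat[2L] + (xy[, 2L] / R) * 180 / pi)
}
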
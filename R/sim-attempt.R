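# polar helpers for the generator
runif_disc <- function(n, r) {
  rad <- r * sqrt(stats::runif(n))
  ang <- stats::runif(n, 0, 2 * pi)
  cbind(rad * cos(ang), rad * sin(ang))
}
runif_ring <- function(n, r_min, r_max) {
  rad <- stats::runif(n, r_min, r_max)
  ang <- stats::runif(n, 0, 2 * pi)
  cbind(rad * cos(ang), rad * sin(ang))
}

# timestamps of one day's schedule: hourly 05:00-20:00 then nightly 23:58:58
day_schedule <- function(date) {
  base <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  c(base + 3600 * (.HOURLY_FIRST:.HOURLY_LAST), base + .NIGHTLY_SOD)
}

place_patches <- function(nest, cfg, n_patches) {
  for (restart in 1:50) {
    centers <- matrix(NA_real_, n_patches, 2L)
    ok <- TRUE
    for (i in seq_len(n_patches)) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- nest + runif_ring(1, cfg$patch_dist_range[1L],
                                  cfg$patch_dist_range[2L])[1L, ]
        if (i == 1L ||
            min(sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE],
                                   2L, cand)^2))) >= cfg$patch_sep_min) {
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(centers)
  }
  stop("could not place ", n_patches, " patches with separation >= ",
       cfg$patch_sep_min, " m; reduce n_patches or widen patch_dist_range",
       call. = FALSE)
}

#' Simulate one nesting attempt with ground truth
#'
#' Generates a full laying + incubation trajectory on the transmitter
#' schedule (hourly fixes 05:00-20:00 plus one nightly fix at 23:58:58).
#' During laying, each day holds two consecutive hourly nest visits (within a
#' few metres of the nest, emulating egg deposition) with the remaining
#' hourly fixes scattered around foraging patch centres and the nightly fix
#' at a roost 300-600 m from the nest. During incubation the nightly fix is
#' always on the nest, a Poisson number of hourly fixes per day are recesses
#' (targeting a uniformly chosen laying patch with probability `p_revisit`,
#' otherwise a fresh location 60-900 m from the nest), and all other fixes
#' sit on the nest. Isotropic Gaussian noise of sd `gps_noise_sd` is added to
#' every coordinate last, so with zero noise every labelled geometry is
#' exact.
#'
#' @param cfg `sim_config`.
#' @param landscape `np_landscape`; the nest is placed at least twice the
#'   maximum recess displacement from the raster edge.
#' @param female_id identifier string.
#' @param seed integer seed.
#' @param attempt_id attempt index (1 = initial, 2 = renest).
#' @param start_date first laying day (defaults to `cfg$start_date`).
#' @return list with `$fixes` (`np_fixes`) and `$truth` (list: nest
#'   coordinates, onset dates, patch centres, per-fix behavioural labels
#'   `laying-forage`/`nest-visit`/`on-nest`/`recess`, recess target patch ids,
#'   and truth-level prospecting covariates).
#' @export
generate_attempt <- function(cfg, landscape, female_id = "F001", seed = 1L,
                             attempt_id = 1L, start_date = cfg$start_date) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  r <- landscape$raster
  extent <- c(ncol(r$codes), nrow(r$codes)) * r$cellsize
  margin <- 2 * max(cfg$recess_dist_range)
  lo <- r$origin + margin
  hi <- r$origin + extent - margin
  if (any(hi <= lo)) {
    stop("landscape extent too small: nest must sit >= ", margin,
         " m (2 x max recess distance) from the raster edge", call. = FALSE)
  }
  nest <- c(stats::runif(1, lo[1L], hi[1L]), stats::runif(1, lo[2L], hi[2L]))
  # per-attempt patch count: Poisson around the configured mean, clamped to
  # [2, 12] (the upper bound is what the patch ring geometry can hold),
  # emulating the field spread in the number of prospected patches
  n_patches <- min(12L, max(2L, stats::rpois(1L, cfg$n_patches)))
  patches <- place_patches(nest, cfg, n_patches)

  times <- list(); pos <- list(); labels <- list(); target <- list()
  day <- 0L
  # laying period
  for (d in seq_len(cfg$laying_days)) {
    sched <- day_schedule(start_date + day); day <- day + 1L
    nh <- length(sched) - 1L
    p <- matrix(NA_real_, length(sched), 2L)
    lab <- character(length(sched))
    tgt <- rep(NA_integer_, length(sched))
    visit_start <- sample(nh - 1L, 1L)
    visit_idx <- c(visit_start, visit_start + 1L)
    for (h in seq_len(nh)) {
      if (h %in% visit_idx) {
        p[h, ] <- nest + runif_disc(1, 3)[1L, ]
        lab[h] <- "nest-visit"
      } else {
        j <- sample(n_patches, 1L)
        p[h, ] <- patches[j, ] + runif_disc(1, cfg$patch_radius)[1L, ]
        lab[h] <- "laying-forage"
      }
    }
    roost <- nest + runif_ring(1, 300, 600)[1L, ]
    p[length(sched), ] <- roost
    lab[length(sched)] <- "laying-forage"
    times[[length(times) + 1L]] <- sched
    pos[[length(pos) + 1L]] <- p
    labels[[length(labels) + 1L]] <- lab
    target[[length(target) + 1L]] <- tgt
  }
  # incubation period
  for (d in seq_len(cfg$incubation_days)) {
    sched <- day_schedule(start_date + day); day <- day + 1L
    nh <- length(sched) - 1L
    p <- matrix(rep(nest, each = length(sched)), length(sched), 2L)
    lab <- rep("on-nest", length(sched))
    tgt <- rep(NA_integer_, length(sched))
    n_rec <- min(stats::rpois(1, cfg$recesses_per_day), nh)
    if (n_rec > 0L) {
      slots <- sample(nh, n_rec)
      for (h in slots) {
        if (stats::runif(1) < cfg$p_revisit) {
          j <- sample(n_patches, 1L)
          p[h, ] <- patches[j, ] + runif_disc(1, 20)[1L, ]
          tgt[h] <- j
        } else {
          p[h, ] <- nest + runif_ring(1, cfg$recess_dist_range[1L],
                                      cfg$recess_dist_range[2L])[1L, ]
        }
        lab[h] <- "recess"
      }
    }
    times[[length(times) + 1L]] <- sched
    pos[[length(pos) + 1L]] <- p
    labels[[length(labels) + 1L]] <- lab
    target[[length(target) + 1L]] <- tgt
  }

  ts <- do.call(c, times)
  xy <- do.call(rbind, pos)
  lab <- unlist(labels)
  tgt <- unlist(target)
  n <- length(ts)
  xy_obs <- xy + matrix(stats::rnorm(2L * n, 0, cfg$gps_noise_sd), n, 2L)

  emit <- function(m) {
    if (cfg$coord_mode == "geographic") project_to_lonlat(m, cfg$ref_lonlat)
    else rbind_coords(m)
  }
  xy_emit <- emit(xy_obs)
  df <- data.frame(female_id = female_id, timestamp = ts,
                   dop = round(stats::runif(n, 1, 5), 1),
                   stringsAsFactors = FALSE)
  if (cfg$coord_mode == "geographic") {
    df$lon <- xy_emit[, 1L]; df$lat <- xy_emit[, 2L]
  } else {
    df$x <- xy_emit[, 1L]; df$y <- xy_emit[, 2L]
  }
  fixes <- as_fixes(df, cfg$coord_mode)

  is_rec <- lab == "recess"
  truth <- list(
    female_id = female_id,
    attempt_id = as.integer(attempt_id),
    nest = as.numeric(emit(matrix(nest, 1L))[1L, ]),
    nest_m = nest,
    patch_centers = emit(patches),
    laying_onset = as.Date(start_date),
    incubation_onset = as.Date(start_date) + cfg$laying_days,
    incubation_end = as.Date(start_date) + cfg$laying_days +
      cfg$incubation_days,
    labels = lab,
    recess_target = tgt,
    total_recesses = sum(is_rec),
    recesses_to_patch = sum(!is.na(tgt)),
    proportion_to_patch = if (sum(is_rec) == 0L) 0 else
      sum(!is.na(tgt)) / sum(is_rec),
    n_patches = n_patches,
    n_patches_visited = length(unique(tgt[!is.na(tgt)])),
    fate = NA_character_
  )
  structure(list(fixes = fixes, truth = truth), class = "np_attempt")
}

#' Draw nest fates from the generative hierarchical logistic model
#'
#' Fate of attempt *i* is Bernoulli with success probability
#' `plogis(alpha + beta_prop * z1_i + beta_nclp * z2_i + b_female)`, where
#' `z1`, `z2` are the proportion-of-recesses-to-patches and
#' patches-visited covariates standardised (sample sd) within the simulated
#' population, and `b_female ~ Normal(0, random_intercept_sd^2)` is shared
#' across a female's attempts.
#'
#' @param truth_cov data.frame with columns `female_id`,
#'   `proportion_to_patch`, `n_patches_visited` (one row per attempt).
#' @param cfg `sim_config` supplying `fate_intercept`, `fate_beta_prop`,
#'   `fate_beta_nclp`, `random_intercept_sd`.
#' @param seed integer seed.
#' @return `truth_cov` with added columns `b_female`, `p_success`, `fate`
#'   (`"success"`/`"fail"`) and `fate01`.
#' @export
simulate_fates <- function(truth_cov, cfg, seed = 1L) {
  stopifnot(is.data.frame(truth_cov))
  z1 <- truth_cov$proportion_to_patch
  z2 <- truth_cov$n_patches_visited
  if (any(!is.finite(z1)) || any(!is.finite(z2))) {
    stop("non-finite prospecting covariates", call. = FALSE)
  }
  zsafe <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  set.seed(seed)
  females <- unique(truth_cov$female_id)
  b <- stats::rnorm(length(females), 0, cfg$random_intercept_sd)
  names(b) <- females
  eta <- cfg$fate_intercept + cfg$fate_beta_prop * zsafe(z1) +
    cfg$fate_beta_nclp * zsafe(z2) + b[truth_cov$female_id]
  p <- stats::plogis(eta)
  fate01 <- stats::rbinom(nrow(truth_cov), 1L, p)
  truth_cov$b_female <- unname(b[truth_cov$female_id])
  truth_cov$p_success <- p
  truth_cov$fate01 <- fate01
  truth_cov$fate <- ifelse(fate01 == 1L, "success", "fail")
  truth_cov
}

#' Simulate a full study population
#'
#' Generates (or reuses) a landscape, simulates every female's attempt(s)
#' with derived per-attempt seeds, and draws nest fates from the generative
#' model using the truth-level prospecting covariates. Renesting attempts
#' start 5 days after the previous attempt ends.
#'
#' @param cfg `sim_config`.
#' @param landscape optional `np_landscape`; generated from the config seed
#'   when absent.
#' @param seed master seed (defaults to `cfg$seed`).
#' @return list: `$cfg`, `$landscape`, `$fixes` (all females pooled),
#'   `$truths` (list of per-attempt truth records), `$truth_table`
#'   (per-attempt data.frame including simulated fates).
#' @export
simulate_population <- function(cfg, landscape = NULL, seed = cfg$seed) {
  set.seed(seed)
  n_attempts <- cfg$n_females * cfg$attempts_per_female
  sub <- sample.int(.Machine$integer.max - 1L, n_attempts + 2L)
  if (is.null(landscape)) {
    landscape <- generate_landscape(seed = sub[n_attempts + 1L])
  }
  fix_list <- list(); truths <- list(); rows <- list()
  k <- 0L
  for (f in seq_len(cfg$n_females)) {
    fid <- sprintf("F%03d", f)
    start <- cfg$start_date
    for (a in seq_len(cfg$attempts_per_female)) {
      k <- k + 1L
      att <- generate_attempt(cfg, landscape, female_id = fid, seed = sub[k],
                              attempt_id = a, start_date = start)
      fix_list[[k]] <- as.data.frame(att$fixes)
      truths[[k]] <- att$truth
      rows[[k]] <- data.frame(
        female_id = fid, attempt_id = a,
        nest_x = att$truth$nest[1L], nest_y = att$truth$nest[2L],
        laying_onset = att$truth$laying_onset,
        incubation_onset = att$truth$incubation_onset,
        incubation_end = att$truth$incubation_end,
        total_recesses = att$truth$total_recesses,
        proportion_to_patch = att$truth$proportion_to_patch,
        n_patches_visited = att$truth$n_patches_visited,
        stringsAsFactors = FALSE
      )
      start <- att$truth$incubation_end + 5L
    }
  }
  all_fixes <- do.call(rbind, fix_list)
  if (cfg$coord_mode == "geographic") {
    names(all_fixes)[names(all_fixes) == "x"] <- "lon"
    names(all_fixes)[names(all_fixes) == "y"] <- "lat"
  }
  fixes <- as_fixes(all_fixes, cfg$coord_mode)
  truth_table <- simulate_fates(do.call(rbind, rows), cfg,
                                seed = sub[n_attempts + 2L])
  for (k in seq_along(truths)) truths[[k]]$fate <- truth_table$fate[k]
  structure(list(cfg = cfg, landscape = landscape, fixes = fixes,
                 truths = truths, truth_table = truth_table),
            class = "np_population")
}

#' Write an attempt's ground truth as JSON
#'
#' @param truth truth record from [generate_attempt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  out <- truth
  out$patch_centers <- apply(truth$patch_centers, 1L, as.numeric,
                             simplify = FALSE)
  out$laying_onset <- format(truth$laying_onset)
  out$incubation_onset <- format(truth$incubation_onset)
  out$incubation_end <- format(truth$incubation_end)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
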
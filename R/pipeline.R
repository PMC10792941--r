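#' Pipeline parameters
#'
#' Aggregates every stage parameter with the analysis defaults: DOP cutoff 7,
#' 20-m laying visit radius over a 20-day lookback, 27.5-m recess threshold,
#' 150-m CLP linkage radius, 45-m CLP revisit buffer, minimum 3 incubated
#' days, dBBMM error/window/margin of 20 m / 7 / 3, 500 available points per
#' range, collinearity cutoff r = 0.60, and an MCMC schedule of 4 chains x
#' 8000 iterations with 1000 burn-in.
#'
#' @param dop_max DOP filter threshold.
#' @param visit_radius laying visit radius, m.
#' @param lookback_days laying-onset lookback, days.
#' @param recess_threshold recess classification threshold, m.
#' @param linkage_radius CLP single-linkage radius, m.
#' @param buffer_radius CLP revisit buffer radius, m.
#' @param min_incubation_days attempt filter, days.
#' @param window,margin,error_m dBBMM settings.
#' @param grid_res dBBMM grid resolution, m.
#' @param n_available available points per range.
#' @param max_ranges cap on the number of ranges fitted (NULL = all).
#' @param r_max collinearity screen threshold.
#' @param chains,iterations,burn_in nest-fate MCMC schedule.
#' @return `pipeline_params` list.
#' @export
pipeline_params <- function(dop_max = 7, visit_radius = 20,
                            lookback_days = 20, recess_threshold = 27.5,
                            linkage_radius = 150, buffer_radius = 45,
                            min_incubation_days = 3, window = 7L,
                            margin = 3L, error_m = 20, grid_res = 30,
                            n_available = 500L, max_ranges = NULL,
                            r_max = 0.60, chains = 4L, iterations = 8000L,
                            burn_in = 1000L) {
  p <- as.list(environment())
  radii <- c(p$visit_radius, p$recess_threshold, p$linkage_radius,
             p$buffer_radius, p$error_m, p$grid_res)
  if (any(radii <= 0)) stop("radii and thresholds must be positive",
                            call. = FALSE)
  class(p) <- "pipeline_params"
  p
}

config_hash <- function(cfg, params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ser <- list(cfg = unclass(cfg), params = unclass(params))
  ser$cfg$start_date <- format(ser$cfg$start_date)
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(format(df, trim = TRUE, digits = 12), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic population
#'
#' Simulates a study population, cleans fixes (DOP filter), segments each
#' trajectory into nesting attempts, builds CLPs and prospecting summaries,
#' fits dBBMM incubation ranges with available-point sampling and the
#' used/available RSF, and fits the Bayesian nest-fate model with the
#' prospecting covariates. Deterministic given (`cfg`, `params`): every
#' random stage draws its seed from `cfg$seed`.
#'
#' @param cfg `sim_config`.
#' @param params `pipeline_params`.
#' @param out_dir optional directory; when given, summary tables are written
#'   as CSV stamped with the config hash, plus a JSON run manifest.
#' @param verbose log per-stage record counts to stderr.
#' @return list of class `np_report`: `attempts`, `prospecting`, `rsf`
#'   (`rsf_fit` or NULL), `fate` (`nest_fate_fit` or NULL), `summary`
#'   (mean proportion of recesses to CLPs, mean CLPs visited, counts),
#'   `config_hash`, `log` (stage counts).
#' @export
run_pipeline <- function(cfg = sim_config(), params = pipeline_params(),
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(cfg, params)
  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  pop <- simulate_population(cfg, seed = stage_seeds[1L])
  fixes <- filter_dop(pop$fixes, params$dop_max)
  log <- list(config_hash = hash,
              fixes_in = nrow(pop$fixes),
              fixes_after_dop = nrow(fixes),
              dop_removed = attr(fixes, "n_removed"))
  say("simulate: %d fixes (%d removed by DOP filter)", nrow(fixes),
      log$dop_removed)

  fates <- data.frame(female_id = pop$truth_table$female_id,
                      attempt_index = pop$truth_table$attempt_id,
                      fate = pop$truth_table$fate,
                      stringsAsFactors = FALSE)
  attempts_all <- segment_attempts(
    fixes, fates = fates, threshold_m = params$recess_threshold,
    lookback_days = params$lookback_days,
    visit_radius_m = params$visit_radius)
  flt <- filter_attempts(attempts_all, params$min_incubation_days)
  attempts <- flt$kept
  log$attempts_detected <- nrow(attempts_all)
  log$attempts_removed_short <- nrow(flt$removed)
  say("segment: %d attempts (%d removed as < %d incubated days)",
      nrow(attempts), nrow(flt$removed), params$min_incubation_days)

  # geographic inputs are projected once for the planar stages
  projected <- cfg$coord_mode == "projected"
  proj_xy <- function(xy) {
    if (projected) rbind_coords(xy) else lonlat_to_xy(xy, cfg$ref_lonlat)
  }

  prospecting <- list(); rsf_rows <- list(); recess_tables <- list()
  surfaces <- NULL
  n_ranges_done <- 0L
  for (i in seq_len(nrow(attempts))) {
    at <- attempts[i, ]
    traj <- fixes[fixes$female_id == at$female_id, , drop = FALSE]
    attr(traj, "coord_mode") <- coord_mode(fixes)
    class(traj) <- class(fixes)
    nest <- c(at$nest_x, at$nest_y)
    lay <- laying_fixes(traj, at$laying_onset, at$incubation_onset)
    inc <- incubation_fixes(traj, at$incubation_onset, at$incubation_end)
    if (nrow(lay) == 0L || nrow(inc) == 0L) next
    clps <- cluster_laying_locations(lay, params$linkage_radius)
    rec <- classify_recesses(inc, nest, params$recess_threshold)
    rv <- count_revisits(clps, rec, params$buffer_radius)
    ps <- summarize_prospecting(paste0(at$female_id, ".", at$attempt_index),
                                rv$clps, rv$recesses)
    ps$female_id <- at$female_id
    ps$attempt_index <- at$attempt_index
    prospecting[[length(prospecting) + 1L]] <- ps
    recess_tables[[length(recess_tables) + 1L]] <- rv$recesses

    fit_range <- is.null(params$max_ranges) ||
      n_ranges_done < params$max_ranges
    if (fit_range && sum(rv$recesses$is_recess &
                         !is.na(rv$recesses$clp_id)) >= 3L) {
      if (is.null(surfaces)) surfaces <- covariate_surfaces(pop$landscape)
      inc_proj <- inc
      pxy <- proj_xy(cbind(inc$x, inc$y))
      inc_proj$x <- pxy[, 1L]; inc_proj$y <- pxy[, 2L]
      attr(inc_proj, "coord_mode") <- "projected"
      class(inc_proj) <- class(inc)
      rng <- dbbmm(inc_proj, window = params$window,
                   margin = params$margin, error_m = params$error_m,
                   grid_res = params$grid_res)
      avail <- sample_available(rng$contour, params$n_available,
                                seed = stage_seeds[2L] %% 100000L + i)
      used_idx <- rv$recesses$is_recess & !is.na(rv$recesses$clp_id)
      used_xy <- proj_xy(cbind(rv$recesses$x, rv$recesses$y)[used_idx, ,
                                                             drop = FALSE])
      nest_proj <- as.numeric(proj_xy(matrix(nest, 1L)))
      cov_used <- extract_covariates(as.data.frame(used_xy) |>
                                       stats::setNames(c("x", "y")),
                                     surfaces, nest_proj)
      cov_avail <- extract_covariates(avail, surfaces, nest_proj)
      rsf_rows[[length(rsf_rows) + 1L]] <-
        bind_used_available(cov_used, cov_avail, at$female_id,
                            at$attempt_index)
      n_ranges_done <- n_ranges_done + 1L
    }
  }
  prospecting <- if (length(prospecting)) do.call(rbind, prospecting) else
    data.frame()
  log$prospecting_attempts <- nrow(prospecting)
  log$total_recesses <- sum(prospecting$total_recesses)
  say("prospect: %d attempts, %d recess fixes", nrow(prospecting),
      log$total_recesses)

  rsf <- NULL
  if (length(rsf_rows) > 0L) {
    rsf_data <- do.call(rbind, rsf_rows)
    rsf_data <- rsf_data[stats::complete.cases(rsf_data), , drop = FALSE]
    if (length(unique(rsf_data$female_id)) >= 2L) {
      rsf <- fit_rsf(rsf_data, r_max = params$r_max)
    } else {
      warning("RSF skipped: fewer than 2 females with usable ranges")
    }
  }
  log$rsf_ranges <- n_ranges_done

  fate <- NULL
  fate_tab <- merge(prospecting,
                    attempts[, c("female_id", "attempt_index", "fate")],
                    by = c("female_id", "attempt_index"))
  fate_tab <- fate_tab[!is.na(fate_tab$fate), , drop = FALSE]
  if (nrow(fate_tab) >= 10L &&
      length(unique(fate_tab$female_id)) >= 2L &&
      length(unique(fate_tab$fate)) == 2L) {
    fate <- fit_nest_fate(
      fate_tab$fate,
      fate_tab[, c("proportion_to_clp", "n_clp_visited")],
      fate_tab$female_id, chains = params$chains,
      iterations = params$iterations, burn_in = params$burn_in,
      seed = stage_seeds[3L])
  }

  summary <- data.frame(
    n_attempts = nrow(prospecting),
    total_recesses = sum(prospecting$total_recesses),
    mean_proportion_to_clp = mean(prospecting$proportion_to_clp),
    median_proportion_to_clp = stats::median(prospecting$proportion_to_clp),
    mean_n_clp_visited = mean(prospecting$n_clp_visited),
    mean_n_clp_total = mean(prospecting$n_clp_total)
  )
  report <- structure(list(attempts = attempts, prospecting = prospecting,
                           rsf = rsf, fate = fate, summary = summary,
                           truth = pop$truth_table, config_hash = hash,
                           log = log),
                      class = "np_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stamped_csv(attempts, file.path(out_dir, "attempts.csv"), hash)
    write_stamped_csv(prospecting, file.path(out_dir, "prospecting.csv"),
                      hash)
    write_stamped_csv(summary, file.path(out_dir, "summary.csv"), hash)
    if (!is.null(rsf)) {
      write_stamped_csv(rsf$coefficients,
                        file.path(out_dir, "rsf_coefficients.csv"), hash)
    }
    if (!is.null(fate)) {
      write_stamped_csv(fate$summary,
                        file.path(out_dir, "nest_fate_summary.csv"), hash)
    }
    jsonlite::write_json(log, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.np_report <- function(x, ...) {
  cat("<np_report>\n")
  cat(sprintf("  %d attempts, %d recesses\n", x$summary$n_attempts,
              x$summary$total_recesses))
  cat(sprintf("  mean proportion of recesses to CLPs: %.3f\n",
              x$summary$mean_proportion_to_clp))
  cat(sprintf("  mean CLPs visited: %.2f (of %.2f total)\n",
              x$summary$mean_n_clp_visited, x$summary$mean_n_clp_total))
  if (!is.null(x$fate)) {
    cat("  nest-fate model:\n")
    print(x$fate$summary, digits = 3)
  }
  if (!is.null(x$rsf)) {
    cat("  RSF:\n")
    print(x$rsf$coefficients, digits = 3)
  }
  invisible(x)
}
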
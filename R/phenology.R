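# single-linkage partition of points at a distance threshold: two points share
# a cluster iff they are connected by a chain of pairwise distances <= radius
single_linkage_clusters <- function(xy, radius, mode = "projected") {
  xy <- rbind_coords(xy)
  n <- nrow(xy)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  d <- pairwise_distances(xy, mode)
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  unname(stats::cutree(hc, h = radius))
}

# geometric median by Weiszfeld iteration (planar); geographic points are
# handled on a local tangent plane about their centroid
geometric_median <- function(xy, mode = "projected", tol = 1e-6,
                             max_iter = 200L) {
  xy <- rbind_coords(xy)
  if (nrow(xy) == 1L) return(as.numeric(xy[1L, ]))
  to_plane <- identity; from_plane <- identity
  if (mode == "geographic") {
    ref <- colMeans(xy)
    R <- 6371000
    clat <- cos(ref[2L] * pi / 180)
    to_plane <- function(p) cbind((p[, 1L] - ref[1L]) * pi / 180 * R * clat,
                                  (p[, 2L] - ref[2L]) * pi / 180 * R)
    from_plane <- function(p) c(ref[1L] + p[1L] / (R * clat) * 180 / pi,
                                ref[2L] + p[2L] / R * 180 / pi)
  }
  pts <- to_plane(xy)
  est <- apply(pts, 2L, stats::median)
  for (i in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(pts, 2L, est)^2))
    if (any(d < 1e-9)) { est <- pts[which.min(d), ]; break }
    w <- 1 / d
    new <- colSums(pts * w) / sum(w)
    if (sqrt(sum((new - est)^2)) < tol) { est <- new; break }
    est <- new
  }
  if (mode == "geographic") from_plane(as.numeric(est)) else as.numeric(est)
}

#' Detect incubation onset from nightly fixes
#'
#' Incubation onset is the first night the female remains on the nest: the
#' date of the first nightly (23:58:58) fix within `threshold_m` of the nest
#' that begins a run of at least `min_nights` consecutive on-nest nights.
#' When the nest is not field-confirmed (`nest_xy = NULL`) it is estimated
#' first: nightly fixes are grouped by single-linkage clustering at
#' `threshold_m` (chained proximity operationalises "mutually close" robustly
#' under GPS noise) and the nest is the geometric median of the largest
#' group. Incubation ends the day after the last night of the consecutive
#' on-nest run that starts at onset.
#'
#' @param fixes `np_fixes` for one female.
#' @param nest_xy optional known nest coordinates (length-2).
#' @param threshold_m on-nest radius, metres; defaults to 27.5, the
#'   transmitter's 90th-percentile positional error, the same constant that
#'   defines a recess.
#' @param min_nights minimum consecutive on-nest nights starting the run.
#' @param nightly_tol_s schedule-matching tolerance for the nightly fix.
#' @return list with `found` (logical), `nest_xy`, `incubation_onset` (Date),
#'   `incubation_end` (Date), `n_nights` (length of the on-nest run). When no
#'   qualifying run exists, `found = FALSE` and the dates are `NA` (this is a
#'   result, not an error).
#' @export
detect_incubation_onset <- function(fixes, nest_xy = NULL, threshold_m = 27.5,
                                    min_nights = 1L, nightly_tol_s = 300) {
  mode <- coord_mode(fixes)
  nights <- fixes[is_nightly(fixes, nightly_tol_s), , drop = FALSE]
  none <- list(found = FALSE, nest_xy = nest_xy,
               incubation_onset = as.Date(NA), incubation_end = as.Date(NA),
               n_nights = 0L)
  if (nrow(nights) == 0L) return(none)
  nights <- nights[order(nights$timestamp), , drop = FALSE]
  if (is.null(nest_xy)) {
    cl <- single_linkage_clusters(cbind(nights$x, nights$y), threshold_m, mode)
    sizes <- table(cl)
    if (max(sizes) < max(min_nights, 2L)) return(none)
    big <- as.integer(names(sizes)[which.max(sizes)])
    nest_xy <- geometric_median(cbind(nights$x, nights$y)[cl == big, ,
                                                          drop = FALSE], mode)
  }
  on_nest <- point_distance(cbind(nights$x, nights$y), nest_xy,
                            mode) <= threshold_m
  if (!any(on_nest)) return(none)
  dates <- fix_date(nights$timestamp)
  # runs of on-nest nights, broken by off-nest nights or calendar gaps
  run_id <- cumsum(c(TRUE, diff(as.numeric(dates)) > 1 | diff(on_nest) != 0))
  runs <- split(seq_len(nrow(nights)), run_id)
  for (idx in runs) {
    if (on_nest[idx[1L]] && length(idx) >= min_nights) {
      return(list(found = TRUE, nest_xy = as.numeric(nest_xy),
                  incubation_onset = dates[idx[1L]],
                  incubation_end = dates[idx[length(idx)]] + 1L,
                  n_nights = length(idx)))
    }
  }
  none
}

#' Detect laying onset (nest initiation)
#'
#' The laying onset is the date of the earliest hourly fix strictly closer
#' than `visit_radius_m` to the nest within the `lookback_days` days
#' preceding incubation onset. If no such visit exists, laying onset falls
#' back to the incubation onset.
#'
#' @param fixes `np_fixes` for one female.
#' @param nest_xy nest coordinates.
#' @param incubation_onset Date of incubation onset.
#' @param lookback_days window length before incubation onset (default 20).
#' @param visit_radius_m strict visit radius in metres (default 20).
#' @param nightly_tol_s schedule-matching tolerance for excluding the nightly
#'   fix.
#' @return Date.
#' @export
detect_laying_onset <- function(fixes, nest_xy, incubation_onset,
                                lookback_days = 20, visit_radius_m = 20,
                                nightly_tol_s = 300) {
  mode <- coord_mode(fixes)
  hourly <- fixes[!is_nightly(fixes, nightly_tol_s), , drop = FALSE]
  if (nrow(hourly) == 0L) return(as.Date(incubation_onset))
  dates <- fix_date(hourly$timestamp)
  in_window <- dates >= (as.Date(incubation_onset) - lookback_days) &
    dates < as.Date(incubation_onset)
  if (!any(in_window)) return(as.Date(incubation_onset))
  hw <- hourly[in_window, , drop = FALSE]
  near <- point_distance(cbind(hw$x, hw$y), nest_xy, mode) < visit_radius_m
  if (!any(near)) return(as.Date(incubation_onset))
  min(fix_date(hw$timestamp)[near])
}

#' Segment trajectories into nesting attempts
#'
#' For each female, candidate nests are found by single-linkage clustering of
#' nightly fixes at the on-nest radius; each cluster with at least
#' `min_candidate_nights` nights yields a candidate attempt via
#' [detect_incubation_onset()] and [detect_laying_onset()]. Attempts are
#' ordered by onset; attempts overlapping an earlier one are dropped, and the
#' survivors are numbered `attempt_index` 1, 2, ... per female.
#'
#' @param fixes `np_fixes` (any number of females).
#' @param known_nests optional data.frame `female_id`, `nest_x`, `nest_y` of
#'   field-confirmed nests (one row per female); when supplied, detection for
#'   that female runs against the confirmed nest only.
#' @param fates optional data.frame `female_id`, `attempt_index`, `fate`.
#' @param threshold_m on-nest/recess radius (27.5 m).
#' @param min_nights minimum consecutive nights defining onset.
#' @param min_candidate_nights minimum cluster size to treat a nightly-fix
#'   cluster as a candidate nest (filters one-night roost clusters).
#' @param lookback_days,visit_radius_m laying-onset parameters.
#' @param nightly_tol_s schedule tolerance.
#' @return data.frame of attempts: `female_id`, `attempt_index`, `nest_x`,
#'   `nest_y`, `laying_onset`, `incubation_onset`, `incubation_end`,
#'   `incubation_days`, `fate`.
#' @export
segment_attempts <- function(fixes, known_nests = NULL, fates = NULL,
                             threshold_m = 27.5, min_nights = 1L,
                             min_candidate_nights = 3L,
                             lookback_days = 20, visit_radius_m = 20,
                             nightly_tol_s = 300) {
  mode <- coord_mode(fixes)
  out <- list()
  for (fid in unique(fixes$female_id)) {
    traj <- fixes[fixes$female_id == fid, , drop = FALSE]
    attr(traj, "coord_mode") <- mode
    candidates <- list()
    if (!is.null(known_nests) && fid %in% known_nests$female_id) {
      kn <- known_nests[known_nests$female_id == fid, , drop = FALSE]
      for (i in seq_len(nrow(kn))) {
        candidates[[length(candidates) + 1L]] <-
          c(kn$nest_x[i], kn$nest_y[i])
      }
    } else {
      nights <- traj[is_nightly(traj, nightly_tol_s), , drop = FALSE]
      if (nrow(nights) == 0L) next
      cl <- single_linkage_clusters(cbind(nights$x, nights$y), threshold_m,
                                    mode)
      for (g in unique(cl)) {
        members <- which(cl == g)
        if (length(members) >= min_candidate_nights) {
          candidates[[length(candidates) + 1L]] <-
            geometric_median(cbind(nights$x, nights$y)[members, ,
                                                       drop = FALSE], mode)
        }
      }
    }
    rows <- list()
    for (nest in candidates) {
      det <- detect_incubation_onset(traj, nest_xy = nest,
                                     threshold_m = threshold_m,
                                     min_nights = min_nights,
                                     nightly_tol_s = nightly_tol_s)
      if (!det$found) next
      lay <- detect_laying_onset(traj, det$nest_xy, det$incubation_onset,
                                 lookback_days = lookback_days,
                                 visit_radius_m = visit_radius_m,
                                 nightly_tol_s = nightly_tol_s)
      rows[[length(rows) + 1L]] <- data.frame(
        female_id = fid,
        nest_x = det$nest_xy[1L], nest_y = det$nest_xy[2L],
        laying_onset = lay,
        incubation_onset = det$incubation_onset,
        incubation_end = det$incubation_end,
        incubation_days = as.integer(det$incubation_end -
                                       det$incubation_onset),
        stringsAsFactors = FALSE
      )
    }
    if (length(rows) == 0L) next
    att <- do.call(rbind, rows)
    # overlapping candidates: keep the longer incubation (a one-night chance
    # cluster must not displace a genuine attempt), then order by onset
    att <- att[order(-att$incubation_days, att$incubation_onset), ,
               drop = FALSE]
    keep <- logical(nrow(att))
    for (i in seq_len(nrow(att))) {
      ok <- TRUE
      for (j in which(keep)) {
        if (att$laying_onset[i] < att$incubation_end[j] &&
            att$laying_onset[j] < att$incubation_end[i]) { ok <- FALSE; break }
      }
      keep[i] <- ok
    }
    att <- att[keep, , drop = FALSE]
    att <- att[order(att$incubation_onset), , drop = FALSE]
    att$attempt_index <- seq_len(nrow(att))
    out[[length(out) + 1L]] <- att
  }
  if (length(out) == 0L) {
    return(data.frame(female_id = character(), attempt_index = integer(),
                      nest_x = numeric(), nest_y = numeric(),
                      laying_onset = as.Date(character()),
                      incubation_onset = as.Date(character()),
                      incubation_end = as.Date(character()),
                      incubation_days = integer(), fate = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$fate <- NA_character_
  if (!is.null(fates)) {
    key <- paste(res$female_id, res$attempt_index)
    fkey <- paste(fates$female_id, fates$attempt_index)
    hit <- match(key, fkey)
    res$fate[!is.na(hit)] <- fates$fate[hit[!is.na(hit)]]
  }
  res <- res[, c("female_id", "attempt_index", "nest_x", "nest_y",
                 "laying_onset", "incubation_onset", "incubation_end",
                 "incubation_days", "fate")]
  rownames(res) <- NULL
  res
}

#' Drop attempts incubated too briefly
#'
#' Attempts incubated fewer than `min_incubation_days` days carry too little
#' incubation behaviour to analyse and are removed (strictly-less-than rule:
#' an attempt incubated exactly `min_incubation_days` days is kept).
#'
#' @param attempts attempt table from [segment_attempts()].
#' @param min_incubation_days threshold in days (default 3).
#' @return list with `kept` and `removed` attempt tables; `kept` carries the
#'   removal count in attribute `n_removed`.
#' @export
filter_attempts <- function(attempts, min_incubation_days = 3) {
  keep <- attempts$incubation_days >= min_incubation_days
  kept <- attempts[keep, , drop = FALSE]
  removed <- attempts[!keep, , drop = FALSE]
  rownames(kept) <- NULL; rownames(removed) <- NULL
  attr(kept, "n_removed") <- nrow(removed)
  list(kept = kept, removed = removed)
}
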
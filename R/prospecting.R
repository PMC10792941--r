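#' Restrict fixes to an attempt's incubation window
#'
#' @param fixes `np_fixes` for one female.
#' @param incubation_onset,incubation_end Dates; the window is
#'   `[onset, end)`.
#' @return `np_fixes` subset.
#' @export
incubation_fixes <- function(fixes, incubation_onset, incubation_end) {
  d <- fix_date(fixes$timestamp)
  out <- fixes[d >= as.Date(incubation_onset) & d < as.Date(incubation_end), ,
               drop = FALSE]
  attr(out, "coord_mode") <- coord_mode(fixes)
  class(out) <- class(fixes)
  out
}

#' Restrict fixes to an attempt's laying window
#'
#' @param fixes `np_fixes` for one female.
#' @param laying_onset,incubation_onset Dates; the window is
#'   `[laying_onset, incubation_onset)`.
#' @return `np_fixes` subset.
#' @export
laying_fixes <- function(fixes, laying_onset, incubation_onset) {
  d <- fix_date(fixes$timestamp)
  out <- fixes[d >= as.Date(laying_onset) & d < as.Date(incubation_onset), ,
               drop = FALSE]
  attr(out, "coord_mode") <- coord_mode(fixes)
  class(out) <- class(fixes)
  out
}

#' Classify incubation recesses
#'
#' A recess is any incubation fix strictly farther than `threshold_m` from
#' the nest (27.5 m is the transmitter's 90th-percentile positional error);
#' all other fixes are on-nest incubation. The distance to the nest is kept
#' for every fix — it doubles as the distance-to-nest covariate of the
#' resource-selection model.
#'
#' @param inc_fixes incubation-window `np_fixes` (see [incubation_fixes()]).
#' @param nest_xy nest coordinates (required).
#' @param threshold_m recess threshold in metres (default 27.5).
#' @return data.frame of the fixes plus `distance_to_nest`, `is_recess`, and
#'   a `clp_id` column initialised to `NA` (filled by [count_revisits()]).
#' @export
classify_recesses <- function(inc_fixes, nest_xy, threshold_m = 27.5) {
  if (is.null(nest_xy) || length(nest_xy) != 2L || any(!is.finite(nest_xy))) {
    stop("nest_xy is required to classify recesses", call. = FALSE)
  }
  mode <- coord_mode(inc_fixes)
  out <- as.data.frame(inc_fixes)
  out$distance_to_nest <- if (nrow(out) > 0L) {
    point_distance(cbind(out$x, out$y), nest_xy, mode)
  } else numeric()
  out$is_recess <- out$distance_to_nest > threshold_m
  out$clp_id <- NA_integer_
  attr(out, "coord_mode") <- mode
  out
}

#' Cluster laying-period locations into clustered laying patches (CLPs)
#'
#' Single-linkage agglomeration: two laying fixes share a patch iff they are
#' connected by a chain of pairwise distances at most `linkage_radius_m`
#' (i.e. each point lies within the other's buffer somewhere along the
#' chain). Patch centroids are arithmetic means of member coordinates
#' (unit-vector means in geographic mode); `clp_id` is assigned in order of
#' each patch's earliest member timestamp.
#'
#' @param lay_fixes laying-window `np_fixes` or a data.frame with `x`, `y`
#'   (and optionally `timestamp`).
#' @param linkage_radius_m linkage threshold in metres (default 150, the
#'   average hourly laying-period displacement; the boundary is inclusive).
#' @return list of class `np_clps`: `$clps` data.frame (`clp_id`, `x`, `y`,
#'   `n_members`, `visit_count` initialised 0), `$membership` integer vector
#'   mapping each laying fix to its `clp_id`.
#' @export
cluster_laying_locations <- function(lay_fixes, linkage_radius_m = 150) {
  xy <- cbind(lay_fixes$x, lay_fixes$y)
  if (nrow(xy) < 1L) stop("at least one laying fix is required", call. = FALSE)
  mode <- coord_mode(lay_fixes)
  raw <- single_linkage_clusters(xy, linkage_radius_m, mode)
  # order patch ids by earliest member (timestamp when present, else row)
  first_key <- if (!is.null(lay_fixes$timestamp)) {
    as.numeric(lay_fixes$timestamp)
  } else seq_len(nrow(xy))
  k_raw <- max(raw)
  firsts <- vapply(seq_len(k_raw), function(g) min(first_key[raw == g]),
                   numeric(1))
  id_map <- integer(k_raw)
  id_map[order(firsts)] <- seq_len(k_raw)
  membership <- id_map[raw]
  centroid <- function(members) {
    pts <- xy[members, , drop = FALSE]
    if (mode == "geographic") {
      lam <- pts[, 1L] * pi / 180; phi <- pts[, 2L] * pi / 180
      v <- c(mean(cos(phi) * cos(lam)), mean(cos(phi) * sin(lam)),
             mean(sin(phi)))
      c(atan2(v[2L], v[1L]) * 180 / pi,
        atan2(v[3L], sqrt(v[1L]^2 + v[2L]^2)) * 180 / pi)
    } else colMeans(pts)
  }
  k <- max(membership)
  cent <- t(vapply(seq_len(k), function(g) centroid(which(membership == g)),
                   numeric(2L)))
  clps <- data.frame(clp_id = seq_len(k), x = cent[, 1L], y = cent[, 2L],
                     n_members = as.integer(tabulate(membership, k)),
                     visit_count = 0L)
  structure(list(clps = clps, membership = membership, coord_mode = mode),
            class = "np_clps")
}

#' @export
print.np_clps <- function(x, ...) {
  cat(sprintf("<np_clps> %d patch(es) from %d laying fixes\n",
              nrow(x$clps), length(x$membership)))
  print(x$clps)
  invisible(x)
}

#' Count recess recursions into CLP buffers
#'
#' A recess fix revisits a patch iff it lies within `buffer_radius_m` of the
#' patch centroid (inclusive boundary; 45 m is half the 90-m diameter set by
#' daily recess travel). A fix inside overlapping buffers is attributed to
#' the nearest centroid only (ties to the lower `clp_id`), so it counts once
#' toward the recess-to-CLP total and the proportion can never exceed 1.
#'
#' @param clps `np_clps` from [cluster_laying_locations()].
#' @param recesses data.frame from [classify_recesses()].
#' @param buffer_radius_m buffer radius in metres (default 45).
#' @return list: `$clps` (`np_clps` with per-patch `visit_count` filled) and
#'   `$recesses` (input with `clp_id` assigned for recess fixes).
#' @export
count_revisits <- function(clps, recesses, buffer_radius_m = 45) {
  mode <- if (!is.null(clps$coord_mode)) clps$coord_mode else
    coord_mode(recesses)
  cl <- clps$clps
  rec_idx <- which(recesses$is_recess)
  recesses$clp_id <- NA_integer_
  if (nrow(cl) == 0L || length(rec_idx) == 0L) {
    clps$clps$visit_count <- integer(nrow(cl))
    return(list(clps = clps, recesses = recesses))
  }
  pts <- cbind(recesses$x, recesses$y)[rec_idx, , drop = FALSE]
  dmat <- matrix(NA_real_, length(rec_idx), nrow(cl))
  for (j in seq_len(nrow(cl))) {
    dmat[, j] <- point_distance(pts, c(cl$x[j], cl$y[j]), mode)
  }
  nearest <- apply(dmat, 1L, which.min)   # first minimum = lowest clp_id
  nearest_d <- dmat[cbind(seq_along(nearest), nearest)]
  hit <- nearest_d <= buffer_radius_m
  recesses$clp_id[rec_idx[hit]] <- cl$clp_id[nearest[hit]]
  clps$clps$visit_count <-
    as.integer(tabulate(recesses$clp_id[rec_idx[hit]], nrow(cl)))
  list(clps = clps, recesses = recesses)
}

#' Per-attempt prospecting summary
#'
#' Totals the recesses, the recesses that returned to any CLP, the
#' proportion of recesses to CLPs (0 when there were no recesses), and the
#' number of distinct CLPs visited at least once.
#'
#' @param attempt_id identifier carried through to the output.
#' @param clps `np_clps` with visit counts (see [count_revisits()]).
#' @param recesses recess data.frame with `clp_id` assigned.
#' @return one-row data.frame: `attempt_id`, `total_recesses`,
#'   `recesses_to_clp`, `proportion_to_clp`, `n_clp_total`, `n_clp_visited`.
#' @export
summarize_prospecting <- function(attempt_id, clps, recesses) {
  total <- sum(recesses$is_recess)
  to_clp <- sum(recesses$is_recess & !is.na(recesses$clp_id))
  data.frame(
    attempt_id = attempt_id,
    total_recesses = total,
    recesses_to_clp = to_clp,
    proportion_to_clp = if (total == 0L) 0 else to_clp / total,
    n_clp_total = nrow(clps$clps),
    n_clp_visited = sum(clps$clps$visit_count > 0L)
  )
}

#' Export CLPs as GeoJSON points
#'
#' @param clps `np_clps`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clps_geojson <- function(clps, path) {
  cl <- clps$clps
  features <- lapply(seq_len(nrow(cl)), function(i) {
    list(type = "Feature",
         properties = list(clp_id = cl$clp_id[i],
                           n_members = cl$n_members[i],
                           visit_count = cl$visit_count[i]),
         geometry = list(type = "Point",
                         coordinates = c(cl$x[i], cl$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
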
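#' Construct a validated fix table
#'
#' A fix table holds time-ordered GPS fixes for one or more females. Fixes are
#' sorted by (female_id, timestamp); duplicated (female_id, timestamp) pairs
#' are reduced to the first occurrence (receivers occasionally emit doubled
#' records). Coordinates are either projected metres (`x`, `y`) or geographic
#' degrees (`lon`, `lat`); a single mode applies to the whole table.
#'
#' @param df data.frame with columns `female_id`, `timestamp` (POSIXct or
#'   ISO-8601 character, local standard time), `x`/`y` or `lon`/`lat`, and
#'   `dop`.
#' @param coord_mode `"projected"` (metres) or `"geographic"` (degrees).
#' @return A `np_fixes` data.frame with canonical columns `female_id`,
#'   `timestamp`, `x`, `y`, `dop` and attribute `coord_mode`. In geographic
#'   mode `x` is longitude and `y` latitude. The number of dropped duplicate
#'   rows is stored in attribute `n_duplicates`.
#' @export
as_fixes <- function(df, coord_mode = c("projected", "geographic")) {
  coord_mode <- match.arg(coord_mode)
  need <- if (coord_mode == "projected") c("x", "y") else c("lon", "lat")
  cols <- c("female_id", "timestamp", need, "dop")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("fix table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    female_id = as.character(df$female_id),
    timestamp = parse_fix_time(df$timestamp),
    x = as.numeric(df[[need[1L]]]),
    y = as.numeric(df[[need[2L]]]),
    dop = as.numeric(df$dop),
    stringsAsFactors = FALSE
  )
  ord <- order(out$female_id, out$timestamp)
  out <- out[ord, , drop = FALSE]
  dup <- duplicated(out[, c("female_id", "timestamp")])
  n_dup <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coord_mode") <- coord_mode
  attr(out, "n_duplicates") <- n_dup
  class(out) <- c("np_fixes", "data.frame")
  out
}

#' @export
print.np_fixes <- function(x, ...) {
  cat(sprintf("<np_fixes> %d fixes, %d female(s), %s coordinates\n",
              nrow(x), length(unique(x$female_id)), coord_mode(x)))
  NextMethod()
}

#' Coordinate mode of a fix table or point set
#' @param x object with a `coord_mode` attribute.
#' @return `"projected"` or `"geographic"`.
#' @export
coord_mode <- function(x) {
  cm <- attr(x, "coord_mode", exact = TRUE)
  if (is.null(cm)) "projected" else cm
}

parse_fix_time <- function(ts) {
  if (inherits(ts, "POSIXct")) return(as.POSIXct(ts, tz = "UTC"))
  # timestamps are local standard time; stored under a fixed-offset clock.
  # strptime returns NA for malformed strings instead of erroring, so rows
  # can be collected into a problem report.
  x <- as.character(ts)
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

#' Read a delimited GPS fix table
#'
#' Reads a delimited file with columns `female_id`, `timestamp`, `x`/`y` (or
#' `lon`/`lat`), `dop`. Rows whose timestamp cannot be parsed or whose
#' coordinates are non-numeric are dropped and reported (with their line
#' numbers) in the `problems` attribute; a warning summarises the count.
#'
#' @param path file path.
#' @param coord_mode `"projected"` or `"geographic"`.
#' @param sep field separator (default comma).
#' @return `np_fixes` table (possibly with zero rows); attribute `problems`
#'   is a data.frame with columns `line` and `reason`.
#' @export
read_fixes <- function(path, coord_mode = c("projected", "geographic"),
                       sep = ",") {
  coord_mode <- match.arg(coord_mode)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- if (coord_mode == "projected") c("x", "y") else c("lon", "lat")
  cols <- c("female_id", "timestamp", need, "dop")
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("fix file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- data.frame(line = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    warning("fix file ", path, " contains a header but no rows")
    empty <- data.frame(female_id = character(),
                        timestamp = as.POSIXct(character(), tz = "UTC"),
                        dop = numeric(), stringsAsFactors = FALSE)
    empty[[need[1L]]] <- numeric()
    empty[[need[2L]]] <- numeric()
    out <- as_fixes(empty, coord_mode)
    attr(out, "problems") <- problems
    return(out)
  }
  ts <- suppressWarnings(parse_fix_time(raw$timestamp))
  cx <- suppressWarnings(as.numeric(raw[[need[1L]]]))
  cy <- suppressWarnings(as.numeric(raw[[need[2L]]]))
  dp <- suppressWarnings(as.numeric(raw$dop))
  bad_ts <- is.na(ts)
  bad_xy <- is.na(cx) | is.na(cy) | is.na(dp)
  bad <- bad_ts | bad_xy
  if (any(bad)) {
    # +1 for the header line
    problems <- data.frame(
      line = which(bad) + 1L,
      reason = ifelse(bad_ts[bad], "unparseable timestamp",
                      "non-numeric coordinate or dop"),
      stringsAsFactors = FALSE
    )
    warning(sum(bad), " malformed row(s) dropped from ", path,
            "; see attr(, 'problems')")
  }
  keep <- !bad
  df <- data.frame(female_id = raw$female_id[keep], timestamp = ts[keep],
                   dop = dp[keep], stringsAsFactors = FALSE)
  df[[need[1L]]] <- cx[keep]
  df[[need[2L]]] <- cy[keep]
  out <- as_fixes(df, coord_mode)
  attr(out, "problems") <- problems
  out
}

#' Write a fix table as delimited text
#'
#' @param fixes `np_fixes` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  df <- as.data.frame(fixes)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S")
  if (coord_mode(fixes) == "geographic") {
    names(df)[names(df) == "x"] <- "lon"
    names(df)[names(df) == "y"] <- "lat"
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove fixes with poor satellite geometry
#'
#' Drops fixes whose dilution of precision exceeds the threshold; the rule is
#' a strict inequality, so `dop == threshold` is retained.
#'
#' @param fixes `np_fixes` table.
#' @param threshold DOP cutoff (default 7).
#' @return Filtered `np_fixes`; attribute `n_removed` records the drop count.
#' @export
filter_dop <- function(fixes, threshold = 7) {
  if (any(fixes$dop < 0, na.rm = TRUE)) {
    stop("negative DOP values are invalid", call. = FALSE)
  }
  keep <- !(fixes$dop > threshold)
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coord_mode") <- coord_mode(fixes)
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(fixes)
  out
}

#' Distance between points under a pluggable metric
#'
#' Projected mode is planar Euclidean distance in metres; geographic mode is
#' great-circle (haversine) distance on a sphere of radius 6,371,000 m.
#'
#' @param a,b numeric length-2 vectors or two-column matrices (x, y) or
#'   (lon, lat). Recycled row-wise if one side has a single point.
#' @param mode `"projected"` or `"geographic"`.
#' @return distance(s) in metres.
#' @export
point_distance <- function(a, b, mode = c("projected", "geographic")) {
  mode <- match.arg(mode)
  a <- rbind_coords(a)
  b <- rbind_coords(b)
  if (mode == "projected") {
    sqrt((a[, 1L] - b[, 1L])^2 + (a[, 2L] - b[, 2L])^2)
  } else {
    geosphere::distHaversine(a, b, r = 6371000)
  }
}

rbind_coords <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 2L) else
    as.matrix(p)[, 1:2, drop = FALSE]
}

# pairwise distance matrix for a small point set, honouring the metric
pairwise_distances <- function(xy, mode = "projected") {
  xy <- rbind_coords(xy)
  if (mode == "projected") {
    as.matrix(stats::dist(xy))
  } else {
    n <- nrow(xy)
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      m[i, ] <- geosphere::distHaversine(xy[i, , drop = FALSE], xy,
                                         r = 6371000)
    }
    (m + t(m)) / 2
  }
}

# seconds since local midnight
seconds_of_day <- function(ts) {
  as.numeric(ts) %% 86400
}

#' Identify nightly (23:58:58) fixes
#'
#' The transmitter schedule records one nightly fix at 23:58:58 plus hourly
#' fixes 05:00-20:00. Real receivers drift a little, so matching uses a
#' tolerance around the nominal nightly second-of-day.
#'
#' @param fixes `np_fixes` table or POSIXct vector.
#' @param tol_s tolerance in seconds (default 300, i.e. 5 minutes).
#' @return logical vector flagging nightly fixes.
#' @export
is_nightly <- function(fixes, tol_s = 300) {
  ts <- if (inherits(fixes, "data.frame")) fixes$timestamp else fixes
  gap <- abs(seconds_of_day(ts) - .NIGHTLY_SOD)
  pmin(gap, 86400 - gap) <= tol_s   # tolerance wraps across midnight
}

# calendar date of a fix (local standard time)
fix_date <- function(ts) {
  as.Date(format(ts, "%Y-%m-%d"))
}
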
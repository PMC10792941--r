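#' Landcover raster container
#'
#' A light in-memory raster: an integer code matrix plus georeferencing.
#' Row 1 of `codes` is the southernmost row; cell centres sit at
#' `origin + (index - 0.5) * cellsize`.
#'
#' @param codes integer matrix (rows = y, cols = x).
#' @param origin numeric length-2, coordinates of the lower-left corner (m).
#' @param cellsize square cell edge length in metres.
#' @param legend named character vector mapping codes to class names.
#' @return A `landcover_raster` list.
#' @export
landcover_raster <- function(codes, origin = c(0, 0), cellsize = 30,
                             legend = default_legend()) {
  codes <- as.matrix(codes)
  if (cellsize <= 0) stop("cellsize must be positive", call. = FALSE)
  present <- unique(as.vector(codes[is.finite(codes)]))
  unknown <- setdiff(present, as.integer(names(legend)))
  if (length(unknown) > 0L) {
    stop("raster contains codes absent from the legend: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  structure(list(codes = codes, origin = as.numeric(origin),
                 cellsize = cellsize, legend = legend),
            class = "landcover_raster")
}

#' Default 6-class landcover legend
#'
#' Water, pine forest, hardwood forest, mixed pine-hardwood forest, open
#' treeless areas, and shrub/scrub, coded 1-6.
#' @return named character vector.
#' @export
default_legend <- function() {
  c(`1` = "water", `2` = "pine", `3` = "hardwood",
    `4` = "mixed", `5` = "open", `6` = "shrub")
}

#' @export
print.landcover_raster <- function(x, ...) {
  cat(sprintf("<landcover_raster> %d x %d cells @ %g m, origin (%g, %g)\n",
              nrow(x$codes), ncol(x$codes), x$cellsize,
              x$origin[1L], x$origin[2L]))
  tab <- table(factor(x$legend[as.character(x$codes)],
                      levels = unname(x$legend)))
  print(tab)
  invisible(x)
}

# cell centre coordinates
raster_xcoords <- function(r) r$origin[1L] + (seq_len(ncol(r$codes)) - 0.5) * r$cellsize
raster_ycoords <- function(r) r$origin[2L] + (seq_len(nrow(r$codes)) - 0.5) * r$cellsize

# smooth a matrix with repeated separable box filters (reflected edges)
smooth_field <- function(m, width = 9L, passes = 3L) {
  half <- width %/% 2L
  smooth_vec <- function(v) {
    padded <- c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1L]))
    out <- stats::filter(padded, rep(1 / width, width), sides = 2)
    as.numeric(out[(half + 1L):(half + length(v))])
  }
  for (p in seq_len(passes)) {
    m <- apply(m, 2L, smooth_vec)
    m <- t(apply(m, 1L, smooth_vec))
  }
  m
}

#' Generate a synthetic landcover mosaic with roads
#'
#' Landcover is a smoothed Gaussian random field thresholded by rank into the
#' six classes at the requested areal proportions, giving blob-like patches
#' at the 30-m granularity of cropland-style rasters. Roads are independent
#' polylines crossing the extent.
#'
#' @param extent numeric length-2, extent in metres (x, y).
#' @param resolution cell size in metres (default 30); must divide the extent.
#' @param class_mix six non-negative weights (normalised to sum 1) giving the
#'   areal share of water, pine, hardwood, mixed, open, shrub.
#' @param n_roads number of road polylines.
#' @param seed integer seed; the same seed yields a bit-identical landscape.
#' @return A `np_landscape` list: `$raster` (`landcover_raster`), `$roads`
#'   (list of n x 2 vertex matrices).
#' @export
generate_landscape <- function(extent = c(5010, 5010), resolution = 30,
                               class_mix = rep(1 / 6, 6), n_roads = 2,
                               seed = 1L) {
  if (any(extent <= 0) || resolution <= 0) {
    stop("extent and resolution must be positive", call. = FALSE)
  }
  if (any(abs(extent / resolution - round(extent / resolution)) > 1e-9)) {
    stop("extent must be divisible by resolution", call. = FALSE)
  }
  if (length(class_mix) != 6L || any(class_mix < 0) || sum(class_mix) <= 0) {
    stop("class_mix must be 6 non-negative weights", call. = FALSE)
  }
  w <- class_mix / sum(class_mix)
  nx <- as.integer(round(extent[1L] / resolution))
  ny <- as.integer(round(extent[2L] / resolution))
  set.seed(seed)
  # one smoothed Gaussian field per class; a cell takes the class whose
  # offset field is largest. Independent fields interleave the classes
  # (thresholding a single field would force a fixed class adjacency order
  # and strongly correlate the distance-to-class surfaces). Offsets are
  # tuned iteratively so areal shares approximate the requested mix.
  fields <- lapply(seq_len(6L), function(k) {
    f <- smooth_field(matrix(stats::rnorm(nx * ny), nrow = ny, ncol = nx))
    (f - mean(f)) / stats::sd(f)
  })
  offsets <- ifelse(w > 0, 0, -Inf)
  stack <- simplify2array(fields)          # ny x nx x 6
  for (it in seq_len(40L)) {
    shifted <- sweep(stack, 3L, offsets, `+`)
    codes <- apply(shifted, c(1L, 2L), which.max)
    shares <- tabulate(codes, 6L) / (nx * ny)
    err <- log(pmax(w, 1e-9)) - log(pmax(shares, 1 / (nx * ny)))
    if (max(abs(err[w > 0])) < 0.02) break
    offsets[w > 0] <- offsets[w > 0] + 0.3 * err[w > 0]
  }
  codes <- matrix(as.integer(codes), nrow = ny, ncol = nx)
  roads <- lapply(seq_len(n_roads), function(i) {
    horizontal <- stats::runif(1) < 0.5
    n_vertex <- 6L
    along <- seq(0, 1, length.out = n_vertex)
    base <- stats::runif(1, 0.2, 0.8)
    lateral <- base + cumsum(c(0, stats::rnorm(n_vertex - 1L, 0, 0.05)))
    lateral <- pmin(pmax(lateral, 0.02), 0.98)
    if (horizontal) {
      cbind(x = along * extent[1L], y = lateral * extent[2L])
    } else {
      cbind(x = lateral * extent[1L], y = along * extent[2L])
    }
  })
  structure(list(raster = landcover_raster(codes, origin = c(0, 0),
                                           cellsize = resolution),
                 roads = roads),
            class = "np_landscape")
}

#' @export
print.np_landscape <- function(x, ...) {
  print(x$raster)
  cat(sprintf("  %d road polyline(s)\n", length(x$roads)))
  invisible(x)
}

#' Write / read a landcover raster as Arc/Info ASCII grid plus JSON legend
#'
#' The grid is written top row first, per the ASCII-grid convention; the
#' legend goes to `<path>.legend.json`.
#'
#' @param raster `landcover_raster`.
#' @param path output path (conventionally `.asc`).
#' @return `path` invisibly (`write_ascii_grid`); a `landcover_raster`
#'   (`read_ascii_grid`).
#' @export
write_ascii_grid <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("ncols %d", ncol(raster$codes)),
           sprintf("nrows %d", nrow(raster$codes)),
           sprintf("xllcorner %.6f", raster$origin[1L]),
           sprintf("yllcorner %.6f", raster$origin[2L]),
           sprintf("cellsize %.6f", raster$cellsize),
           "NODATA_value -9999")
  writeLines(hdr, con)
  for (i in rev(seq_len(nrow(raster$codes)))) {
    writeLines(paste(raster$codes[i, ], collapse = " "), con)
  }
  jsonlite::write_json(as.list(raster$legend),
                       paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  vals <- vapply(hdr, function(h) as.numeric(h[2L]), numeric(1))
  names(vals) <- vapply(hdr, `[[`, character(1), 1L)
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  body <- lines[-(1:6)]
  rows <- lapply(body, function(l) as.integer(strsplit(trimws(l), "\\s+")[[1L]]))
  codes <- do.call(rbind, rev(rows))
  legend_path <- paste0(path, ".legend.json")
  legend <- if (file.exists(legend_path)) {
    unlist(jsonlite::read_json(legend_path))
  } else default_legend()
  landcover_raster(codes, origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
                   cellsize = vals[["cellsize"]], legend = legend)
}

#' Write roads as GeoJSON LineStrings
#'
#' @param roads list of n x 2 vertex matrices.
#' @param path output path.
#' @return `path` invisibly (write); list of matrices (read).
#' @export
write_roads_geojson <- function(roads, path) {
  features <- lapply(seq_along(roads), function(i) {
    coords <- lapply(seq_len(nrow(roads[[i]])), function(j)
      as.numeric(roads[[i]][j, 1:2]))
    list(type = "Feature",
         properties = list(road_id = i),
         geometry = list(type = "LineString", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roads_geojson
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    do.call(rbind, lapply(f$geometry$coordinates, function(c2)
      c(x = as.numeric(c2[[1L]]), y = as.numeric(c2[[2L]]))))
  })
}
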
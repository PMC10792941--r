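#' Reclassify a landcover raster
#'
#' Applies a surjective code mapping (e.g. collapsing a many-class cropland
#' legend onto the six analysis classes). Cell count is preserved; every raw
#' code must be covered by the mapping.
#'
#' @param raster `landcover_raster`.
#' @param mapping named integer vector: names are raw codes, values are
#'   target codes (1-6 under the default legend).
#' @param legend legend for the output raster.
#' @return reclassified `landcover_raster`.
#' @export
reclass_landcover <- function(raster, mapping, legend = default_legend()) {
  codes <- raster$codes
  present <- unique(as.vector(codes))
  unmapped <- setdiff(present, as.integer(names(mapping)))
  if (length(unmapped) > 0L) {
    stop("unmapped landcover code(s): ", paste(sort(unmapped), collapse = ", "),
         call. = FALSE)
  }
  new_codes <- matrix(as.integer(mapping[as.character(codes)]),
                      nrow = nrow(codes), ncol = ncol(codes))
  landcover_raster(new_codes, origin = raster$origin,
                   cellsize = raster$cellsize, legend = legend)
}

# Felzenszwalb & Huttenlocher 1-D squared distance transform (lower envelope
# of parabolas); `f` holds 0 at sources and a large sentinel elsewhere
.EDT_BIG <- 1e12
edt_1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (k > 1L && s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# exact 2-D squared EDT in cell units via two separable passes
edt_2d <- function(mask) {
  f <- ifelse(mask, 0, .EDT_BIG)
  g <- t(apply(f, 1L, edt_1d))
  apply(g, 2L, edt_1d)
}

#' Distance-to-feature surface
#'
#' Builds a grid whose cells hold the Euclidean distance (metres, cell
#' centre to cell centre) from each cell to the nearest cell of a landcover
#' class, or the nearest point on a road polyline. Class distances use an
#' exact separable Euclidean distance transform; road distances are exact
#' point-to-segment computations.
#'
#' @param raster `landcover_raster`.
#' @param target class code (1-6), class name (e.g. `"water"`), or a list of
#'   road vertex matrices.
#' @return surface of class `np_surface`: list with `values` matrix,
#'   `origin`, `cellsize`. If the target class is absent from the extent the
#'   surface is all `Inf` with a warning.
#' @export
distance_surface <- function(raster, target) {
  if (is.list(target)) return(road_distance_surface(raster, target))
  code <- if (is.character(target)) {
    m <- match(target, raster$legend)
    if (is.na(m)) stop("unknown class name: ", target, call. = FALSE)
    as.integer(names(raster$legend)[m])
  } else as.integer(target)
  mask <- raster$codes == code
  if (!any(mask)) {
    warning("target class ", target, " absent from extent; all-Inf surface")
    vals <- matrix(Inf, nrow(raster$codes), ncol(raster$codes))
  } else {
    d2 <- edt_2d(mask)
    vals <- sqrt(d2) * raster$cellsize
  }
  structure(list(values = vals, origin = raster$origin,
                 cellsize = raster$cellsize),
            class = "np_surface")
}

point_segment_distance <- function(px, py, a, b) {
  vx <- b[1L] - a[1L]; vy <- b[2L] - a[2L]
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(pmax(((px - a[1L]) * vx + (py - a[2L]) * vy) / len2, 0), 1)
  sqrt((px - (a[1L] + t * vx))^2 + (py - (a[2L] + t * vy))^2)
}

road_distance_surface <- function(raster, roads) {
  xc <- raster_xcoords(raster); yc <- raster_ycoords(raster)
  px <- rep(xc, each = length(yc)); py <- rep(yc, length(xc))
  best <- rep(Inf, length(px))
  for (road in roads) {
    for (s in seq_len(nrow(road) - 1L)) {
      best <- pmin(best, point_segment_distance(px, py, road[s, 1:2],
                                                road[s + 1L, 1:2]))
    }
  }
  structure(list(values = matrix(best, nrow = length(yc), ncol = length(xc)),
                 origin = raster$origin, cellsize = raster$cellsize),
            class = "np_surface")
}

#' Build the full covariate surface stack for a landscape
#'
#' One distance surface per landcover class plus distance to roads.
#'
#' @param landscape `np_landscape`.
#' @return named list of `np_surface` objects (`dist_water` ... `dist_shrub`,
#'   `dist_road`).
#' @export
covariate_surfaces <- function(landscape) {
  r <- landscape$raster
  out <- lapply(as.integer(names(r$legend)), function(code)
    distance_surface(r, code))
  names(out) <- paste0("dist_", unname(r$legend))
  out$dist_road <- road_distance_surface(r, landscape$roads)
  out
}

# (row, col) of the cell containing each point; NA outside the extent
cell_index <- function(surface, xy) {
  xy <- rbind_coords(xy)
  col <- floor((xy[, 1L] - surface$origin[1L]) / surface$cellsize) + 1L
  row <- floor((xy[, 2L] - surface$origin[2L]) / surface$cellsize) + 1L
  bad <- col < 1L | col > ncol(surface$values) |
    row < 1L | row > nrow(surface$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Extract covariates at points
#'
#' Looks up each distance surface at the cell containing the point (no
#' interpolation) and computes the distance to the nest directly
#' point-to-point. Points outside the raster extent yield `NA` covariates
#' and a row in the `problems` attribute rather than an error. Inputs are
#' planar metres; project geographic points first.
#'
#' @param points data.frame or matrix with `x`, `y` (metres).
#' @param surfaces named list of `np_surface` (see [covariate_surfaces()]).
#' @param nest_xy nest coordinates (metres); omit with `NULL` to skip
#'   `dist_nest`.
#' @return data.frame with `dist_nest` (when requested) and one column per
#'   surface.
#' @export
extract_covariates <- function(points, surfaces, nest_xy = NULL) {
  xy <- rbind_coords(if (is.data.frame(points)) cbind(points$x, points$y)
                     else points)
  out <- data.frame(row.names = seq_len(nrow(xy)))
  if (!is.null(nest_xy)) {
    out$dist_nest <- point_distance(xy, nest_xy, "projected")
  }
  idx <- cell_index(surfaces[[1L]], xy)
  outside <- is.na(idx[, 1L])
  for (nm in names(surfaces)) {
    v <- rep(NA_real_, nrow(xy))
    v[!outside] <- surfaces[[nm]]$values[idx[!outside, , drop = FALSE]]
    out[[nm]] <- v
  }
  if (any(outside)) {
    attr(out, "problems") <- data.frame(
      point = which(outside), reason = "outside raster extent")
  }
  out
}

# inverse of the local equirectangular projection used by the generator
lonlat_to_xy <- function(lonlat, ref_lonlat) {
  R <- 6371000
  p <- rbind_coords(lonlat)
  lat0 <- ref_lonlat[2L] * pi / 180
  cbind(x = (p[, 1L] - ref_lonlat[1L]) * pi / 180 * R * cos(lat0),
        y = (p[, 2L] - ref_lonlat[2L]) * pi / 180 * R)
}
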
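# Independent brute-force oracles and small simulators used across tests.

# union-find single-linkage partition over all pairwise distances
bf_single_linkage <- function(xy, radius) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      if (d <= radius) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# all-pairs revisit counting: nearest centroid, hit iff distance <= radius
bf_revisits <- function(centroids, pts, radius) {
  assign_id <- rep(NA_integer_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((centroids[, 1L] - pts[i, 1L])^2 +
                (centroids[, 2L] - pts[i, 2L])^2)
    j <- which.min(d)
    if (d[j] <= radius) assign_id[i] <- j
  }
  list(assign = assign_id,
       counts = tabulate(assign_id, nbins = nrow(centroids)))
}

# noisy 2-D Brownian motion observed at regular intervals
sim_brownian_track <- function(sigma2, n, dt, err, seed) {
  set.seed(seed)
  steps <- matrix(rnorm(2L * (n - 1L), 0, sqrt(sigma2 * dt)), n - 1L, 2L)
  xy <- rbind(c(0, 0), apply(steps, 2L, cumsum))
  list(xy = xy + matrix(rnorm(2L * n, 0, err), n, 2L),
       t = (0:(n - 1L)) * dt)
}

# minimal projected fix table
make_fixes <- function(x, y, start = "2021-04-01 06:00:00", by = 3600,
                       female = "F1", dop = 1) {
  n <- length(x)
  as_fixes(data.frame(
    female_id = female,
    timestamp = as.POSIXct(start, tz = "UTC") + by * (seq_len(n) - 1L),
    x = x, y = y, dop = dop), "projected")
}

# shared small landscape for tests that need one (built once per run)
test_landscape <- local({
  ls_cache <- NULL
  function() {
    if (is.null(ls_cache)) ls_cache <<- generate_landscape(seed = 99L)
    ls_cache
  }
})
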
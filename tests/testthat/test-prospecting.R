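test_that("recess classification is a strict inequality at 27.5 m", {
  fx <- make_fixes(c(27.5, 27.6, 0), c(0, 0, 0))
  rec <- classify_recesses(fx, c(0, 0))
  expect_equal(rec$is_recess, c(FALSE, TRUE, FALSE))
  expect_equal(rec$distance_to_nest, c(27.5, 27.6, 0))
})

test_that("classification requires a nest", {
  expect_error(classify_recesses(make_fixes(1, 1), NULL), "nest_xy")
  expect_error(classify_recesses(make_fixes(1, 1), c(NA, 1)), "nest_xy")
})

test_that("generated recesses are recovered exactly at zero noise", {
  cfg <- sim_config(gps_noise_sd = 0, laying_days = 4, incubation_days = 20)
  att <- generate_attempt(cfg, test_landscape(), seed = 55)
  inc <- incubation_fixes(att$fixes, att$truth$incubation_onset,
                          att$truth$incubation_end)
  rec <- classify_recesses(inc, att$truth$nest_m)
  lab <- att$truth$labels[att$fixes$timestamp %in% inc$timestamp]
  expect_equal(sum(rec$is_recess), sum(lab == "recess"))
})

test_that("one laying fix yields one singleton CLP at itself", {
  clps <- cluster_laying_locations(data.frame(x = 12, y = -5))
  expect_equal(nrow(clps$clps), 1L)
  expect_equal(c(clps$clps$x, clps$clps$y), c(12, -5))
  expect_equal(clps$clps$n_members, 1L)
})

test_that("the 150-m linkage boundary is inclusive", {
  two <- function(d) nrow(cluster_laying_locations(
    data.frame(x = c(0, d), y = 0))$clps)
  expect_equal(two(150.0), 1L)
  expect_equal(two(150.1), 2L)
})

test_that("clp ids follow the earliest member timestamp", {
  # second visited area appears first in space but later in time
  fx <- make_fixes(c(0, 10, 1000, 1010, 5), c(0, 0, 0, 0, 5))
  clps <- cluster_laying_locations(fx)
  expect_equal(nrow(clps$clps), 2L)
  expect_equal(clps$membership, c(1L, 1L, 2L, 2L, 1L))
  expect_lt(clps$clps$x[1], clps$clps$x[2])
})

test_that("single-linkage clustering matches the union-find oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    xy <- cbind(runif(n, 0, 2000), runif(n, 0, 2000))
    fx <- data.frame(x = xy[, 1], y = xy[, 2])
    got <- cluster_laying_locations(fx, 150)$membership
    want <- bf_single_linkage(xy, 150)
    # same partition up to relabelling
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("revisit buffer boundary is inclusive and ties go to the lower
           clp id", {
  clps <- cluster_laying_locations(
    make_fixes(c(0, 1000), c(0, 0)))
  rec45 <- data.frame(x = 45, y = 0, is_recess = TRUE)
  rv <- count_revisits(clps, rec45, 45)
  expect_equal(rv$recesses$clp_id, 1L)
  expect_equal(rv$clps$clps$visit_count, c(1L, 0L))
  # equidistant 30 m from both centroids: counted once, lower id wins
  clps2 <- cluster_laying_locations(make_fixes(c(0, 60), c(0, 0)))
  expect_equal(nrow(clps2$clps), 1L)  # 60 m apart merges at 150-m linkage
  clps2 <- cluster_laying_locations(make_fixes(c(0, 600), c(0, 0)))
  mid <- data.frame(x = 300, y = 0, is_recess = TRUE)
  rv2 <- count_revisits(clps2, mid, 300)
  expect_equal(rv2$recesses$clp_id, 1L)
  expect_equal(sum(rv2$clps$clps$visit_count), 1L)
})

test_that("non-recess fixes are never assigned to a CLP", {
  clps <- cluster_laying_locations(make_fixes(0, 0))
  rec <- data.frame(x = c(10, 10), y = 0, is_recess = c(FALSE, TRUE))
  rv <- count_revisits(clps, rec, 45)
  expect_equal(rv$recesses$clp_id, c(NA_integer_, 1L))
})

test_that("empty CLP set gives zero counts, no assignments", {
  clps <- cluster_laying_locations(make_fixes(0, 0))
  clps$clps <- clps$clps[0, ]
  rec <- data.frame(x = 1:3, y = 0, is_recess = TRUE)
  rv <- count_revisits(clps, rec, 45)
  expect_true(all(is.na(rv$recesses$clp_id)))
})

test_that("revisit counting matches the brute-force oracle", {
  set.seed(77)
  for (rep in 1:10) {
    n_clp <- sample(5:20, 1); n_rec <- sample(50:500, 1)
    cent <- cbind(runif(n_clp, 0, 3000), runif(n_clp, 0, 3000))
    pts <- cbind(runif(n_rec, 0, 3000), runif(n_rec, 0, 3000))
    clps <- structure(list(
      clps = data.frame(clp_id = seq_len(n_clp), x = cent[, 1],
                        y = cent[, 2], n_members = 1L, visit_count = 0L),
      membership = seq_len(n_clp), coord_mode = "projected"),
      class = "np_clps")
    rec <- data.frame(x = pts[, 1], y = pts[, 2], is_recess = TRUE)
    rv <- count_revisits(clps, rec, 45)
    want <- bf_revisits(cent, pts, 45)
    expect_equal(rv$recesses$clp_id, want$assign)
    expect_equal(rv$clps$clps$visit_count, want$counts)
  }
})

test_that("prospecting summary handles the empty and saturated cases", {
  clps <- cluster_laying_locations(make_fixes(0, 0))
  none <- data.frame(x = numeric(), y = numeric(), is_recess = logical(),
                     clp_id = integer())
  s0 <- summarize_prospecting("a0", clps, none)
  expect_equal(s0$proportion_to_clp, 0)
  expect_equal(s0$n_clp_visited, 0L)
  # 40 recesses, all inside buffers, 5 of 9 CLPs touched
  cent <- make_fixes(seq(0, 8) * 1000, rep(0, 9))
  clps9 <- cluster_laying_locations(cent)
  rec <- data.frame(x = rep(seq(0, 4) * 1000, each = 8), y = 10,
                    is_recess = TRUE)
  rv <- count_revisits(clps9, rec, 45)
  s <- summarize_prospecting("a1", rv$clps, rv$recesses)
  expect_equal(s$total_recesses, 40L)
  expect_equal(s$proportion_to_clp, 1.0)
  expect_equal(s$n_clp_visited, 5L)
  expect_equal(s$n_clp_total, 9L)
})

test_that("summaries are invariant under translation", {
  cfg <- sim_config(laying_days = 4, incubation_days = 10)
  att <- generate_attempt(cfg, test_landscape(), seed = 13)
  run <- function(shift) {
    fx <- att$fixes; fx$x <- fx$x + shift[1]; fx$y <- fx$y + shift[2]
    nest <- att$truth$nest_m + shift
    lay <- laying_fixes(fx, att$truth$laying_onset,
                        att$truth$incubation_onset)
    inc <- incubation_fixes(fx, att$truth$incubation_onset,
                            att$truth$incubation_end)
    rv <- count_revisits(cluster_laying_locations(lay),
                         classify_recesses(inc, nest))
    summarize_prospecting("a", rv$clps, rv$recesses)
  }
  expect_equal(run(c(0, 0)), run(c(12345.6, -9876.5)))
})

test_that("proportion and visits are monotone in the buffer radius;
           patch count is monotone in the linkage radius", {
  cfg <- sim_config(laying_days = 6, incubation_days = 15)
  att <- generate_attempt(cfg, test_landscape(), seed = 17)
  lay <- laying_fixes(att$fixes, att$truth$laying_onset,
                      att$truth$incubation_onset)
  inc <- incubation_fixes(att$fixes, att$truth$incubation_onset,
                          att$truth$incubation_end)
  rec <- classify_recesses(inc, att$truth$nest_m)
  clps <- cluster_laying_locations(lay)
  props <- vapply(c(15, 45, 75, 150), function(r) {
    rv <- count_revisits(clps, rec, r)
    s <- summarize_prospecting("a", rv$clps, rv$recesses)
    s$proportion_to_clp
  }, numeric(1))
  expect_true(all(diff(props) >= 0))
  n_clp <- vapply(c(50, 150, 300, 1000), function(r) {
    nrow(cluster_laying_locations(lay, r)$clps)
  }, numeric(1))
  expect_true(all(diff(n_clp) <= 0))
})

test_that("CLPs export as GeoJSON point features", {
  clps <- cluster_laying_locations(make_fixes(c(0, 500), c(0, 0)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_clps_geojson(clps, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 2L)
  expect_equal(gj$features[[1]]$geometry$type, "Point")
})
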
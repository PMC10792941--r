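test_that("sim_config validates its invariants", {
  expect_error(sim_config(p_revisit = 1.2), "p_revisit")
  expect_error(sim_config(n_females = 0), "counts")
  expect_error(sim_config(gps_noise_sd = -1), "gps_noise_sd")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("landscape grid arithmetic and determinism hold", {
  ls1 <- generate_landscape(extent = c(3000, 3000), resolution = 30,
                            seed = 5)
  expect_equal(dim(ls1$raster$codes), c(100L, 100L))
  expect_equal(length(ls1$raster$codes), 10000L)
  ls2 <- generate_landscape(extent = c(3000, 3000), resolution = 30,
                            seed = 5)
  expect_identical(ls1$raster$codes, ls2$raster$codes)
  expect_error(generate_landscape(extent = c(-10, 100)), "positive")
  expect_error(generate_landscape(extent = c(100, 100), resolution = 33),
               "divisible")
})

test_that("degenerate class mix yields a single-class raster with zero
           distance everywhere", {
  ls1 <- generate_landscape(extent = c(900, 900), resolution = 30,
                            class_mix = c(0, 1, 0, 0, 0, 0), seed = 1)
  expect_true(all(ls1$raster$codes == 2L))
  surf <- distance_surface(ls1$raster, "pine")
  expect_true(all(surf$values == 0))
})

test_that("class mix weights control areal shares", {
  ls1 <- generate_landscape(extent = c(3000, 3000), resolution = 30,
                            class_mix = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1),
                            seed = 3)
  shares <- tabulate(ls1$raster$codes, 6) / 10000
  expect_equal(shares[1], 0.5, tolerance = 0.01)
})

test_that("attempt fix count matches the enumerated schedule", {
  # schedule per day: hourly 05:00..20:00 (16) + nightly 23:58:58 (1)
  n_per_day <- length(seq(5, 20)) + 1L
  cfg <- sim_config(laying_days = 12, incubation_days = 28)
  att <- generate_attempt(cfg, test_landscape(), seed = 2)
  expect_equal(nrow(att$fixes), (12 + 28) * n_per_day)
  expect_equal(nrow(att$fixes), 680L)
})

test_that("every generated timestamp is on the transmitter schedule", {
  cfg <- sim_config(laying_days = 3, incubation_days = 4)
  att <- generate_attempt(cfg, test_landscape(), seed = 8)
  sod <- as.numeric(att$fixes$timestamp) %% 86400
  hourly <- sod %% 3600 == 0 & sod >= 5 * 3600 & sod <= 20 * 3600
  nightly <- sod == 23 * 3600 + 58 * 60 + 58
  expect_true(all(hourly | nightly))
})

test_that("zero-noise geometry matches the behavioural labels exactly", {
  cfg <- sim_config(gps_noise_sd = 0, laying_days = 5, incubation_days = 10)
  att <- generate_attempt(cfg, test_landscape(), seed = 4)
  d_nest <- point_distance(cbind(att$fixes$x, att$fixes$y),
                           att$truth$nest_m, "projected")
  expect_true(all(d_nest[att$truth$labels == "on-nest"] == 0))
  expect_true(all(d_nest[att$truth$labels == "recess"] > 27.5))
  expect_true(all(d_nest[att$truth$labels == "nest-visit"] < 20))
  # labels partition all fixes
  expect_true(all(att$truth$labels %in%
                    c("laying-forage", "nest-visit", "on-nest", "recess")))
  expect_equal(length(att$truth$labels), nrow(att$fixes))
})

test_that("no recesses and no noise pin every incubation fix to the nest", {
  cfg <- sim_config(gps_noise_sd = 0, recesses_per_day = 0,
                    laying_days = 2, incubation_days = 5)
  att <- generate_attempt(cfg, test_landscape(), seed = 6)
  inc <- incubation_fixes(att$fixes, att$truth$incubation_onset,
                          att$truth$incubation_end)
  expect_true(all(inc$x == att$truth$nest_m[1]))
  expect_true(all(inc$y == att$truth$nest_m[2]))
})

test_that("p_revisit = 1 sends every recess to a laying patch", {
  cfg <- sim_config(p_revisit = 1, gps_noise_sd = 0, laying_days = 3,
                    incubation_days = 10)
  att <- generate_attempt(cfg, test_landscape(), seed = 7)
  rec <- att$truth$labels == "recess"
  expect_gt(sum(rec), 0)
  expect_true(all(!is.na(att$truth$recess_target[rec])))
  expect_equal(att$truth$proportion_to_patch, 1)
})

test_that("recess targets lie within the patch radius before noise", {
  cfg <- sim_config(gps_noise_sd = 0, laying_days = 2, incubation_days = 15)
  att <- generate_attempt(cfg, test_landscape(), seed = 11)
  tgt <- att$truth$recess_target
  hit <- which(!is.na(tgt))
  for (i in hit) {
    d <- point_distance(c(att$fixes$x[i], att$fixes$y[i]),
                        att$truth$patch_centers[tgt[i], ], "projected")
    expect_lte(d, cfg$patch_radius)
  }
})

test_that("the generator is reproducible from (cfg, seed)", {
  cfg <- sim_config(laying_days = 2, incubation_days = 3)
  a1 <- generate_attempt(cfg, test_landscape(), seed = 123)
  a2 <- generate_attempt(cfg, test_landscape(), seed = 123)
  expect_identical(as.data.frame(a1$fixes), as.data.frame(a2$fixes))
  expect_identical(a1$truth, a2$truth)
})

test_that("geographic mode emits lon/lat consistent with the projection", {
  cfg <- sim_config(coord_mode = "geographic", laying_days = 2,
                    incubation_days = 3, gps_noise_sd = 0)
  att <- generate_attempt(cfg, test_landscape(), seed = 5)
  expect_equal(coord_mode(att$fixes), "geographic")
  # haversine distance between on-nest fixes and the emitted nest is ~0
  inc <- incubation_fixes(att$fixes, att$truth$incubation_onset,
                          att$truth$incubation_end)
  on_nest <- inc[is_nightly(inc), ]
  d <- point_distance(cbind(on_nest$x, on_nest$y), att$truth$nest,
                      "geographic")
  expect_true(all(d < 0.1))
})

test_that("null fate model produces a balanced success rate", {
  cfg <- sim_config(fate_intercept = 0, fate_beta_prop = 0,
                    fate_beta_nclp = 0, random_intercept_sd = 0)
  tc <- data.frame(female_id = sprintf("F%04d", 1:2000),
                   proportion_to_patch = runif(2000),
                   n_patches_visited = rpois(2000, 5))
  fates <- simulate_fates(tc, cfg, seed = 1)
  # exact binomial 99.9% interval around 0.5 at n = 2000
  expect_gt(mean(fates$fate01), 0.5 - 3.3 * sqrt(0.25 / 2000))
  expect_lt(mean(fates$fate01), 0.5 + 3.3 * sqrt(0.25 / 2000))
})

test_that("a saturating intercept forces universal success", {
  cfg <- sim_config(fate_intercept = 50, fate_beta_prop = 0,
                    fate_beta_nclp = 0, random_intercept_sd = 0)
  tc <- data.frame(female_id = sprintf("F%03d", 1:100),
                   proportion_to_patch = runif(100),
                   n_patches_visited = rpois(100, 5))
  expect_true(all(simulate_fates(tc, cfg, seed = 2)$fate01 == 1L))
})

test_that("fate probabilities match the closed-form logistic", {
  # covariate alternating -1/+1: standardised value is ~+1 for the high group
  cfg <- sim_config(fate_intercept = 0, fate_beta_prop = 0,
                    fate_beta_nclp = 1, random_intercept_sd = 0)
  n <- 4000
  tc <- data.frame(female_id = sprintf("F%05d", 1:n),
                   proportion_to_patch = 0.5,
                   n_patches_visited = rep(c(-1, 1), n / 2))
  fates <- simulate_fates(tc, cfg, seed = 3)
  hi <- fates$fate01[tc$n_patches_visited == 1]
  p_theory <- plogis(1)  # 0.7311 at one standardised unit
  expect_equal(unique(round(fates$p_success[tc$n_patches_visited == 1], 3)),
               round(plogis(1 / sd(tc$n_patches_visited)), 3))
  expect_lt(abs(mean(hi) - p_theory), 3.3 * sqrt(p_theory * (1 - p_theory) /
                                                   length(hi)) + 0.001)
})

test_that("non-finite covariates are a data error", {
  cfg <- sim_config()
  tc <- data.frame(female_id = c("A", "B"), proportion_to_patch = c(0.5, NA),
                   n_patches_visited = c(3, 4))
  expect_error(simulate_fates(tc, cfg), "non-finite")
})

test_that("simulate_population shares the female random effect across
           renesting attempts", {
  cfg <- sim_config(n_females = 3, attempts_per_female = 2, laying_days = 3,
                    incubation_days = 5, seed = 21)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$truth_table), 6L)
  b <- tapply(pop$truth_table$b_female, pop$truth_table$female_id,
              function(v) length(unique(v)))
  expect_true(all(b == 1L))
  # attempts ordered, non-overlapping
  for (f in unique(pop$truth_table$female_id)) {
    tt <- pop$truth_table[pop$truth_table$female_id == f, ]
    expect_true(tt$incubation_end[1] <= tt$laying_onset[2])
  }
})

test_that("truth JSON serialises and parses", {
  cfg <- sim_config(laying_days = 2, incubation_days = 3)
  att <- generate_attempt(cfg, test_landscape(), seed = 31)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(att$truth, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$female_id, att$truth$female_id)
  expect_equal(as.Date(back$incubation_onset), att$truth$incubation_onset)
  expect_equal(length(back$labels), nrow(att$fixes))
})
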
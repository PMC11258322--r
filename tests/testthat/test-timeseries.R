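# Incremental strain series, accumulation, depth-time maps, difference curves.

test_that("identical frames give zero strain maps; unordered timestamps error", {
  cfg <- small_config(seed = 41)
  v <- make_cornea_phantom(cfg)
  frames <- lapply(0:3, function(k) { f <- v; f$timestamp <- k * 60; f })
  maps <- incremental_strain_series(frames)
  expect_length(maps, 3L)
  for (m in maps) expect_lt(max(abs(m$data[m$valid])), 1e-12)
  frames[[2]]$timestamp <- 500
  expect_error(incremental_strain_series(frames), "increasing")
  expect_error(incremental_strain_series(frames[1]), "two frames")
})

test_that("constant-rate increments match the ground-truth rate", {
  cfg <- small_config(n_z = 64, n_x = 32, corneal_thickness = 40 * 4.48,
                      seed = 42)
  r <- 1.5e-3
  sc <- deformation_scenario("const", duration = 6, frame_interval = 60,
                             rate_profile = function(d, t) rep(r, length(d)))
  p <- processing_params(delta = cfg$delta * 1e-6)
  sim <- simulate_timeseries(cfg, sc, p, keep_fields = FALSE)
  surf <- surfaces_from_config(cfg)
  maps <- incremental_strain_series(sim$frames, p)
  for (m in maps) {
    expect_true(attr(m, "pair_valid"))
    # interior regional mean tracks the imposed increment (band away from
    # both boundaries to avoid window-edge attenuation)
    zi <- (surf$anterior[1, 1] + 8):(surf$posterior[1, 1] - 8)
    vals <- m$data[zi, , 2][m$valid[zi, , 2]]
    expect_equal(mean(vals), r * 1, tolerance = 0.02)
  }
})

test_that("a dropout frame invalidates exactly its two adjacent pairs", {
  cfg <- small_config(seed = 43, snr_db = 25)
  sc <- deformation_scenario("drop", duration = 8, frame_interval = 60,
                             rate_profile = function(d, t) rep(5e-4, length(d)),
                             dropout_period = 4, dropout_duration = 1L)
  p <- processing_params(delta = cfg$delta * 1e-6)
  sim <- simulate_timeseries(cfg, sc, p, keep_fields = FALSE)
  maps <- incremental_strain_series(sim$frames, p)
  pv <- vapply(maps, function(m) isTRUE(attr(m, "pair_valid")), logical(1))
  # dropout frames at t = 4 and t = 8 min (indices 5 and 9): pairs (4,5),
  # (5,6), (8,9) are invalid; pair (8,9) is the last one
  expect_equal(which(!pv), c(4L, 5L, 8L))
})

test_that("accumulation arithmetic, invalid handling, and additivity", {
  # constant increment s over k pairs -> cum = 100 * k * s
  s <- 2e-4
  cv <- accumulate_strain(rep(s, 10), t_min = 1:10)
  expect_equal(cv$cum_strain, 100 * s * (1:10))
  # all-zero increments -> flat zero curve
  expect_true(all(accumulate_strain(rep(0, 5), t_min = 1:5)$cum_strain == 0))
  # invalid increments contribute zero but stay recorded
  inc <- c(1e-3, 2e-3, 5e-3, 1e-3)
  ok <- c(TRUE, TRUE, FALSE, TRUE)
  cv <- accumulate_strain(inc, ok, t_min = 1:4)
  expect_equal(cv$cum_strain[4], 100 * sum(inc[ok]))
  expect_equal(cv$increment, inc)
  # additivity: accumulating [0,T] equals accumulate [0,t] + accumulate (t,T]
  set.seed(44)
  inc <- rnorm(20, 1e-3, 5e-4)
  ok <- runif(20) > 0.2
  full <- accumulate_strain(inc, ok, t_min = 1:20)
  first <- accumulate_strain(inc[1:8], ok[1:8], t_min = 1:8)
  second <- accumulate_strain(inc[9:20], ok[9:20], t_min = 9:20)
  expect_equal(full$cum_strain[20],
               first$cum_strain[8] + second$cum_strain[12])
  expect_error(accumulate_strain(inc, ok, t_min = rep(1, 20)), "increasing")
})

test_that("noiseless linear scenario gives an R^2 > 0.999 cumulative curve", {
  cfg <- small_config(n_z = 64, corneal_thickness = 40 * 4.48, seed = 45)
  sc <- deformation_scenario("lin", duration = 20, frame_interval = 60,
                             rate_profile = function(d, t) rep(1e-3, length(d)))
  p <- processing_params(delta = cfg$delta * 1e-6)
  sim <- simulate_timeseries(cfg, sc, p, keep_fields = FALSE)
  cv <- strain_curve(sim$frames, surfaces_from_config(cfg),
                     region_spec(band = "anterior", band_depth = 100),
                     p)
  fit <- stats::lm(cum_strain ~ t, data = cv)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999)
})

test_that("depth-time map confines cxl shrinkage to the anterior band after onset", {
  cfg <- phantom_config(n_z = 72, n_x = 32, n_y = 3, delta = 16, pitch_x = 12,
                        pitch_y = 120, anterior_apex_depth = 100,
                        corneal_thickness = 800, snr_db = 25, seed = 46)
  p <- processing_params(delta = 16e-6)
  frac <- 200 / cfg$corneal_thickness
  sc <- deformation_scenario("cxl_like", duration = 40, frame_interval = 120,
                             rate_profile = function(d, t) {
                               if (t < 20) rep(1e-3, length(d))
                               else ifelse(d <= frac, -1e-3, 1e-3)
                             },
                             onset_time = 20, affected_depth = 200)
  sim <- simulate_timeseries(cfg, sc, p, keep_fields = FALSE)
  maps <- incremental_strain_series(sim$frames, p)
  dtm <- depth_time_map(maps, lateral_halfwidth_x = 224, pitch_x_um = 12)
  surf <- surfaces_from_config(cfg)
  a <- round(mean(surf$anterior)); b <- round(mean(surf$posterior))
  aff_px <- round(frac * (b - a))
  margin <- 2 * p$w_z + 1  # strain-map axial resolution
  ant_rows <- (a + 2):(a + aff_px - 2)
  post_rows <- (a + aff_px + margin):(b - 2)
  pre <- dtm$t_min < 19
  post <- dtm$t_min > 22
  expect_gt(mean(dtm$M[ant_rows, pre], na.rm = TRUE), 0)
  expect_lt(mean(dtm$M[ant_rows, post], na.rm = TRUE), 0)
  expect_gt(mean(dtm$M[post_rows, post], na.rm = TRUE), 0)
  # uniform-in-time pre-onset columns agree with each other
  col_means <- colMeans(dtm$M[(a + 2):(b - 2), pre], na.rm = TRUE)
  expect_lt(stats::sd(col_means) / mean(col_means), 0.2)
})

test_that("dropout pairs appear as masked columns in the depth-time map", {
  cfg <- small_config(seed = 47, snr_db = 25)
  sc <- deformation_scenario("drop", duration = 8, frame_interval = 60,
                             rate_profile = function(d, t) rep(5e-4, length(d)),
                             dropout_period = 4, dropout_duration = 1L)
  p <- processing_params(delta = cfg$delta * 1e-6)
  sim <- simulate_timeseries(cfg, sc, p, keep_fields = FALSE)
  maps <- incremental_strain_series(sim$frames, p)
  dtm <- depth_time_map(maps, 224, 12)
  expect_equal(which(!dtm$pair_valid), c(4L, 5L, 8L))
  expect_true(all(is.na(dtm$M[, !dtm$pair_valid])))
  expect_true(all(colSums(!is.na(dtm$M[, dtm$pair_valid])) > 0))
})

test_that("difference curves subtract on a common grid", {
  a <- accumulate_strain(rep(1e-3, 10), t_min = 1:10, label = "cxl")
  # identical curves -> identically zero
  dz <- difference_curve(a, a)
  expect_true(all(abs(dz$cum_strain) < 1e-12))
  # different grids: linear interpolation, endpoint values preserved at
  # shared nodes
  b <- accumulate_strain(rep(2e-3, 5), t_min = seq(2, 10, 2), label = "ctrl")
  d <- difference_curve(a, b)
  expect_equal(min(d$t), 2)
  expect_equal(max(d$t), 10)
  shared <- d$t %in% b$t
  expect_equal(d$cum_strain[d$t == 10],
               a$cum_strain[a$t == 10] - b$cum_strain[b$t == 10])
  # disjoint ranges are an input error
  c2 <- accumulate_strain(rep(1e-3, 3), t_min = 101:103)
  expect_error(difference_curve(a, c2), "overlap")
})

test_that("simulated cxl minus control is near zero before onset, negative after", {
  cfg <- phantom_config(n_z = 72, n_x = 32, n_y = 3, delta = 16, pitch_x = 12,
                        pitch_y = 120, anterior_apex_depth = 100,
                        corneal_thickness = 800, snr_db = 25, seed = 48)
  p <- processing_params(delta = 16e-6)
  frac <- 200 / cfg$corneal_thickness
  region <- region_spec(band = "anterior", band_depth = 200)
  ctrl_sc <- deformation_scenario("ctrl", duration = 40, frame_interval = 120,
                                  rate_profile = function(d, t) rep(1e-3, length(d)))
  cxl_sc <- deformation_scenario("cxl", duration = 40, frame_interval = 120,
                                 rate_profile = function(d, t) {
                                   if (t < 20) rep(1e-3, length(d))
                                   else ifelse(d <= frac, -1e-3, 1e-3)
                                 }, onset_time = 20, affected_depth = 200)
  surf <- surfaces_from_config(cfg)
  sim_c <- simulate_timeseries(cfg, ctrl_sc, p, keep_fields = FALSE)
  cfg2 <- cfg; cfg2$seed <- 49L
  sim_x <- simulate_timeseries(cfg2, cxl_sc, p, keep_fields = FALSE)
  cv_c <- strain_curve(sim_c$frames, surf, region, p, label = "ctrl")
  cv_x <- strain_curve(sim_x$frames, surf, region, p, label = "cxl")
  dc <- difference_curve(cv_x, cv_c)
  expect_lt(max(abs(dc$cum_strain[dc$t < 19])), 0.5)
  expect_lt(dc$cum_strain[nrow(dc)], -2)
  # increasingly negative: last point is the minimum
  post <- dc$cum_strain[dc$t > 22]
  expect_true(all(diff(post) < 0.1))
})
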
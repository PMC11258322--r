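# Synthetic speckle phantom and deformation scenarios.

test_that("configuration invariants are enforced", {
  expect_error(phantom_config(n_z = 10, delta = 4.48, n_x = 4, n_y = 1,
                              anterior_apex_depth = 10,
                              corneal_thickness = 100, seed = 1),
               "does not fit")
  expect_error(small_config(seed = 1, decorrelation = -1), "decorrelation")
  expect_error(phantom_config(n_z = 48, n_x = 24, n_y = 2), "seed")
  expect_error(small_config(seed = 1, curvature_radius = 100),
               "curvature_radius")
})

test_that("noise-free slab has speckle support exactly between the surfaces", {
  cfg <- small_config(seed = 7)
  v <- make_cornea_phantom(cfg)
  surf <- phantom_surfaces(cfg)
  zc <- (seq_len(cfg$n_z) - 0.5) * cfg$delta
  for (y in seq_len(cfg$n_y)) {
    inside <- outer(zc, surf$anterior_um[, y], ">=") &
      outer(zc, surf$posterior_um[, y], "<=")
    amp <- Mod(v$data[, , y])
    expect_true(all(amp[!inside] == 0))
    expect_true(all(amp[inside] > 0))
  }
})

test_that("phantom generation is deterministic for a fixed seed", {
  cfg <- small_config(seed = 3, snr_db = 20)
  expect_identical(make_cornea_phantom(cfg)$data, make_cornea_phantom(cfg)$data)
  sc <- scenario_preset("hypotonic_swelling",
                        thickness = cfg$corneal_thickness,
                        frame_interval = 600)
  s1 <- simulate_timeseries(cfg, sc, keep_fields = FALSE)
  s2 <- simulate_timeseries(cfg, sc, keep_fields = FALSE)
  expect_identical(lapply(s1$frames, `[[`, "data"),
                   lapply(s2$frames, `[[`, "data"))
})

test_that("curved-phantom surfaces follow the analytic circle equation", {
  R_um <- 7500
  cfg <- phantom_config(n_z = 120, n_x = 40, n_y = 3, delta = 4.48,
                        pitch_x = 12, pitch_y = 120,
                        anterior_apex_depth = 30, corneal_thickness = 250,
                        curvature_radius = R_um, snr_db = Inf, seed = 4)
  v <- make_cornea_phantom(cfg)
  # oracle: circle/plane intersection per column, independent arithmetic
  x_um <- (seq_len(cfg$n_x) - (cfg$n_x + 1) / 2) * cfg$pitch_x
  y_um <- (seq_len(cfg$n_y) - (cfg$n_y + 1) / 2) * cfg$pitch_y
  for (y in seq_len(cfg$n_y)) for (x in seq_len(cfg$n_x)) {
    amp <- Mod(v$data[, x, y])
    first_px <- which(amp > 0)[1]
    ant_um <- 30 + R_um - sqrt(R_um^2 - x_um[x]^2 - y_um[y]^2)
    expect_lt(abs(first_px - (ant_um / cfg$delta + 0.5)), 1.0)
  }
})

test_that("phase-only displacement preserves amplitude and imposes the phase", {
  cfg <- small_config(seed = 5)
  p <- processing_params(delta = cfg$delta * 1e-6)
  v <- make_cornea_phantom(cfg)
  # zero displacement is the identity
  v0 <- apply_axial_displacement(v, array(0, dim(v$data)), p)
  expect_identical(v0$data, v$data)
  # uniform displacement: per-voxel phase change 4 pi n U0 / lambda
  U0 <- 5e-8
  v1 <- apply_axial_displacement(v, array(U0, dim(v$data)), p)
  expect_equal(Mod(v1$data), Mod(v$data), tolerance = 1e-12)
  nz <- Mod(v$data) > 0
  dphi <- Arg(v1$data[nz] * Conj(v$data[nz]))
  expect_equal(dphi, rep(4 * pi * p$n_refr * U0 / p$lambda_mean, sum(nz)),
               tolerance = 1e-10)
  # exceeding the wrap-free bound is a metadata warning, not an error
  vbig <- apply_axial_displacement(
    v, array(2 * displacement_bound(p), dim(v$data)), p)
  expect_match(vbig$meta$warnings, "wrap-free")
  expect_null(v1$meta$warnings)
})

test_that("resample mode shifts the speckle pattern axially", {
  cfg <- small_config(seed = 6)
  p <- processing_params(delta = cfg$delta * 1e-6)
  v <- make_cornea_phantom(cfg)
  shift_px <- 3
  U <- array(shift_px * p$delta, dim(v$data))
  vs <- suppressWarnings(apply_axial_displacement(v, U, p, mode = "resample"))
  # amplitude pattern moved down by shift_px pixels (up to interpolation)
  a0 <- Mod(v$data[10:30, 5, 1])
  a1 <- Mod(vs$data[(10 + shift_px):(30 + shift_px), 5, 1])
  expect_equal(a1, a0, tolerance = 1e-8)
})

test_that("scenario constructor validates and presets are well-formed", {
  expect_error(deformation_scenario("x", duration = 0, frame_interval = 1,
                                    rate_profile = function(d, t) d * 0),
               "duration")
  expect_error(deformation_scenario("x", duration = 10, frame_interval = 1,
                                    rate_profile = function(d, t) rep(NaN, length(d))),
               "finite")
  expect_error(deformation_scenario("x", duration = 10, frame_interval = 1,
                                    onset_time = 11,
                                    rate_profile = function(d, t) d * 0),
               "onset_time")
  for (nm in c("isotonic", "hypotonic_swelling", "hypertonic_deswelling",
               "control_swelling", "cxl")) {
    sc <- scenario_preset(nm)
    expect_s3_class(sc, "oce_scenario")
    expect_true(all(is.finite(sc$rate_profile(seq(0, 1, 0.1), 10))))
  }
  # hypertonic preset crosses zero at 55% depth
  sc <- scenario_preset("hypertonic_deswelling")
  expect_lt(sc$rate_profile(0, 10), 0)
  expect_gt(sc$rate_profile(1, 10), 0)
  expect_equal(sc$rate_profile(0.55, 10), 0)
})

test_that("zero-rate scenario yields identical frames and zero true strain", {
  cfg <- small_config(seed = 8)
  sc <- deformation_scenario("null", duration = 5, frame_interval = 60,
                             rate_profile = function(d, t) rep(0, length(d)))
  sim <- simulate_timeseries(cfg, sc)
  expect_identical(sim$frames[[1]]$data, sim$frames[[6]]$data)
  expect_true(all(sim$truth$eps_inc_d == 0))
  expect_true(all(vapply(sim$truth$eps_inc, function(e) all(e == 0),
                         logical(1))))
})

test_that("constant-rate scenario integrates to rate times duration at every depth", {
  cfg <- small_config(seed = 9)
  r <- 2e-3
  sc <- deformation_scenario("const", duration = 10, frame_interval = 30,
                             rate_profile = function(d, t) rep(r, length(d)))
  sim <- simulate_timeseries(cfg, sc, keep_fields = FALSE)
  # closed-form integral oracle: cumulative strain = r * T uniformly
  final <- sim$truth$eps_cum_d[, ncol(sim$truth$eps_cum_d)]
  expect_equal(final, rep(r * 10, length(final)), tolerance = 1e-12)
})

test_that("true strain equals the axial derivative of true displacement", {
  cfg <- small_config(seed = 10)
  sc <- deformation_scenario("lin", duration = 6, frame_interval = 120,
                             rate_profile = function(d, t) 1e-3 * (1 - d))
  sim <- simulate_timeseries(cfg, sc)
  tr <- sim$truth
  delta_m <- cfg$delta * 1e-6
  for (k in seq_along(tr$eps_inc)) {
    dU <- (tr$U[[k + 1]] - tr$U[[k]])  # incremental displacement
    # forward difference at pixel z gives the strain at pixel z+1
    fd <- (dU[2:cfg$n_z, , , drop = FALSE] -
             dU[seq_len(cfg$n_z - 1), , , drop = FALSE]) / delta_m
    eps <- tr$eps_inc[[k]][2:cfg$n_z, , , drop = FALSE]
    expect_lt(max(abs(fd - eps)), 1e-3 * cfg$delta)  # O(delta) tolerance
  }
})

test_that("cxl scenario shrinks only the affected anterior band after onset", {
  cfg <- small_config(seed = 11)
  sc <- scenario_preset("cxl", thickness = cfg$corneal_thickness,
                        frame_interval = 120)
  sim <- simulate_timeseries(cfg, sc, keep_fields = FALSE)
  tr <- sim$truth
  frac <- sc$affected_depth / cfg$corneal_thickness
  t_mid <- (tr$t_min[-1] + tr$t_min[-length(tr$t_min)]) / 2
  neg <- tr$eps_inc_d < 0
  for (k in seq_along(t_mid)) {
    if (any(neg[, k])) {
      expect_true(t_mid[k] >= sc$onset_time)
      expect_true(all(tr$d_grid[neg[, k]] <= frac + 1e-9))
    }
  }
  expect_true(any(neg))
})

test_that("dropout frames are scheduled and phase-randomised", {
  cfg <- small_config(seed = 12)
  sc <- deformation_scenario("drop", duration = 10, frame_interval = 60,
                             rate_profile = function(d, t) rep(0, length(d)),
                             dropout_period = 4, dropout_duration = 1L)
  sim <- simulate_timeseries(cfg, sc)
  expect_equal(sim$truth$dropout_frames, c(5L, 9L))  # t = 4 and 8 min
  k <- sim$truth$dropout_frames[1]
  # amplitude preserved, phase decorrelated
  expect_equal(Mod(sim$frames[[k]]$data), Mod(sim$frames[[k - 1]]$data),
               tolerance = 1e-12)
  p <- processing_params(delta = cfg$delta * 1e-6)
  qm <- quality_mask(sim$frames[[k - 1]], sim$frames[[k]], p)
  expect_false(qm$frame_valid)
})
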
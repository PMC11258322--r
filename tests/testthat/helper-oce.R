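# Shared fixtures and independent brute-force oracles.

# small flat-slab phantom config; tissue spans pixels 6..35 at default sizes
small_config <- function(n_z = 48L, n_x = 24L, n_y = 2L, delta = 4.48,
                         anterior_apex_depth = 25,
                         corneal_thickness = 30 * delta, snr_db = Inf,
                         speckle = TRUE, seed = 1, ...) {
  phantom_config(n_z = n_z, n_x = n_x, n_y = n_y, delta = delta,
                 pitch_x = 12, pitch_y = 120,
                 anterior_apex_depth = anterior_apex_depth,
                 corneal_thickness = corneal_thickness, snr_db = snr_db,
                 speckle = speckle, seed = seed, ...)
}

# random complex volume (no tissue structure) for pure estimator tests
random_volume <- function(n_z, n_x, n_y, seed, delta = 4.48e-6) {
  set.seed(seed)
  n <- n_z * n_x * n_y
  oce_volume(array(complex(real = stats::rnorm(n),
                           imaginary = stats::rnorm(n)),
                   c(n_z, n_x, n_y)),
             delta = delta, pitch_x = 12e-6, pitch_y = 120e-6)
}

# naive nested-loop implementation of the amplitude-weighted windowed
# cross-correlation (same conjugation convention as the package: later frame
# times conjugate of earlier frame), independent of the box-sum code path
naive_W <- function(c1, c2, w_z, w_x) {
  d <- dim(c1)
  W <- array(0i, d)
  for (y in seq_len(d[3])) for (x in seq_len(d[2])) for (z in seq_len(d[1])) {
    s <- 0i
    for (j in max(1, z - w_z):min(d[1], z + w_z))
      for (k in max(1, x - w_x):min(d[2], x + w_x))
        s <- s + c2[j, k, y] * Conj(c1[j, k, y])
    if (Mod(s) > 0) W[z, x, y] <- s / Mod(s)
  }
  W
}

# naive second cross-correlation (axial-shift products of W)
naive_R <- function(W, w_z, w_x) {
  d <- dim(W)
  R <- array(0i, d)
  for (y in seq_len(d[3])) for (x in seq_len(d[2])) for (z in seq_len(d[1])) {
    s <- 0i
    for (j in max(1, z - w_z):min(d[1], z + w_z))
      for (k in max(1, x - w_x):min(d[2], x + w_x))
        if (j + 1 <= d[1]) s <- s + W[j + 1, k, y] * Conj(W[j, k, y])
    R[z, x, y] <- s
  }
  R
}

# displacement field (m) with constant axial strain eps0 inside the whole
# frame, posterior (bottom) row fixed
ramp_displacement <- function(dims, eps0, delta_m) {
  U <- array(0, dims)
  u_col <- -(dims[1] - seq_len(dims[1])) * eps0 * delta_m
  for (y in seq_len(dims[3])) for (x in seq_len(dims[2])) U[, x, y] <- u_col
  U
}

# frame pair with imposed constant strain on a uniform-amplitude phantom
# (exact closed-form recovery) or a speckle phantom
strain_pair <- function(eps0, speckle = FALSE, seed = 2, n_z = 60L,
                        n_x = 24L, n_y = 1L, snr_db = Inf) {
  cfg <- phantom_config(n_z = n_z, n_x = n_x, n_y = n_y, delta = 4.48,
                        pitch_x = 12, pitch_y = 120, anterior_apex_depth = 0,
                        corneal_thickness = n_z * 4.48, snr_db = snr_db,
                        speckle = speckle, seed = seed)
  params <- processing_params(delta = 4.48e-6)
  v1 <- make_cornea_phantom(cfg)
  U <- ramp_displacement(dim(v1$data), eps0, params$delta)
  v2 <- suppressWarnings(apply_axial_displacement(v1, U, params))
  v2$timestamp <- 1
  list(v1 = v1, v2 = v2, params = params, cfg = cfg, U = U)
}

# axial rows whose W and R windows are fully in-bounds (strain there is free
# of border-truncation offsets)
interior <- function(n, w) (2L * w + 1L):(n - 2L * w - 2L)
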
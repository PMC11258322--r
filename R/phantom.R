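# Synthetic complex OCT speckle phantom of a curved two-surface cornea, with
# prescribed depth- and time-dependent axial deformation fields.

#' Phantom configuration
#'
#' Geometry, sampling, speckle and noise parameters of the synthetic corneal
#' C-scan generator. Defaults emulate a spectral-domain OCT system imaging a
#' porcine cornea: 4.48 um axial sampling in tissue, 12 um lateral pitch
#' (1000 A-scans over 12 mm) and 100 B-scans; reduced sizes are the norm for
#' tests and simulations.
#'
#' @param n_z,n_x,n_y Axial samples, A-scans per B-scan, and B-scans.
#' @param delta Axial pixel pitch in tissue (um).
#' @param pitch_x,pitch_y Lateral pitches (um).
#' @param anterior_apex_depth Depth of the anterior surface apex below the
#'   top of the frame (um).
#' @param corneal_thickness Axial thickness of the tissue band (um).
#' @param curvature_radius Radius of the anterior surface (um); `Inf` gives a
#'   flat slab. The posterior surface is axially parallel to the anterior.
#' @param scatterer_density Mean scatterers per voxel of the speckle model.
#' @param snr_db Amplitude signal-to-noise ratio (dB) of the detector noise
#'   added to every frame; `Inf` disables noise.
#' @param decorrelation Per-frame phase-noise standard deviation (rad),
#'   modelling frame-to-frame speckle decorrelation.
#' @param psf_sigma_z,psf_sigma_x Gaussian point-spread-function widths
#'   (pixels) used to correlate the speckle; defaults follow 3.26 um axial /
#'   12 um lateral resolution at the default pitches.
#' @param speckle If `TRUE` (default) the tissue is fully developed speckle
#'   (random scatterers convolved with the PSF, circular-Gaussian statistics).
#'   If `FALSE` the tissue has unit amplitude with uniform random phase: this
#'   removes the amplitude weighting inside the estimator's windows and is
#'   used for closed-form recovery checks.
#' @param seed Mandatory integer RNG seed; all randomness in the phantom and
#'   its time series derives from it.
#' @return An object of class `oce_phantom_config`.
#' @examples
#' cfg <- phantom_config(n_z = 64, n_x = 32, n_y = 3, seed = 1)
#' vol <- make_cornea_phantom(cfg)
#' @export
phantom_config <- function(n_z = 900L, n_x = 1000L, n_y = 100L,
                           delta = 4.48, pitch_x = 12, pitch_y = 120,
                           anterior_apex_depth = 150,
                           corneal_thickness = 1000,
                           curvature_radius = Inf,
                           scatterer_density = 2,
                           snr_db = 25,
                           decorrelation = 0,
                           psf_sigma_z = 0.31,
                           psf_sigma_x = 0.42,
                           speckle = TRUE,
                           seed) {
  if (missing(seed))
    stop("'seed' is mandatory in a phantom configuration", call. = FALSE)
  seed <- as.integer(seed)
  n_z <- as.integer(n_z); n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (any(c(n_z, n_x, n_y) < 1L))
    stop("grid sizes must be positive integers", call. = FALSE)
  for (nm in c("delta", "pitch_x", "pitch_y"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  stopifnot_scalar(anterior_apex_depth, "anterior_apex_depth")
  stopifnot_scalar(corneal_thickness, "corneal_thickness", positive = TRUE)
  if (anterior_apex_depth < 0)
    stop("'anterior_apex_depth' must be >= 0", call. = FALSE)
  if (!is.numeric(curvature_radius) || length(curvature_radius) != 1L ||
      is.na(curvature_radius) || curvature_radius <= 0)
    stop("'curvature_radius' must be a positive number (Inf = flat)",
         call. = FALSE)
  stopifnot_scalar(scatterer_density, "scatterer_density", positive = TRUE)
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db))
    stop("'snr_db' must be a number (Inf = noise free)", call. = FALSE)
  stopifnot_scalar(decorrelation, "decorrelation")
  if (decorrelation < 0) stop("'decorrelation' must be >= 0", call. = FALSE)
  cfg <- structure(list(
    n_z = n_z, n_x = n_x, n_y = n_y, delta = delta,
    pitch_x = pitch_x, pitch_y = pitch_y,
    anterior_apex_depth = anterior_apex_depth,
    corneal_thickness = corneal_thickness,
    curvature_radius = curvature_radius,
    scatterer_density = scatterer_density, snr_db = snr_db,
    decorrelation = decorrelation,
    psf_sigma_z = psf_sigma_z, psf_sigma_x = psf_sigma_x,
    speckle = isTRUE(speckle), seed = seed), class = "oce_phantom_config")
  # the cornea (including curvature sag across the imaged field) must fit
  surf <- phantom_surfaces(cfg)
  if (max(surf$posterior_um) > n_z * delta)
    stop("cornea does not fit in the frame: increase n_z or reduce ",
         "anterior_apex_depth/corneal_thickness/curvature sag", call. = FALSE)
  cfg
}

#' @export
print.oce_phantom_config <- function(x, ...) {
  cat(sprintf("Cornea phantom config: %d x %d x %d (z, x, y)\n",
              x$n_z, x$n_x, x$n_y))
  cat(sprintf("  pitches %.2f/%.1f/%.1f um; apex %.0f um, thickness %.0f um, R %s um\n",
              x$delta, x$pitch_x, x$pitch_y, x$anterior_apex_depth,
              x$corneal_thickness,
              if (is.finite(x$curvature_radius))
                sprintf("%.0f", x$curvature_radius) else "Inf"))
  cat(sprintf("  %s amplitude, SNR %s dB, decorrelation %.3g rad, seed %d\n",
              if (x$speckle) "speckle" else "uniform",
              if (is.finite(x$snr_db)) sprintf("%.0f", x$snr_db) else "Inf",
              x$decorrelation, x$seed))
  invisible(x)
}

#' Analytic surface positions of the phantom
#'
#' Anterior and posterior boundary depths (um) per lateral position, from the
#' circle (sphere) equation of the anterior surface; the posterior surface is
#' axially parallel at `corneal_thickness` below.
#'
#' @param config An [phantom_config()] object.
#' @return List with matrices `anterior_um`, `posterior_um` (`n_x` x `n_y`)
#'   and the corresponding first/last in-tissue pixel indices `anterior_idx`,
#'   `posterior_idx` (pixel z centres at `(z - 0.5) * delta`).
#' @export
phantom_surfaces <- function(config) {
  x_um <- (seq_len(config$n_x) - (config$n_x + 1) / 2) * config$pitch_x
  y_um <- (seq_len(config$n_y) - (config$n_y + 1) / 2) * config$pitch_y
  r2 <- outer(x_um^2, y_um^2, "+")
  R <- config$curvature_radius
  sag <- if (is.finite(R)) {
    if (max(r2) >= R^2)
      stop("curvature_radius smaller than the lateral half-field; ",
           "the anterior surface does not cover the frame", call. = FALSE)
    R - sqrt(R^2 - r2)
  } else {
    r2 * 0
  }
  ant <- config$anterior_apex_depth + sag
  post <- ant + config$corneal_thickness
  zc <- (seq_len(config$n_z) - 0.5) * config$delta
  a_idx <- matrix(findInterval(ant, zc) + 1L, config$n_x, config$n_y)
  p_idx <- matrix(findInterval(post - 1e-9, zc), config$n_x, config$n_y)
  list(anterior_um = ant, posterior_um = post,
       anterior_idx = a_idx, posterior_idx = p_idx)
}

# logical [z, x, y] array: pixel centre inside the tissue band
tissue_mask <- function(config, surf = phantom_surfaces(config)) {
  zc <- (seq_len(config$n_z) - 0.5) * config$delta
  m <- array(FALSE, c(config$n_z, config$n_x, config$n_y))
  for (y in seq_len(config$n_y)) {
    m[, , y] <- outer(zc, surf$anterior_um[, y], ">=") &
      outer(zc, surf$posterior_um[, y], "<=")
  }
  m
}

# circular-Gaussian speckle (or unit-amplitude random-phase) field on the
# full grid; tissue support applied by the caller
base_field <- function(config) {
  d <- c(config$n_z, config$n_x, config$n_y)
  n <- prod(d)
  if (config$speckle) {
    occ <- sqrt(stats::rpois(n, config$scatterer_density))
    f <- array(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) /
                 sqrt(2) * occ, d)
    for (y in seq_len(d[3]))
      f[, , y] <- gauss_blur(f[, , y], config$psf_sigma_z, config$psf_sigma_x)
    # renormalise to unit mean intensity so snr_db has a fixed reference
    f / sqrt(mean(Mod(f)^2))
  } else {
    array(exp(1i * stats::runif(n, -pi, pi)), d)
  }
}

# additive complex detector noise for one frame, sigma from snr_db relative
# to unit rms tissue amplitude
detector_noise <- function(config) {
  if (!is.finite(config$snr_db)) return(0i)
  d <- c(config$n_z, config$n_x, config$n_y)
  sigma <- 10^(-config$snr_db / 20)
  array(complex(real = stats::rnorm(prod(d)),
                imaginary = stats::rnorm(prod(d))) * sigma / sqrt(2), d)
}

#' Generate one synthetic corneal C-scan
#'
#' Complex speckle confined to the band between the two corneal surfaces
#' (circular-Gaussian statistics from randomly placed point scatterers
#' convolved with a Gaussian PSF), near-zero amplitude outside (detector
#' noise floor set by `snr_db`). Deterministic for a fixed seed.
#'
#' @param config An [phantom_config()] object.
#' @param timestamp Acquisition time (s) stored on the volume.
#' @return An [oce_volume()].
#' @export
make_cornea_phantom <- function(config, timestamp = 0) {
  if (!inherits(config, "oce_phantom_config"))
    stop("'config' must be an 'oce_phantom_config'", call. = FALSE)
  set.seed(config$seed)
  f <- base_field(config)
  f[!tissue_mask(config)] <- 0i
  f <- f + detector_noise(config)
  oce_volume(f, delta = config$delta * 1e-6,
             pitch_x = config$pitch_x * 1e-6,
             pitch_y = config$pitch_y * 1e-6, timestamp = timestamp)
}

#' Apply a prescribed axial displacement field to a volume
#'
#' In `phase_only` mode every voxel is multiplied by the unit-modulus factor
#' `exp(1i * 4 pi n U / lambda_mean)` — the phase the phase-sensitive
#' estimator reads back — leaving amplitudes untouched. In `resample` mode
#' the speckle pattern is additionally shifted axially by `U / delta` pixels
#' (linear interpolation), which introduces decorrelation as in real tissue
#' motion. Displacements exceeding the wrap-free bound
#' `lambda_mean / (4 n)` are recorded as a warning in the returned volume's
#' metadata (aliasing), not an error.
#'
#' @param vol An [oce_volume()].
#' @param U Numeric array of axial displacements (m), same dimensions as
#'   `vol$data` (positive = towards larger depth).
#' @param params [processing_params()] supplying `lambda_mean`, `n_refr` and
#'   `delta`.
#' @param mode `"phase_only"` (default) or `"resample"`.
#' @return The displaced [oce_volume()].
#' @export
apply_axial_displacement <- function(vol, U, params = processing_params(),
                                     mode = c("phase_only", "resample")) {
  mode <- match.arg(mode)
  if (!inherits(vol, "oce_volume"))
    stop("'vol' must be an 'oce_volume'", call. = FALSE)
  if (is.null(dim(U)) || !identical(dim(U), dim(vol$data)))
    stop("'U' must be an array with the dimensions of the volume",
         call. = FALSE)
  if (any(!is.finite(U)))
    stop("'U' must be finite everywhere", call. = FALSE)
  meta <- vol$meta
  bound <- displacement_bound(params)
  if (max(abs(U)) > bound) {
    meta$warnings <- c(meta$warnings,
                       sprintf("displacement exceeds the wrap-free bound %.3g m; phase will alias",
                               bound))
  }
  data <- vol$data
  if (mode == "resample") {
    d <- dim(data)
    zi <- seq_len(d[1])
    for (y in seq_len(d[3])) {
      for (x in seq_len(d[2])) {
        src <- zi - U[, x, y] / params$delta
        re <- stats::approx(zi, Re(data[, x, y]), xout = src, rule = 2)$y
        im <- stats::approx(zi, Im(data[, x, y]), xout = src, rule = 2)$y
        data[, x, y] <- complex(real = re, imaginary = im)
      }
    }
  }
  data <- data * exp(1i * 4 * pi * params$n_refr * U / params$lambda_mean)
  oce_volume(data, vol$delta, vol$pitch_x, vol$pitch_y, vol$timestamp,
             meta = meta)
}

#' Deformation scenario
#'
#' A prescribed deformation history: an axial strain-rate profile over
#' normalized stromal depth `d` in `[0, 1]` (0 = anterior surface, 1 =
#' posterior surface) and time, the acquisition cadence, and an optional
#' periodic frame-dropout schedule mimicking fluid-application artifacts.
#'
#' @param name Scenario label; one of `"isotonic"`, `"hypotonic_swelling"`,
#'   `"hypertonic_deswelling"`, `"control_swelling"`, `"cxl"`, or any custom
#'   string.
#' @param duration Experiment duration (min).
#' @param frame_interval Time between C-scans (s).
#' @param rate_profile `function(d, t)` returning the axial strain rate
#'   (1/min) at normalized depth `d` (vectorised) and time `t` (min).
#' @param onset_time Treatment onset (min); informational except through
#'   `rate_profile` (used by the CXL preset).
#' @param affected_depth Depth (um) of the treatment-affected anterior band
#'   (CXL preset).
#' @param dropout_period Period (min) of frame dropouts; 0 disables them.
#' @param dropout_duration Number of consecutive frames lost per dropout.
#' @return An object of class `oce_scenario`.
#' @seealso [scenario_preset()] for presets with literature-derived rates.
#' @export
deformation_scenario <- function(name, duration, frame_interval, rate_profile,
                                 onset_time = NA_real_,
                                 affected_depth = NA_real_,
                                 dropout_period = 0, dropout_duration = 1L) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  if (!is.function(rate_profile))
    stop("'rate_profile' must be a function(d, t)", call. = FALSE)
  if (!is.na(onset_time) && onset_time >= duration)
    stop("'onset_time' must be < duration", call. = FALSE)
  stopifnot_scalar(dropout_period, "dropout_period")
  if (dropout_period < 0) stop("'dropout_period' must be >= 0", call. = FALSE)
  dgrid <- seq(0, 1, length.out = 21)
  for (t in c(0, duration / 2, duration)) {
    v <- rate_profile(dgrid, t)
    if (length(v) != length(dgrid) || any(!is.finite(v)))
      stop("'rate_profile' must return finite values for all d in [0,1]",
           call. = FALSE)
  }
  structure(list(name = as.character(name), duration = duration,
                 frame_interval = frame_interval, rate_profile = rate_profile,
                 onset_time = onset_time, affected_depth = affected_depth,
                 dropout_period = dropout_period,
                 dropout_duration = as.integer(dropout_duration)),
            class = "oce_scenario")
}

#' @export
print.oce_scenario <- function(x, ...) {
  cat(sprintf("Deformation scenario '%s': %.0f min at 1 frame / %.0f s\n",
              x$name, x$duration, x$frame_interval))
  if (!is.na(x$onset_time))
    cat(sprintf("  onset %.0f min, affected depth %.0f um\n",
                x$onset_time, x$affected_depth))
  if (x$dropout_period > 0)
    cat(sprintf("  dropouts: %d frame(s) every %.0f min\n",
                x$dropout_duration, x$dropout_period))
  invisible(x)
}

#' Preset deformation scenarios
#'
#' Scenarios emulating the osmotic preservation-media and cross-linking
#' experiments. Rate magnitudes are descriptive defaults: reported cumulative
#' strains divided by the corresponding durations.
#'
#' * `isotonic` — near-isotonic medium (MeM Dextran 5%): small uniform
#'   deswelling, about -1.8% over 45 min.
#' * `hypotonic_swelling` — PBS: uniform swelling of 3.7% in the first
#'   20 min, near-plateau afterwards; 45 min, one frame per minute.
#' * `hypertonic_deswelling` — MeM Dextran 7%: strain rate linear in depth,
#'   from anterior shrinkage (-5.6% at 20 min) to posterior swelling,
#'   crossing zero at 55% of thickness.
#' * `control_swelling` — the irrigation-only control arms of the CXL
#'   protocol: uniform swelling at 0.14 %/min for 20 min, then 0.09 %/min;
#'   80 min, one frame per 20 s, dropouts every 5 min.
#' * `cxl` — as the control until UV onset at minute 20, then shrinkage at
#'   -0.05 %/min inside the anterior `affected_depth` (200 um) with continued
#'   posterior swelling.
#'
#' @param name Preset name (see above).
#' @param thickness Corneal thickness (um) used to convert `affected_depth`
#'   to a normalized-depth fraction; should match the phantom config.
#' @param frame_interval Override of the preset cadence (s).
#' @return An [deformation_scenario()] object.
#' @export
scenario_preset <- function(name = c("isotonic", "hypotonic_swelling",
                                     "hypertonic_deswelling",
                                     "control_swelling", "cxl"),
                            thickness = 1000, frame_interval = NULL) {
  name <- match.arg(name)
  sc <- switch(
    name,
    isotonic = deformation_scenario(
      name, duration = 45, frame_interval = frame_interval %||% 60,
      rate_profile = function(d, t) rep(-4e-4, length(d))),
    hypotonic_swelling = deformation_scenario(
      name, duration = 45, frame_interval = frame_interval %||% 60,
      rate_profile = function(d, t)
        rep(if (t <= 20) 1.85e-3 else 8e-5, length(d))),
    hypertonic_deswelling = deformation_scenario(
      name, duration = 45, frame_interval = frame_interval %||% 60,
      rate_profile = function(d, t) -2.8e-3 * (0.55 - d) / 0.55),
    control_swelling = deformation_scenario(
      name, duration = 80, frame_interval = frame_interval %||% 20,
      rate_profile = function(d, t)
        rep(if (t <= 20) 1.4e-3 else 9e-4, length(d)),
      dropout_period = 5, dropout_duration = 1L),
    cxl = {
      frac <- min(1, 200 / thickness)
      deformation_scenario(
        name, duration = 80, frame_interval = frame_interval %||% 20,
        rate_profile = function(d, t) {
          if (t <= 20) rep(1.4e-3, length(d))
          else ifelse(d <= frac, -5e-4, 9e-4)
        },
        onset_time = 20, affected_depth = 200,
        dropout_period = 5, dropout_duration = 1L)
    })
  sc
}

#' Simulate a time series of deforming C-scans with ground truth
#'
#' Builds one static speckle realisation of the phantom and, for each frame
#' at `t_k = k * frame_interval`, imposes the cumulative axial displacement
#' obtained by integrating the scenario's strain-rate profile over time and
#' depth (posterior surface held fixed; swelling moves the anterior surface
#' towards the probe). Displacement is imposed in `phase_only` mode; fresh
#' detector noise (and optional decorrelation phase noise) is drawn per
#' frame. Frames scheduled as dropouts have their phase fully randomised,
#' emulating fluid-application artifacts. Per-pair displacement increments
#' exceeding the wrap-free bound are recorded as metadata warnings.
#'
#' @param config [phantom_config()].
#' @param scenario [deformation_scenario()] or [scenario_preset()] output.
#' @param params [processing_params()]; defaults to the config's axial pitch.
#' @param keep_fields Keep full per-frame true displacement and per-pair true
#'   strain arrays in the ground truth (memory-heavy for large grids).
#' @return A list with `frames` (list of [oce_volume()]s) and `truth`, an
#'   `oce_ground_truth` list with elements `t_min` (frame times, min),
#'   `eps_cum_d` / `eps_inc_d` (true cumulative/incremental strain on a
#'   normalized-depth grid `d_grid`, one column per frame/pair),
#'   `anterior_idx`/`posterior_idx` surface matrices, `dropout_frames`
#'   (1-based frame indices), and — when `keep_fields` — `U` (list of per-
#'   frame displacement arrays, m) and `eps_inc` (list of per-pair strain
#'   arrays).
#' @export
simulate_timeseries <- function(config, scenario,
                                params = processing_params(delta = config$delta * 1e-6),
                                keep_fields = TRUE) {
  if (!inherits(config, "oce_phantom_config"))
    stop("'config' must be an 'oce_phantom_config'", call. = FALSE)
  if (!inherits(scenario, "oce_scenario"))
    stop("'scenario' must be an 'oce_scenario'", call. = FALSE)
  set.seed(config$seed)

  surf <- phantom_surfaces(config)
  base <- base_field(config)
  tis <- tissue_mask(config, surf)
  base[!tis] <- 0i

  d <- c(config$n_z, config$n_x, config$n_y)
  dt_min <- scenario$frame_interval / 60
  n_frames <- floor(scenario$duration / dt_min) + 1L  # frame 0 at t = 0
  t_min <- (seq_len(n_frames) - 1L) * dt_min

  # dropout schedule: frames falling in [m * period, m * period + dur frames)
  dropout <- rep(FALSE, n_frames)
  if (scenario$dropout_period > 0) {
    for (m in seq_len(floor(scenario$duration / scenario$dropout_period))) {
      k0 <- which(t_min >= m * scenario$dropout_period)[1]
      if (!is.na(k0))
        dropout[k0:min(n_frames, k0 + scenario$dropout_duration - 1L)] <- TRUE
    }
  }

  # normalized-depth grid for the truth and per-column lookup indices
  n_d <- 101L
  d_grid <- seq(0, 1, length.out = n_d)
  zc <- (seq_len(config$n_z) - 0.5) * config$delta
  # d_idx[z, x, y]: index into d_grid, NA outside tissue
  d_idx <- array(NA_integer_, d)
  for (y in seq_len(config$n_y)) {
    dn <- outer(zc, surf$anterior_um[, y], "-") / config$corneal_thickness
    dn[dn < 0 | dn > 1] <- NA
    d_idx[, , y] <- matrix(as.integer(round(dn * (n_d - 1L))) + 1L,
                           config$n_z, config$n_x)
  }

  eps_cum_d <- matrix(0, n_d, n_frames)
  for (k in 2:n_frames) {
    t_mid <- (t_min[k - 1] + t_min[k]) / 2
    eps_cum_d[, k] <- eps_cum_d[, k - 1] +
      scenario$rate_profile(d_grid, t_mid) * dt_min
  }
  eps_inc_d <- eps_cum_d[, -1, drop = FALSE] -
    eps_cum_d[, -n_frames, drop = FALSE]

  delta_m <- config$delta * 1e-6
  k_phase <- 4 * pi * params$n_refr / params$lambda_mean
  bound <- displacement_bound(params)
  max_inc <- max(abs(eps_inc_d)) * config$corneal_thickness * 1e-6
  warn <- if (max_inc > bound)
    sprintf("per-pair displacement increment up to %.3g m exceeds the wrap-free bound %.3g m",
            max_inc, bound) else NULL

  # cumulative displacement field (m) for frame k from the truth profile:
  # posterior fixed, U(z) = -delta * sum_{z' > z} eps(z')
  u_field <- function(k) {
    U <- array(0, d)
    if (k == 1L) return(U)
    prof <- eps_cum_d[, k]
    for (y in seq_len(config$n_y)) {
      eps_zx <- matrix(0, config$n_z, config$n_x)
      idx <- d_idx[, , y]
      ok <- !is.na(idx)
      eps_zx[ok] <- prof[idx[ok]]
      s <- matrix(apply(eps_zx[config$n_z:1, , drop = FALSE], 2, cumsum),
                  config$n_z, config$n_x)[config$n_z:1, , drop = FALSE]
      U[, , y] <- -delta_m * (s - eps_zx)
    }
    U
  }

  frames <- vector("list", n_frames)
  U_list <- if (keep_fields) vector("list", n_frames) else NULL
  for (k in seq_len(n_frames)) {
    U <- u_field(k)
    dat <- base * exp(1i * k_phase * U)
    if (config$decorrelation > 0)
      dat <- dat * exp(1i * array(stats::rnorm(prod(d), 0, config$decorrelation), d))
    dat <- dat + detector_noise(config)
    if (dropout[k])
      dat <- Mod(dat) * exp(1i * array(stats::runif(prod(d), -pi, pi), d))
    frames[[k]] <- oce_volume(dat, delta_m, config$pitch_x * 1e-6,
                              config$pitch_y * 1e-6,
                              timestamp = t_min[k] * 60,
                              meta = list(warnings = warn,
                                          dropout = dropout[k]))
    if (keep_fields) U_list[[k]] <- U
  }

  eps_inc <- NULL
  if (keep_fields) {
    eps_inc <- vector("list", n_frames - 1L)
    for (k in seq_len(n_frames - 1L)) {
      E <- array(0, d)
      prof <- eps_inc_d[, k]
      for (y in seq_len(config$n_y)) {
        idx <- d_idx[, , y]
        ok <- !is.na(idx)
        e <- matrix(0, config$n_z, config$n_x)
        e[ok] <- prof[idx[ok]]
        E[, , y] <- e
      }
      eps_inc[[k]] <- E
    }
  }

  truth <- structure(list(
    t_min = t_min, d_grid = d_grid, eps_cum_d = eps_cum_d,
    eps_inc_d = eps_inc_d, anterior_idx = surf$anterior_idx,
    posterior_idx = surf$posterior_idx,
    anterior_um = surf$anterior_um, posterior_um = surf$posterior_um,
    dropout_frames = which(dropout), U = U_list, eps_inc = eps_inc),
    class = "oce_ground_truth")
  list(frames = frames, truth = truth)
}

#' @export
print.oce_ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d frames over %.0f min, %d dropout frame(s)\n",
              length(x$t_min), max(x$t_min), length(x$dropout_frames)))
  cat(sprintf("  final cumulative strain: anterior %.3g, posterior %.3g\n",
              x$eps_cum_d[1, ncol(x$eps_cum_d)],
              x$eps_cum_d[nrow(x$eps_cum_d), ncol(x$eps_cum_d)]))
  invisible(x)
}
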
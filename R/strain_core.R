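# Phase-sensitive displacement and axial strain estimation from pairs of
# complex OCT volumes, via amplitude-weighted complex cross-correlations.

#' Processing parameters for the phase-sensitive strain estimator
#'
#' Physical and window constants of the displacement/strain estimator.
#' Defaults follow a spectral-domain OCT system operating at 877.8 nm in
#' corneal tissue (refractive index 1.375) with an axial sampling unit of
#' 4.48 um and a 7 x 7 pixel (half-width 3) phase-processing window.
#'
#' @param lambda_mean Central wavelength of the source (m).
#' @param n_refr Refractive index of the tissue.
#' @param delta Axial sampling unit in tissue (m).
#' @param w_z,w_x Axial and lateral half-widths of the phase-processing
#'   window (pixels); the window spans `2*w + 1` pixels.
#' @param amp_threshold Relative amplitude floor used by [quality_mask()]:
#'   pixels below `amp_threshold` times the frame's reference (upper-quartile)
#'   amplitude are masked. In `[0, 1)`.
#' @return An object of class `oce_params`.
#' @examples
#' p <- processing_params()
#' strain_bound(p)   # largest unambiguous per-pair strain
#' @export
processing_params <- function(lambda_mean = 877.8e-9, n_refr = 1.375,
                              delta = 4.48e-6, w_z = 3L, w_x = 3L,
                              amp_threshold = 0.1) {
  stopifnot_scalar(lambda_mean, "lambda_mean", positive = TRUE)
  stopifnot_scalar(n_refr, "n_refr")
  stopifnot_scalar(delta, "delta", positive = TRUE)
  if (n_refr < 1) stop("'n_refr' must be >= 1", call. = FALSE)
  w_z <- as.integer(w_z); w_x <- as.integer(w_x)
  if (is.na(w_z) || is.na(w_x) || w_z < 0L || w_x < 0L)
    stop("'w_z' and 'w_x' must be non-negative integers", call. = FALSE)
  stopifnot_scalar(amp_threshold, "amp_threshold")
  if (amp_threshold < 0 || amp_threshold >= 1)
    stop("'amp_threshold' must be in [0, 1)", call. = FALSE)
  structure(list(lambda_mean = lambda_mean, n_refr = n_refr, delta = delta,
                 w_z = w_z, w_x = w_x, amp_threshold = amp_threshold),
            class = "oce_params")
}

#' @export
print.oce_params <- function(x, ...) {
  cat("OCE processing parameters\n")
  cat(sprintf("  lambda_mean: %.1f nm, n: %.3f, delta: %.2f um\n",
              x$lambda_mean * 1e9, x$n_refr, x$delta * 1e6))
  cat(sprintf("  window half-widths: w_z = %d, w_x = %d pixels\n",
              x$w_z, x$w_x))
  cat(sprintf("  amplitude threshold: %.2f\n", x$amp_threshold))
  cat(sprintf("  per-pair displacement bound: %.1f nm, strain bound: %.3g\n",
              displacement_bound(x) * 1e9, strain_bound(x)))
  invisible(x)
}

#' Unambiguous per-pair displacement and strain bounds
#'
#' Phase differences live on (-pi, pi], so per frame pair the measurable
#' axial displacement is bounded by `lambda_mean / (4 n)` and the axial
#' strain by `lambda_mean / (4 n delta)`; larger values alias (wrap).
#'
#' @param params An [processing_params()] object.
#' @return The bound (m for displacement, dimensionless for strain).
#' @export
displacement_bound <- function(params) {
  params$lambda_mean / (4 * params$n_refr)
}

#' @rdname displacement_bound
#' @export
strain_bound <- function(params) {
  params$lambda_mean / (4 * params$n_refr * params$delta)
}

#' Complex OCT volume constructor
#'
#' A C-scan: a 3-D complex reflectivity field indexed `[z, x, y]` (axial
#' sample, A-scan within B-scan, B-scan), with physical pixel pitches and an
#' acquisition timestamp. The z index runs from the shallowest optical depth
#' downwards.
#'
#' @param data 3-D complex array `[z, x, y]`.
#' @param delta Axial pixel pitch in tissue (m).
#' @param pitch_x,pitch_y Lateral pitches (m).
#' @param timestamp Acquisition time (s).
#' @param meta Optional list of metadata (e.g. wrap warnings).
#' @return An object of class `oce_volume`.
#' @export
oce_volume <- function(data, delta, pitch_x, pitch_y, timestamp = 0,
                       meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array [z, x, y]", call. = FALSE)
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (any(!is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  stopifnot_scalar(delta, "delta", positive = TRUE)
  stopifnot_scalar(pitch_x, "pitch_x", positive = TRUE)
  stopifnot_scalar(pitch_y, "pitch_y", positive = TRUE)
  structure(list(data = data, delta = delta, pitch_x = pitch_x,
                 pitch_y = pitch_y, timestamp = timestamp, meta = meta),
            class = "oce_volume")
}

#' @export
print.oce_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Complex OCT volume: %d x %d x %d (z, x, y)\n", d[1], d[2], d[3]))
  cat(sprintf("  pitches: %.2f (z) x %.2f (x) x %.2f (y) um, t = %.1f s\n",
              x$delta * 1e6, x$pitch_x * 1e6, x$pitch_y * 1e6, x$timestamp))
  if (length(x$meta$warnings))
    cat("  warnings:", paste(x$meta$warnings, collapse = "; "), "\n")
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(c(a$delta, a$pitch_x, a$pitch_y),
                     c(b$delta, b$pitch_x, b$pitch_y)))
}

new_complex_map <- function(data, valid, kind) {
  structure(list(data = data, valid = valid, kind = kind),
            class = "oce_complex_map")
}

#' @export
print.oce_complex_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Complex correlation map (kind %s): %d x %d x %d, %.1f%% valid\n",
              x$kind, d[1], d[2], d[3], 100 * mean(x$valid)))
  invisible(x)
}

#' Amplitude-weighted complex cross-correlation between two C-scans
#'
#' At every voxel the complex products of the two interference signals are
#' summed over a `(2*w_z+1) x (2*w_x+1)` window within the B-scan and the sum
#' is normalised by its own modulus, so the result `W` has unit modulus
#' wherever defined and its angle is the local phase difference between the
#' scans. The conjugation order is chosen so that a phase factor applied to
#' the *later* scan is read back with its own sign (axial motion towards
#' larger depth gives positive angle). Windows are truncated at array
#' borders; positions where the windowed sum has (numerically) zero modulus
#' are flagged invalid and set to 0.
#'
#' @param c1,c2 Two [oce_volume()]s on the same grid (`c1` earlier, `c2`
#'   later).
#' @param params [processing_params()].
#' @return An `oce_complex_map` of kind `"W"` with fields `data` (complex,
#'   unit modulus where valid) and `valid` (logical).
#' @export
complex_cross_correlation <- function(c1, c2, params = processing_params()) {
  if (!inherits(c1, "oce_volume") || !inherits(c2, "oce_volume"))
    stop("inputs must be 'oce_volume' objects", call. = FALSE)
  if (!same_grid(c1, c2))
    stop("volumes must share shape and pixel pitches", call. = FALSE)
  d <- dim(c1$data)
  W <- array(0i, d)
  valid <- array(FALSE, d)
  for (y in seq_len(d[3])) {
    p <- c2$data[, , y] * Conj(c1$data[, , y])
    s <- box_sum(p, params$w_z, params$w_x)
    a <- box_sum(Mod(c1$data[, , y]) * Mod(c2$data[, , y]),
                 params$w_z, params$w_x)
    ok <- Mod(s) > a * 1e-12 & a > 0
    w <- array(0i, d[1:2])
    w[ok] <- s[ok] / Mod(s[ok])
    W[, , y] <- w
    valid[, , y] <- ok
  }
  new_complex_map(W, valid, "W")
}

#' Axial displacement map from a phase-correlation map
#'
#' Converts the angle of the unit-modulus cross-correlation `W` into axial
#' displacement, `U = lambda_mean * angle(W) / (4 pi n)`. Per frame pair the
#' displacement is confined to `(-lambda/(4n), lambda/(4n)]`; larger motion
#' aliases.
#'
#' @param W An `oce_complex_map` of kind `"W"`.
#' @param params [processing_params()].
#' @return An `oce_field` with `data` (displacement, m), `valid`, and
#'   `kind = "displacement"`.
#' @export
displacement_map <- function(W, params = processing_params()) {
  if (!inherits(W, "oce_complex_map") || W$kind != "W")
    stop("'W' must be a complex map of kind 'W'", call. = FALSE)
  U <- params$lambda_mean * Arg(W$data) / (4 * pi * params$n_refr)
  new_field(U, W$valid, "displacement", "m")
}

#' Strain cross-correlation of a phase map with its axial shift
#'
#' Second complex cross-correlation: products of `W` at depth `z+1` with the
#' conjugate of `W` at depth `z`, summed over the same phase-processing
#' window, so the angle of the result is the local axial phase gradient
#' (radians per axial sample). Invalid `W` positions contribute zero to the
#' sums; the ordering makes axial expansion (tissue swelling) come out as a
#' positive angle.
#'
#' @param W An `oce_complex_map` of kind `"W"`.
#' @param params [processing_params()].
#' @return An `oce_complex_map` of kind `"R"` (not unit-normalised; only its
#'   angle is used).
#' @export
strain_correlation <- function(W, params = processing_params()) {
  if (!inherits(W, "oce_complex_map") || W$kind != "W")
    stop("'W' must be a complex map of kind 'W'", call. = FALSE)
  d <- dim(W$data)
  if (d[1] < 2L * params$w_z + 2L)
    stop("volume too shallow for the axial window: need n_z >= 2*w_z + 2",
         call. = FALSE)
  R <- array(0i, d)
  valid <- array(FALSE, d)
  nz <- d[1]
  for (y in seq_len(d[3])) {
    w <- W$data[, , y]
    v <- W$valid[, , y]
    p <- array(0i, d[1:2])
    p[seq_len(nz - 1L), ] <- w[2:nz, , drop = FALSE] *
      Conj(w[seq_len(nz - 1L), , drop = FALSE])
    cnt <- array(0, d[1:2])
    cnt[seq_len(nz - 1L), ] <- (v[2:nz, , drop = FALSE] &
                                  v[seq_len(nz - 1L), , drop = FALSE]) * 1
    s <- box_sum(p, params$w_z, params$w_x)
    n_ok <- box_sum(cnt, params$w_z, params$w_x)
    ok <- n_ok > 0 & Mod(s) > 0
    s[!ok] <- 0i
    R[, , y] <- s
    valid[, , y] <- ok
  }
  new_complex_map(R, valid, "R")
}

#' Axial strain map from the strain cross-correlation
#'
#' `eps_zz = lambda_mean * angle(R) / (4 pi n delta)`: the axial gradient of
#' displacement, positive for axial expansion (swelling). Per frame pair the
#' strain is confined to `(-lambda/(4 n delta), lambda/(4 n delta)]`.
#'
#' @param R An `oce_complex_map` of kind `"R"` from [strain_correlation()].
#' @param params [processing_params()].
#' @return An `oce_field` with `data` (strain, dimensionless), `valid`, and
#'   `kind = "strain"`.
#' @export
axial_strain_map <- function(R, params = processing_params()) {
  if (!inherits(R, "oce_complex_map") || R$kind != "R")
    stop("'R' must be a complex map of kind 'R'", call. = FALSE)
  eps <- params$lambda_mean * Arg(R$data) /
    (4 * pi * params$n_refr * params$delta)
  new_field(eps, R$valid, "strain", "-")
}

new_field <- function(data, valid, kind, units) {
  structure(list(data = data, valid = valid, kind = kind, units = units),
            class = "oce_field")
}

#' @export
print.oce_field <- function(x, ...) {
  d <- dim(x$data)
  v <- x$data[x$valid]
  cat(sprintf("OCE %s field [%s]: %d x %d x %d, %.1f%% valid\n",
              x$kind, x$units, d[1], d[2], d[3], 100 * mean(x$valid)))
  if (length(v))
    cat(sprintf("  valid range: [%.3g, %.3g], mean %.3g\n",
                min(v), max(v), mean(v)))
  invisible(x)
}

#' Amplitude and decorrelation quality mask for a frame pair
#'
#' Masks pixels whose structural amplitude in either frame falls below
#' `amp_threshold` times the frame's reference amplitude (the upper quartile
#' of that frame's amplitudes, a robust in-tissue level), and flags the whole
#' pair invalid when the phase correlation between the frames collapses
#' (e.g. fluid-application artifacts that randomise the phase) or too few
#' pixels survive masking.
#'
#' @param c1,c2 The two [oce_volume()]s of the pair.
#' @param params [processing_params()]; supplies `amp_threshold` and the
#'   correlation window.
#' @param corr_floor Minimum mean correlation coefficient
#'   `|sum(C2 C1*)| / sum(|C1||C2|)` (summed over the lateral window, so a
#'   genuine axial strain ramp does not depress it) over unmasked pixels for
#'   the pair to count as valid.
#' @param valid_floor Minimum fraction of unmasked pixels.
#' @return A list with `mask` (logical array, TRUE = usable), `frame_valid`
#'   (logical scalar), and `mean_corr` (mean correlation coefficient over the
#'   mask).
#' @export
quality_mask <- function(c1, c2, params = processing_params(),
                         corr_floor = 0.75, valid_floor = 0.25) {
  if (!same_grid(c1, c2))
    stop("volumes must share shape and pixel pitches", call. = FALSE)
  a1 <- Mod(c1$data)
  a2 <- Mod(c2$data)
  ref1 <- stats::quantile(a1, 0.75, names = FALSE)
  ref2 <- stats::quantile(a2, 0.75, names = FALSE)
  if (ref1 <= 0 || ref2 <= 0) {
    return(list(mask = array(FALSE, dim(a1)), frame_valid = FALSE,
                mean_corr = NA_real_))
  }
  mask <- a1 > params$amp_threshold * ref1 & a2 > params$amp_threshold * ref2
  frac <- mean(mask)
  if (!any(mask)) {
    return(list(mask = mask, frame_valid = FALSE, mean_corr = NA_real_))
  }
  # lateral-window phase-correlation coefficient: 1 for coherent speckle,
  # ~ 1/sqrt(window size) for decorrelated phase. Only the lateral window is
  # summed so that the axial phase ramp of a genuine strain field does not
  # depress the coefficient.
  d <- dim(a1)
  q <- array(0, d)
  for (y in seq_len(d[3])) {
    s <- box_sum(c2$data[, , y] * Conj(c1$data[, , y]), 0L, params$w_x)
    a <- box_sum(a1[, , y] * a2[, , y], 0L, params$w_x)
    qy <- array(0, d[1:2])
    pos <- a > 0
    qy[pos] <- Mod(s[pos]) / a[pos]
    q[, , y] <- qy
  }
  mean_corr <- mean(q[mask])
  list(mask = mask,
       frame_valid = frac >= valid_floor && mean_corr >= corr_floor,
       mean_corr = mean_corr)
}

#' One-call strain map for a pair of C-scans
#'
#' Convenience wrapper chaining [complex_cross_correlation()],
#' [strain_correlation()], [axial_strain_map()] and [quality_mask()]; the
#' returned strain field's validity is the intersection of the correlation
#' validity and the amplitude mask.
#'
#' @inheritParams quality_mask
#' @return An `oce_field` of kind `"strain"` with attribute `pair_valid`.
#' @export
strain_map_pair <- function(c1, c2, params = processing_params(),
                            corr_floor = 0.75, valid_floor = 0.25) {
  W <- complex_cross_correlation(c1, c2, params)
  eps <- axial_strain_map(strain_correlation(W, params), params)
  qm <- quality_mask(c1, c2, params, corr_floor, valid_floor)
  eps$valid <- eps$valid & qm$mask
  attr(eps, "pair_valid") <- qm$frame_valid
  attr(eps, "mean_corr") <- qm$mean_corr
  eps
}
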
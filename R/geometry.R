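# Corneal surface detection from structural amplitude, and the averaging
# regions used for regional strain: anterior/posterior depth bands anchored to
# the detected surfaces, central lateral windows, normalized-depth profiles.

#' Detect corneal surfaces from structural amplitude
#'
#' Per A-scan, the axial amplitude profile is smoothed with a running mean
#' and thresholded at a fraction of the column maximum; the anterior surface
#' is the first and the posterior the last axial index above threshold.
#' Columns whose detection fails (no pixels above threshold, or a gap smaller
#' than `min_gap` pixels) are interpolated from neighbouring columns and
#' flagged. Detected boundaries are median-filtered across the lateral
#' direction to suppress speckle outliers.
#'
#' @param vol An [oce_volume()] (its amplitude is used) or a non-negative
#'   3-D amplitude array.
#' @param min_gap Minimum anterior-posterior separation (pixels).
#' @param frac Threshold as a fraction of the smoothed column maximum.
#' @param smooth Half-width (pixels) of the axial running-mean smoother.
#' @param median_k Window width (odd) of the lateral median filter.
#' @return An object of class `oce_surfaces`: matrices `anterior`,
#'   `posterior` (axial pixel index, `n_x` x `n_y`), `thickness_um`,
#'   `flagged` (columns whose detection was interpolated), and `delta_um`.
#' @export
detect_surfaces <- function(vol, min_gap = 3L, frac = 0.3, smooth = 2L,
                            median_k = 5L) {
  if (inherits(vol, "oce_volume")) {
    amp <- Mod(vol$data)
    delta_um <- vol$delta * 1e6
  } else {
    amp <- vol
    delta_um <- attr(vol, "delta_um") %||% NA_real_
    if (any(amp < 0)) stop("amplitude must be non-negative", call. = FALSE)
  }
  d <- dim(amp)
  if (length(d) != 3L) stop("expected a 3-D volume", call. = FALSE)
  # robust noise scale: the lower decile of amplitudes is noise-dominated
  # whenever a non-tissue background is in the frame (Rayleigh quantile:
  # q(p) = s * sqrt(-2 log(1 - p)), so s = q10 / 0.459); zero when noise free
  noise_sigma <- stats::quantile(amp, 0.10, names = FALSE) /
    sqrt(-2 * log(0.9))
  thr_raw <- 3.5 * noise_sigma
  ant <- post <- matrix(NA_real_, d[2], d[3])
  for (y in seq_len(d[3])) {
    for (x in seq_len(d[2])) {
      raw <- amp[, x, y]
      a <- run_mean(raw, smooth)
      mx <- max(a)
      if (mx <= 0 || mx <= 2 * thr_raw) next
      idx <- which(a > frac * mx)
      if (length(idx) < 2L || (max(idx) - min(idx)) < min_gap) next
      # refine on the unsmoothed profile: the running mean leaks tissue
      # amplitude up to `smooth` pixels across the true boundary
      lo <- max(1L, min(idx) - smooth - 1L)
      hi <- min(d[1], min(idx) + smooth)
      cand <- lo - 1L + which(raw[lo:hi] > thr_raw)
      ant[x, y] <- if (length(cand)) min(cand) else min(idx)
      lo <- max(1L, max(idx) - smooth)
      hi <- min(d[1], max(idx) + smooth + 1L)
      cand <- lo - 1L + which(raw[lo:hi] > thr_raw)
      post[x, y] <- if (length(cand)) max(cand) else max(idx)
    }
  }
  failed <- is.na(ant)
  if (mean(failed) > 0.5)
    stop("surface detection failed on more than half of the A-scans",
         call. = FALSE)
  # lateral median filtering + interpolation of failed columns, per B-scan
  for (y in seq_len(d[3])) {
    for (s in list("ant", "post")) {
      v <- if (s == "ant") ant[, y] else post[, y]
      ok <- !is.na(v)
      if (sum(ok) >= 2L && any(!ok))
        v[!ok] <- stats::approx(which(ok), v[ok], xout = which(!ok),
                                rule = 2)$y
      if (sum(ok) == 1L) v[!ok] <- v[ok]
      if (length(v) >= median_k)
        v <- stats::runmed(v, median_k, endrule = "keep")
      if (s == "ant") ant[, y] <- v else post[, y] <- v
    }
  }
  structure(list(anterior = ant, posterior = post,
                 thickness_um = (post - ant) * delta_um,
                 flagged = failed, delta_um = delta_um),
            class = "oce_surfaces")
}

#' @export
print.oce_surfaces <- function(x, ...) {
  cat(sprintf("Corneal surfaces over %d x %d A-scans\n",
              nrow(x$anterior), ncol(x$anterior)))
  cat(sprintf("  anterior index %.1f-%.1f, posterior %.1f-%.1f, mean thickness %.0f um\n",
              min(x$anterior), max(x$anterior), min(x$posterior),
              max(x$posterior), mean(x$thickness_um)))
  if (any(x$flagged))
    cat(sprintf("  %d column(s) interpolated\n", sum(x$flagged)))
  invisible(x)
}

#' Surfaces from phantom ground truth
#'
#' Convenience constructor building an `oce_surfaces` object from the
#' analytic surfaces of a [phantom_config()], bypassing detection.
#'
#' @param config [phantom_config()].
#' @return An `oce_surfaces` object.
#' @export
surfaces_from_config <- function(config) {
  s <- phantom_surfaces(config)
  structure(list(anterior = s$anterior_idx * 1.0,
                 posterior = s$posterior_idx * 1.0,
                 thickness_um = (s$posterior_idx - s$anterior_idx) * config$delta,
                 flagged = matrix(FALSE, config$n_x, config$n_y),
                 delta_um = config$delta),
            class = "oce_surfaces")
}

#' Averaging-region specification
#'
#' Defines the regional mean used for cumulative strain curves: a depth band
#' anchored to a corneal surface and a centred lateral window. Defaults
#' follow the anterior/posterior 400 um of corneal thickness averaged over a
#' central 4 x 0.48 mm lateral region.
#'
#' @param band `"anterior"`, `"posterior"`, or `"full"` (entire thickness).
#' @param band_depth Band depth (um), measured downward from the anterior
#'   surface or upward from the posterior surface.
#' @param lateral_halfwidth_x,lateral_halfwidth_y Half-widths (um) of the
#'   centred lateral window (2000 and 240 um give 4 x 0.48 mm).
#' @return An object of class `oce_region`.
#' @export
region_spec <- function(band = c("anterior", "posterior", "full"),
                        band_depth = 400, lateral_halfwidth_x = 2000,
                        lateral_halfwidth_y = 240) {
  band <- match.arg(band)
  stopifnot_scalar(band_depth, "band_depth", positive = TRUE)
  stopifnot_scalar(lateral_halfwidth_x, "lateral_halfwidth_x", positive = TRUE)
  stopifnot_scalar(lateral_halfwidth_y, "lateral_halfwidth_y", positive = TRUE)
  structure(list(band = band, band_depth = band_depth,
                 lateral_halfwidth_x = lateral_halfwidth_x,
                 lateral_halfwidth_y = lateral_halfwidth_y),
            class = "oce_region")
}

# indices of the centred lateral window
central_window <- function(n, halfwidth_um, pitch_um) {
  c0 <- (n + 1) / 2
  hw <- halfwidth_um / pitch_um
  idx <- which(abs(seq_len(n) - c0) <= hw)
  if (!length(idx)) idx <- unique(pmin(pmax(round(c0), 1L), n))
  idx
}

# per-column z range of a band, clipped to the tissue; returns c(z0, z1) or
# NULL when empty
band_range <- function(a, p, band, band_px) {
  if (band == "full") return(c(ceiling(a), floor(p)))
  if (band == "anterior") {
    z0 <- a
    z1 <- min(a + band_px, p)
  } else {
    z0 <- max(p - band_px, a)
    z1 <- p
  }
  z0 <- ceiling(z0); z1 <- floor(z1)
  if (z1 < z0) return(NULL)
  c(z0, z1)
}

#' Regional mean strain
#'
#' Mean of the valid strain pixels inside a surface-anchored depth band,
#' restricted to the central lateral window: the anterior band spans from the
#' anterior surface downward by `band_depth`, the posterior band from the
#' posterior surface upward. Bands deeper than the local thickness are
#' clipped with a warning.
#'
#' @param strain An `oce_field` of kind `"strain"` (from
#'   [axial_strain_map()] or [strain_map_pair()]).
#' @param surf An `oce_surfaces` object on the same grid.
#' @param region An [region_spec()].
#' @param pitch_x_um,pitch_y_um Lateral pitches (um) of the strain grid.
#' @return A list with `mean` (strain) and `n` (contributing pixels).
#' @export
region_mean <- function(strain, surf, region = region_spec(),
                        pitch_x_um = 12, pitch_y_um = 120) {
  if (!inherits(strain, "oce_field") || strain$kind != "strain")
    stop("'strain' must be an oce_field of kind 'strain'", call. = FALSE)
  d <- dim(strain$data)
  if (!identical(dim(surf$anterior), c(d[2], d[3])))
    stop("'surf' grid does not match the strain map", call. = FALSE)
  band_px <- region$band_depth / surf$delta_um
  if (region$band != "full" &&
      region$band_depth > min(surf$thickness_um) + 1e-9)
    warning("band_depth exceeds the local corneal thickness; band clipped")
  xs <- central_window(d[2], region$lateral_halfwidth_x, pitch_x_um)
  ys <- central_window(d[3], region$lateral_halfwidth_y, pitch_y_um)
  tot <- 0
  n <- 0L
  for (y in ys) for (x in xs) {
    zr <- band_range(surf$anterior[x, y], surf$posterior[x, y],
                     region$band, band_px)
    if (is.null(zr)) next
    zr[1] <- max(zr[1], 1L); zr[2] <- min(zr[2], d[1])
    if (zr[2] < zr[1]) next
    z <- zr[1]:zr[2]
    ok <- strain$valid[z, x, y]
    if (any(ok)) {
      tot <- tot + sum(strain$data[z, x, y][ok])
      n <- n + sum(ok)
    }
  }
  if (n == 0L)
    stop("no valid strain pixels inside the requested region", call. = FALSE)
  list(mean = tot / n, n = n)
}

#' Strain profile over normalized corneal depth
#'
#' Resamples each A-scan's strain onto `n_bins` equal fractions of the local
#' thickness (normalized depth `d` in `[0, 1]`, 0 = anterior surface) and
#' averages across the central lateral window of the central B-scan, the
#' depth-profile construction used for depth-resolved strain plots.
#'
#' @param strain An `oce_field` of kind `"strain"`.
#' @param surf An `oce_surfaces` object.
#' @param n_bins Number of normalized-depth bins (>= 2).
#' @param lateral_halfwidth_x Half-width (um) of the central window along x
#'   (224 um spans 40 A-scans at 11.2 um pitch).
#' @param pitch_x_um Lateral pitch (um).
#' @param y_index B-scan index (default central).
#' @return A data frame with `d` (bin centre), `strain` (mean), and `n`
#'   (contributing pixels per bin).
#' @export
depth_profile <- function(strain, surf, n_bins = 20L,
                          lateral_halfwidth_x = 224, pitch_x_um = 12,
                          y_index = NULL) {
  if (n_bins < 2L) stop("'n_bins' must be >= 2", call. = FALSE)
  d <- dim(strain$data)
  y <- y_index %||% as.integer(ceiling(d[3] / 2))
  xs <- central_window(d[2], lateral_halfwidth_x, pitch_x_um)
  acc <- numeric(n_bins)
  cnt <- integer(n_bins)
  for (x in xs) {
    a <- surf$anterior[x, y]
    p <- surf$posterior[x, y]
    if (p <= a) next
    z <- max(1L, ceiling(a)):min(d[1], floor(p))
    dn <- (z - a) / (p - a)
    bin <- pmin(pmax(floor(dn * n_bins) + 1L, 1L), n_bins)
    ok <- strain$valid[z, x, y]
    if (!any(ok)) next
    tb <- tapply(strain$data[z, x, y][ok], bin[ok], sum)
    nb <- tapply(rep(1L, sum(ok)), bin[ok], sum)
    ib <- as.integer(names(tb))
    acc[ib] <- acc[ib] + as.numeric(tb)
    cnt[ib] <- cnt[ib] + as.integer(nb)
  }
  if (all(cnt == 0L))
    stop("no valid strain pixels inside the requested region", call. = FALSE)
  data.frame(d = (seq_len(n_bins) - 0.5) / n_bins,
             strain = ifelse(cnt > 0, acc / cnt, NA_real_), n = cnt)
}
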
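# Cumulative regional strain curves, depth-time strain maps, and group
# difference curves built from per-pair strain maps.

#' Incremental strain maps between consecutive C-scans
#'
#' Runs the phase-sensitive estimator on every consecutive pair of a
#' time-ordered series: one strain map per pair `(k, k+1)`. Pairs involving a
#' decorrelated (dropout) frame are flagged invalid by the quality mask.
#'
#' @param frames List of [oce_volume()]s with strictly increasing timestamps.
#' @param params [processing_params()].
#' @param corr_floor,valid_floor Passed to [quality_mask()].
#' @return A list of `oce_field` strain maps (see [strain_map_pair()]), each
#'   carrying attributes `pair_valid` and `t_mid_min` (pair midpoint time in
#'   minutes).
#' @export
incremental_strain_series <- function(frames, params = processing_params(),
                                      corr_floor = 0.75, valid_floor = 0.25) {
  if (length(frames) < 2L)
    stop("need at least two frames", call. = FALSE)
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (any(diff(ts) <= 0))
    stop("frame timestamps must be strictly increasing", call. = FALSE)
  out <- vector("list", length(frames) - 1L)
  for (k in seq_along(out)) {
    eps <- strain_map_pair(frames[[k]], frames[[k + 1L]], params,
                           corr_floor, valid_floor)
    attr(eps, "t_mid_min") <- (ts[k] + ts[k + 1L]) / 2 / 60
    out[[k]] <- eps
  }
  out
}

#' Accumulate regional strain increments into a cumulative curve
#'
#' Running sum of per-pair regional mean strains, expressed in percent.
#' Invalid increments contribute zero (the running sum carries through) and
#' stay flagged; they are not interpolated.
#'
#' @param increments Numeric vector of per-pair regional mean strains (-).
#' @param valid Logical vector of per-pair validity flags.
#' @param t_min Numeric vector of pair midpoint times (minutes), strictly
#'   increasing.
#' @param label Sample or group identifier.
#' @return An object of class `oce_strain_curve`: a data frame with columns
#'   `t` (min), `increment`, `valid`, and `cum_strain` (%), plus a `label`
#'   attribute.
#' @export
accumulate_strain <- function(increments, valid = rep(TRUE, length(increments)),
                              t_min, label = "sample") {
  n <- length(increments)
  if (length(valid) != n || length(t_min) != n)
    stop("'increments', 'valid' and 't_min' must have equal length",
         call. = FALSE)
  if (any(diff(t_min) <= 0))
    stop("'t_min' must be strictly increasing", call. = FALSE)
  inc <- ifelse(valid & is.finite(increments), increments, 0)
  curve <- data.frame(t = t_min, increment = increments, valid = valid,
                      cum_strain = 100 * cumsum(inc))
  attr(curve, "label") <- label
  class(curve) <- c("oce_strain_curve", "data.frame")
  curve
}

#' Regional cumulative strain curve from a C-scan series
#'
#' Convenience pipeline: [incremental_strain_series()], [region_mean()] per
#' pair, then [accumulate_strain()]. The spatial regional mean is taken per
#' pair first and the means are then accumulated over time.
#'
#' @param frames List of [oce_volume()]s.
#' @param surf An `oce_surfaces` object.
#' @param region An [region_spec()].
#' @param params [processing_params()].
#' @param label Sample identifier.
#' @param ... Passed to [incremental_strain_series()].
#' @return An `oce_strain_curve`.
#' @export
strain_curve <- function(frames, surf, region = region_spec(),
                         params = processing_params(), label = "sample", ...) {
  maps <- incremental_strain_series(frames, params, ...)
  curve_from_maps(maps, surf, region, frames[[1]]$pitch_x * 1e6,
                  frames[[1]]$pitch_y * 1e6, label)
}

# cumulative curve from an already-computed incremental strain series
curve_from_maps <- function(maps, surf, region, pitch_x_um, pitch_y_um,
                            label = "sample") {
  inc <- numeric(length(maps))
  ok <- logical(length(maps))
  tm <- vapply(maps, function(m) attr(m, "t_mid_min"), numeric(1))
  for (k in seq_along(maps)) {
    ok[k] <- isTRUE(attr(maps[[k]], "pair_valid"))
    inc[k] <- if (ok[k]) {
      rm <- tryCatch(region_mean(maps[[k]], surf, region, pitch_x_um,
                                 pitch_y_um),
                     error = function(e) NULL)
      if (is.null(rm)) { ok[k] <- FALSE; 0 } else rm$mean
    } else 0
  }
  accumulate_strain(inc, ok, tm, label)
}

#' @export
print.oce_strain_curve <- function(x, ...) {
  cat(sprintf("Cumulative strain curve '%s': %d pairs over %.1f min, %d invalid\n",
              attr(x, "label") %||% "?", nrow(x), max(x$t), sum(!x$valid)))
  cat(sprintf("  final cumulative strain: %.2f%%\n", x$cum_strain[nrow(x)]))
  invisible(x)
}

#' @export
plot.oce_strain_curve <- function(x, ...,
                                  xlab = "time (min)",
                                  ylab = "cumulative axial strain (%)") {
  graphics::plot(x$t, x$cum_strain, type = "l", xlab = xlab, ylab = ylab, ...)
  if (any(!x$valid))
    graphics::points(x$t[!x$valid], x$cum_strain[!x$valid], pch = 4,
                     col = "red")
  invisible(x)
}

#' Depth-time strain map
#'
#' For each frame pair, the strain is averaged laterally over the central
#' window of the central B-scan, producing a 2-D map of strain versus axial
#' pixel (rows) and time (columns). Invalid pairs become fully masked (NA)
#' columns, the vertical-stripe artifacts of fluid application.
#'
#' @param maps List of per-pair strain maps from
#'   [incremental_strain_series()].
#' @param lateral_halfwidth_x Half-width (um) of the lateral window.
#' @param pitch_x_um Lateral pitch (um).
#' @param y_index B-scan index (default central).
#' @param cumulative If `TRUE`, columns are the running sum over valid pairs
#'   (cumulative strain); default shows per-pair incremental strain.
#' @return An object of class `oce_depth_time_map`: list with matrix `M`
#'   (`n_z` x pairs), `t_min`, and `pair_valid`.
#' @export
depth_time_map <- function(maps, lateral_halfwidth_x = 224, pitch_x_um = 12,
                           y_index = NULL, cumulative = FALSE) {
  if (!length(maps)) stop("empty strain series", call. = FALSE)
  d <- dim(maps[[1]]$data)
  y <- y_index %||% as.integer(ceiling(d[3] / 2))
  xs <- central_window(d[2], lateral_halfwidth_x, pitch_x_um)
  M <- matrix(NA_real_, d[1], length(maps))
  pv <- logical(length(maps))
  for (k in seq_along(maps)) {
    pv[k] <- isTRUE(attr(maps[[k]], "pair_valid"))
    if (!pv[k]) next
    e <- maps[[k]]$data[, xs, y, drop = FALSE]
    v <- maps[[k]]$valid[, xs, y, drop = FALSE]
    e[!v] <- NA
    M[, k] <- rowMeans(e[, , 1, drop = FALSE], na.rm = TRUE)
  }
  M[is.nan(M)] <- NA
  if (cumulative) {
    Z <- M
    Z[is.na(Z)] <- 0
    M <- t(apply(Z, 1, cumsum))
    M[, !pv] <- NA
  }
  structure(list(M = M,
                 t_min = vapply(maps, function(m) attr(m, "t_mid_min"),
                                numeric(1)),
                 pair_valid = pv),
            class = "oce_depth_time_map")
}

#' @export
print.oce_depth_time_map <- function(x, ...) {
  cat(sprintf("Depth-time strain map: %d depths x %d pairs (%d masked)\n",
              nrow(x$M), ncol(x$M), sum(!x$pair_valid)))
  invisible(x)
}

#' @export
plot.oce_depth_time_map <- function(x, ...,
                                    xlab = "time (min)",
                                    ylab = "axial pixel",
                                    col = grDevices::hcl.colors(64, "Blue-Red 3")) {
  graphics::image(x$t_min, seq_len(nrow(x$M)), t(x$M),
                  ylim = c(nrow(x$M), 1), xlab = xlab, ylab = ylab,
                  col = col, ...)
  invisible(x)
}

#' Difference between two cumulative strain curves
#'
#' Resamples curve `b` onto the time grid of curve `a` (linear interpolation
#' over the overlapping range) and subtracts pointwise, the construction used
#' to isolate a treatment effect from its control (treated minus control). A
#' point is valid where `a` is valid and both `b` neighbours used by the
#' interpolation are valid.
#'
#' @param a,b `oce_strain_curve` objects (`a - b`).
#' @param label Label of the returned curve.
#' @return An `oce_strain_curve` restricted to the overlapping time range
#'   (its `increment` column holds the differenced increments of `a`).
#' @export
difference_curve <- function(a, b, label = NULL) {
  t0 <- max(min(a$t), min(b$t))
  t1 <- min(max(a$t), max(b$t))
  if (t0 > t1)
    stop("curves do not overlap in time", call. = FALSE)
  keep <- a$t >= t0 - 1e-9 & a$t <= t1 + 1e-9
  tt <- a$t[keep]
  bi <- stats::approx(b$t, b$cum_strain, xout = tt, rule = 1)$y
  # validity of interpolated b: both bracketing source points valid
  lo <- findInterval(tt, b$t)
  lo <- pmin(pmax(lo, 1L), nrow(b))
  hi <- pmin(lo + 1L, nrow(b))
  at_node <- abs(b$t[lo] - tt) < 1e-9
  bv <- ifelse(at_node, b$valid[lo], b$valid[lo] & b$valid[hi])
  out <- data.frame(t = tt,
                    increment = a$increment[keep],
                    valid = a$valid[keep] & bv,
                    cum_strain = a$cum_strain[keep] - bi)
  attr(out, "label") <- label %||%
    paste0(attr(a, "label") %||% "a", " - ", attr(b, "label") %||% "b")
  class(out) <- c("oce_strain_curve", "data.frame")
  out
}
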
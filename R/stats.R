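# Segmented linear-regression slopes of cumulative strain curves and
# paired/unpaired t-test comparisons of slopes between groups.

#' Per-segment linear regression of a cumulative strain curve
#'
#' Splits the curve at the given minute bounds and fits an ordinary
#' least-squares line `cum_strain ~ t` to the valid points of each closed
#' segment. Default segments follow an 80-minute treatment protocol:
#' pre-treatment (1-20 min), irradiation (21-50 min), post-treatment
#' (51-80 min). Slopes are in percent strain per minute. Segments with fewer
#' than 3 valid points are flagged unfit and excluded from comparisons.
#'
#' @param curve An `oce_strain_curve` (or data frame with columns `t`,
#'   `cum_strain`, `valid`).
#' @param breaks List of 2-vectors `c(t0, t1)` (minutes), each a closed
#'   segment within the curve's time range.
#' @return An object of class `oce_segfit`: a data frame with one row per
#'   segment (`segment`, `t0`, `t1`, `slope`, `intercept`, `r2`, `n`, `ok`).
#' @examples
#' cv <- accumulate_strain(rep(0.0014, 80), t_min = 1:80)
#' coef(segment_slopes(cv))
#' @export
segment_slopes <- function(curve,
                           breaks = list(c(1, 20), c(21, 50), c(51, 80))) {
  if (!all(c("t", "cum_strain", "valid") %in% names(curve)))
    stop("'curve' must have columns t, cum_strain, valid", call. = FALSE)
  if (!length(breaks)) stop("'breaks' must be non-empty", call. = FALSE)
  rows <- lapply(breaks, function(b) {
    if (length(b) != 2L || b[2] <= b[1])
      stop("each break must be c(t0, t1) with t1 > t0", call. = FALSE)
    sel <- curve$valid & curve$t >= b[1] - 1e-9 & curve$t <= b[2] + 1e-9
    n <- sum(sel)
    if (n < 3L) {
      return(data.frame(segment = sprintf("%g-%g min", b[1], b[2]),
                        t0 = b[1], t1 = b[2], slope = NA_real_,
                        intercept = NA_real_, r2 = NA_real_, n = n,
                        ok = FALSE))
    }
    fit <- stats::lm(cum_strain ~ t, data = curve[sel, ])
    tss <- sum((curve$cum_strain[sel] - mean(curve$cum_strain[sel]))^2)
    r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
    data.frame(segment = sprintf("%g-%g min", b[1], b[2]),
               t0 = b[1], t1 = b[2],
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r2 = r2, n = n, ok = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "label") <- attr(curve, "label")
  class(out) <- c("oce_segfit", "data.frame")
  out
}

#' @export
coef.oce_segfit <- function(object, ...) {
  stats::setNames(object$slope, object$segment)
}

#' @export
print.oce_segfit <- function(x, ...) {
  cat(sprintf("Segment slopes%s (%% strain / min):\n",
              if (!is.null(attr(x, "label")))
                paste0(" for '", attr(x, "label"), "'") else ""))
  for (i in seq_len(nrow(x))) {
    if (x$ok[i])
      cat(sprintf("  %-12s m = %+.4f, r2 = %.4f, n = %d\n",
                  x$segment[i], x$slope[i], x$r2[i], x$n[i]))
    else
      cat(sprintf("  %-12s unfit (n = %d < 3 valid points)\n",
                  x$segment[i], x$n[i]))
  }
  invisible(x)
}

#' @export
summary.oce_segfit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Compare per-sample slopes between two groups
#'
#' Two-sided t-test on per-sample regression slopes: paired for within-group
#' comparisons of different segments of the same samples, two-sample
#' otherwise. Unpaired tests use Welch's correction by default; set
#' `var_equal = TRUE` for Student's pooled test. Differences are customarily
#' called significant at p < 0.05 (no multiple-testing correction is
#' applied). When both groups are constant and equal the t statistic is
#' undefined; this is reported as no difference (t = 0, p = 1) with a
#' warning.
#'
#' @param slopes_a,slopes_b Numeric vectors of per-sample slopes (%/min).
#' @param paired Paired test (requires equal lengths, matched order).
#' @param var_equal For unpaired tests, assume equal variances (Student)
#'   instead of Welch.
#' @param labels Character 2-vector naming the groups.
#' @param segment Optional segment label carried into the result.
#' @return An object of class `oce_slope_test`: list with `t`, `df`, `p`,
#'   `mean_a`, `mean_b`, `paired`, `method`, `labels`, `segment`.
#' @export
compare_slopes <- function(slopes_a, slopes_b, paired = FALSE,
                           var_equal = FALSE, labels = c("a", "b"),
                           segment = NA_character_) {
  slopes_a <- slopes_a[is.finite(slopes_a)]
  slopes_b <- slopes_b[is.finite(slopes_b)]
  if (length(slopes_a) < 2L || length(slopes_b) < 2L)
    stop("each group needs at least 2 finite slopes", call. = FALSE)
  if (paired && length(slopes_a) != length(slopes_b))
    stop("paired comparison requires equal sample counts", call. = FALSE)
  degenerate <- if (paired) {
    stats::sd(slopes_a - slopes_b) == 0 && mean(slopes_a - slopes_b) == 0
  } else {
    stats::sd(slopes_a) == 0 && stats::sd(slopes_b) == 0 &&
      mean(slopes_a) == mean(slopes_b)
  }
  if (degenerate) {
    warning("zero variance and equal means: t undefined, reported as no difference")
    res <- list(t = 0, df = NA_real_, p = 1)
    method <- "degenerate (no variance)"
  } else {
    tt <- stats::t.test(slopes_a, slopes_b, paired = paired,
                        var.equal = var_equal)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
    method <- tt$method
  }
  structure(list(t = res$t, df = res$df, p = res$p,
                 mean_a = mean(slopes_a), mean_b = mean(slopes_b),
                 sd_a = stats::sd(slopes_a), sd_b = stats::sd(slopes_b),
                 n_a = length(slopes_a), n_b = length(slopes_b),
                 paired = paired, method = method, labels = labels,
                 segment = segment,
                 slopes_a = slopes_a, slopes_b = slopes_b),
            class = "oce_slope_test")
}

#' @export
print.oce_slope_test <- function(x, ...) {
  cat(sprintf("Slope comparison %s vs %s%s (%s)\n", x$labels[1], x$labels[2],
              if (!is.na(x$segment)) paste0(", segment ", x$segment) else "",
              x$method))
  cat(sprintf("  m = %.3f +/- %.3f (n=%d) vs %.3f +/- %.3f (n=%d) %%/min\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  t = %.3f, df = %.2f, p = %.4g%s\n", x$t, x$df, x$p,
              if (is.finite(x$p) && x$p < 0.05) " (significant at 0.05)" else ""))
  invisible(x)
}
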
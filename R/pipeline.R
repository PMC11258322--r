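# End-to-end pipeline: group simulation -> strain processing -> regional
# curves -> segmented slope statistics, with YAML configuration and CSV/JSON
# outputs.

# scenario with its strain-rate profile scaled by a constant factor
scale_scenario <- function(scenario, factor) {
  base <- scenario$rate_profile
  deformation_scenario(scenario$name, scenario$duration,
                       scenario$frame_interval,
                       rate_profile = function(d, t) factor * base(d, t),
                       onset_time = scenario$onset_time,
                       affected_depth = scenario$affected_depth,
                       dropout_period = scenario$dropout_period,
                       dropout_duration = scenario$dropout_duration)
}

#' Simulate a treatment group of eyes and extract regional strain curves
#'
#' Simulates `n` independent eyes under one deformation scenario (each with
#' its own speckle and noise realisation) and computes the cumulative
#' regional strain curve of each. Optional per-eye scaling of the strain-rate
#' profile (`rate_scale_sd`) emulates biological variability between eyes.
#'
#' @param config [phantom_config()] template; each eye gets `seed + i`.
#' @param scenario [deformation_scenario()].
#' @param n Number of eyes.
#' @param region [region_spec()].
#' @param params [processing_params()].
#' @param seed Integer seed governing eye seeds and rate scaling.
#' @param rate_scale_sd Standard deviation of the per-eye multiplicative rate
#'   factor `1 + N(0, sd)` (0 = identical true rates).
#' @param label Group label.
#' @param keep_first_maps Keep the incremental strain maps of the first eye
#'   (for a representative depth-time map).
#' @return A list with `curves` (list of `oce_strain_curve`), `config`,
#'   `label`, and optionally `first_eye_maps`.
#' @export
simulate_group_curves <- function(config, scenario, n, region = region_spec(),
                                  params = processing_params(delta = config$delta * 1e-6),
                                  seed = config$seed, rate_scale_sd = 0,
                                  label = scenario$name,
                                  keep_first_maps = FALSE) {
  set.seed(seed)
  factors <- 1 + stats::rnorm(n, 0, rate_scale_sd)
  curves <- vector("list", n)
  first_maps <- NULL
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- as.integer((seed + 7919L * i) %% .Machine$integer.max)
    sc_i <- if (rate_scale_sd > 0) scale_scenario(scenario, factors[i])
            else scenario
    sim <- simulate_timeseries(cfg_i, sc_i, params, keep_fields = FALSE)
    surf <- surfaces_from_config(cfg_i)
    maps <- incremental_strain_series(sim$frames, params)
    curves[[i]] <- curve_from_maps(maps, surf, region,
                                   cfg_i$pitch_x, cfg_i$pitch_y,
                                   label = sprintf("%s_%02d", label, i))
    if (i == 1L && keep_first_maps) first_maps <- maps
  }
  list(curves = curves, config = config, label = label,
       first_eye_maps = first_maps)
}

#' Per-sample segment slopes for a group
#'
#' @param group Output of [simulate_group_curves()] (or a bare list of
#'   curves).
#' @param breaks Segment bounds, see [segment_slopes()].
#' @return Matrix of slopes, one row per sample, one column per segment.
#' @export
group_slopes <- function(group, breaks = list(c(1, 20), c(21, 50), c(51, 80))) {
  curves <- if (!is.null(group$curves)) group$curves else group
  s <- t(vapply(curves, function(cv) segment_slopes(cv, breaks)$slope,
                numeric(length(breaks))))
  colnames(s) <- vapply(breaks, function(b) sprintf("%g-%g min", b[1], b[2]),
                        character(1))
  s
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_oce_pipeline()]: phantom
#' geometry, scenario names for two groups, group size, processing and region
#' parameters, segment bounds, and the master seed. Unknown fields are
#' rejected; the configuration round-trips losslessly through YAML.
#'
#' @param seed Master integer seed.
#' @param groups Character vector of two [scenario_preset()] names.
#' @param n_per_group Eyes per group.
#' @param frame_interval Acquisition cadence (s).
#' @param rate_scale_sd Per-eye rate variability (see
#'   [simulate_group_curves()]).
#' @param phantom Named list of [phantom_config()] overrides (no seed).
#' @param processing Named list of [processing_params()] overrides.
#' @param region Named list of [region_spec()] overrides.
#' @param breaks List of segment bounds (2-vectors, minutes).
#' @return A list of class `oce_pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            groups = c("control_swelling", "cxl"),
                            n_per_group = 6L,
                            frame_interval = 60,
                            rate_scale_sd = 0.25,
                            phantom = list(),
                            processing = list(),
                            region = list(),
                            breaks = list(c(1, 20), c(21, 50), c(51, 80))) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (length(groups) != 2L)
    stop("'groups' must name exactly two scenarios", call. = FALSE)
  phantom_defaults <- list(n_z = 72L, n_x = 32L, n_y = 3L, delta = 16,
                           pitch_x = 12, pitch_y = 120,
                           anterior_apex_depth = 100, corneal_thickness = 800,
                           curvature_radius = Inf, snr_db = 25)
  bad <- setdiff(names(phantom), names(formals(phantom_config)))
  if (length(bad))
    stop("unknown phantom field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(names(processing), names(formals(processing_params)))
  if (length(bad))
    stop("unknown processing field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(names(region), names(formals(region_spec)))
  if (length(bad))
    stop("unknown region field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ph <- utils::modifyList(phantom_defaults, phantom)
  structure(list(seed = as.integer(seed), groups = as.character(groups),
                 n_per_group = as.integer(n_per_group),
                 frame_interval = frame_interval,
                 rate_scale_sd = rate_scale_sd, phantom = ph,
                 processing = processing, region = region,
                 breaks = lapply(breaks, as.numeric)),
            class = "oce_pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a validated
#'   `oce_pipeline_config`; [write_pipeline_config()] returns `path`
#'   invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config An `oce_pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full simulation-to-statistics pipeline
#'
#' Simulates the two configured treatment groups, computes each eye's
#' cumulative regional strain curve, fits segment slopes, and performs the
#' between-group (unpaired, per segment) and within-group (paired, segment
#' vs segment, first group named in the comparison) slope comparisons. When
#' `out_dir` is given, writes `curves.csv`, `slopes.csv`, `comparisons.csv`,
#' a depth-time map CSV of the first eye of each group, and a `manifest.json`
#' recording the package version, the configuration and its hash. Output is
#' deterministic for a fixed configuration (including its seed).
#'
#' @param config An [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list with `curves` (data frame), `slopes` (per group),
#'   `comparisons` (data frame), `depth_time` (per group), and `manifest`.
#' @export
run_oce_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "oce_pipeline_config"))
    stop("'config' must come from pipeline_config()", call. = FALSE)
  t_start <- proc.time()[["elapsed"]]
  ph <- do.call(phantom_config, c(config$phantom, list(seed = config$seed)))
  params <- do.call(processing_params,
                    utils::modifyList(list(delta = ph$delta * 1e-6),
                                      config$processing))
  region <- do.call(region_spec, config$region)
  timings <- c()

  groups <- list()
  dt_maps <- list()
  for (g in config$groups) {
    t0 <- proc.time()[["elapsed"]]
    sc <- scenario_preset(g, thickness = ph$corneal_thickness,
                          frame_interval = config$frame_interval)
    grp <- simulate_group_curves(
      ph, sc, config$n_per_group, region, params,
      seed = as.integer((config$seed + sum(utf8ToInt(g))) %%
                          .Machine$integer.max),
      rate_scale_sd = config$rate_scale_sd, label = g,
      keep_first_maps = TRUE)
    groups[[g]] <- grp
    dt_maps[[g]] <- depth_time_map(grp$first_eye_maps,
                                   pitch_x_um = ph$pitch_x)
    timings[g] <- proc.time()[["elapsed"]] - t0
  }

  curves_df <- do.call(rbind, lapply(unlist(lapply(groups, `[[`, "curves"),
                                            recursive = FALSE),
                                     function(cv) {
                                       cv$label <- attr(cv, "label")
                                       as.data.frame(cv)
                                     }))
  slopes <- lapply(groups, group_slopes, breaks = config$breaks)

  seg_names <- colnames(slopes[[1]])
  comp <- list()
  for (s in seq_along(seg_names)) {
    ct <- compare_slopes(slopes[[1]][, s], slopes[[2]][, s], paired = FALSE,
                         labels = config$groups, segment = seg_names[s])
    comp[[length(comp) + 1L]] <- data.frame(
      group_a = config$groups[1], group_b = config$groups[2],
      segment_a = seg_names[s], segment_b = seg_names[s], paired = FALSE,
      mean_a = ct$mean_a, mean_b = ct$mean_b, t = ct$t, df = ct$df, p = ct$p)
  }
  for (g in config$groups) {
    sl <- slopes[[g]]
    for (i in seq_along(seg_names)) for (j in seq_along(seg_names)) {
      if (j <= i) next
      ct <- compare_slopes(sl[, i], sl[, j], paired = TRUE,
                           labels = c(g, g), segment = NA)
      comp[[length(comp) + 1L]] <- data.frame(
        group_a = g, group_b = g, segment_a = seg_names[i],
        segment_b = seg_names[j], paired = TRUE,
        mean_a = ct$mean_a, mean_b = ct$mean_b, t = ct$t, df = ct$df,
        p = ct$p)
    }
  }
  comparisons <- do.call(rbind, comp)

  manifest <- list(package = "oceStrain",
                   version = as.character(utils::packageVersion("oceStrain")),
                   config = unclass(config),
                   timings_s = as.list(round(timings, 2)),
                   total_s = round(proc.time()[["elapsed"]] - t_start, 2))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(curves_df, file.path(out_dir, "curves.csv"),
                     row.names = FALSE)
    sl_df <- do.call(rbind, lapply(names(slopes), function(g) {
      df <- as.data.frame(slopes[[g]])
      df$group <- g
      df$sample <- seq_len(nrow(df))
      df
    }))
    utils::write.csv(sl_df, file.path(out_dir, "slopes.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    for (g in names(dt_maps)) {
      M <- dt_maps[[g]]$M
      colnames(M) <- sprintf("t%.1f", dt_maps[[g]]$t_min)
      utils::write.csv(M, file.path(out_dir, sprintf("depth_time_%s.csv", g)),
                       row.names = FALSE)
    }
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA, force = TRUE)
    tmp <- tempfile()
    writeLines(cfg_json, tmp)
    manifest$config_md5 <- unname(tools::md5sum(tmp))
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(list(curves = curves_df, slopes = slopes,
                 comparisons = comparisons, depth_time = dt_maps,
                 manifest = manifest))
}
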
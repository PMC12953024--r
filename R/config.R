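#' Read an experiment configuration (JSON or YAML)
#'
#' The schema mirrors [run_experiment()]: `kind` (one of cell-pace,
#' clamp-iv, apd-restitution, cable-cv, substrate, rotor), `iso`, `seed`,
#' `outdir`, optional `mods` (overrides for [bars_modifiers()]), optional
#' `curves` (`ec50`, `hill`, `alpha_max`), and kind-specific fields
#' (`pcl`, `n_beats`, `channel`, `density`, `delta`, `grid` with
#' `nx`/`ny`/`dx`/`sigma_l`/`sigma_t`, `duration_post_s2`, ...).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return Named list (class `experiment_config`).
#' @export
read_experiment_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  kinds <- c("cell-pace", "clamp-iv", "apd-restitution", "cable-cv",
             "substrate", "rotor")
  errs <- character(0)
  if (is.null(cfg$kind) || !cfg$kind %in% kinds)
    errs <- c(errs, sprintf("kind: must be one of %s",
                            paste(kinds, collapse = ", ")))
  if (!is.null(cfg$iso) && (!is.numeric(cfg$iso) || cfg$iso < 0))
    errs <- c(errs, "iso: must be a non-negative number (uM)")
  if (!is.null(cfg$seed) && !is.numeric(cfg$seed))
    errs <- c(errs, "seed: must be an integer")
  if (!is.null(cfg$mods) && !is.list(cfg$mods))
    errs <- c(errs, "mods: must be a named list of modifier overrides")
  if (length(errs))
    stop("invalid experiment config:\n  ", paste(errs, collapse = "\n  "))
  structure(cfg, class = c("experiment_config", class(cfg)))
}

config_grid <- function(cfg, default_nx = 25, default_ny = 1) {
  g <- cfg$grid
  build_sheet(nx = g$nx %||% default_nx, ny = g$ny %||% default_ny,
              dx = g$dx %||% 400,
              sigma_l = g$sigma_l %||% 0.1608,
              sigma_t = g$sigma_t %||% 0.0448)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured experiment end to end
#'
#' Dispatches to the matching protocol, writes all artifacts (trace /
#' curve CSVs, metric JSON, the resolved configuration) under
#' `cfg$outdir`, and returns a manifest. All randomness (substrate maps,
#' S2 search order) derives from `cfg$seed`.
#'
#' @param cfg An `experiment_config`, a plain named list, or a path.
#' @return Manifest list: `kind`, `outputs` (paths), `metrics`, and the
#'   resolved configuration.
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- read_experiment_config(cfg)
  cfg <- validate_config(cfg)
  outdir <- cfg$outdir %||% tempfile("ventbars_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  iso <- cfg$iso %||% 0
  seed <- as.integer(cfg$seed %||% 1)
  mods <- do.call(bars_modifiers, as.list(cfg$mods))
  curves <- do.call(dose_response_curves, as.list(cfg$curves))
  outputs <- list(); metrics <- list(); flags <- list()

  if (cfg$kind == "cell-pace") {
    p <- pace_to_steady_state(iso, pcl = cfg$pcl %||% 1000,
                              n_beats = cfg$n_beats %||% 1000,
                              curves = curves, mods = mods)
    f <- measure_features(p)
    metrics <- list(apd90_ms = f$apd90, peak_vm_mV = f$peak_vm,
                    resting_vm_mV = f$resting_vm,
                    max_upstroke_mV_ms = f$max_upstroke,
                    cat_amplitude_mM = f$cat_amplitude,
                    cat_duration_ms = f$cat_duration,
                    n_beats_run = p$n_beats, converged = p$converged)
    outputs$trace <- file.path(outdir, "final_beat.csv")
    write_cell_trace(p$trace, outputs$trace)
  } else if (cfg$kind == "clamp-iv") {
    iv <- voltage_clamp_iv(cfg$channel %||% "ICaL", iso = iso,
                           normalize = isTRUE(cfg$normalize),
                           n_precondition_beats = cfg$n_precondition_beats %||% 200,
                           curves = curves, mods = mods)
    outputs$iv <- file.path(outdir, "iv_curve.csv")
    write.csv(iv, outputs$iv, row.names = FALSE)
    metrics <- list(peak = min(iv$peak), peak_vm = iv$step_vm[which.min(iv$peak)])
  } else if (cfg$kind == "apd-restitution") {
    rc <- apd_restitution(iso, pcl_start = cfg$pcl_start %||% 2000,
                          n_beats = cfg$n_beats %||% 1000,
                          curves = curves, mods = mods)
    outputs$restitution <- file.path(outdir, "apd_restitution.csv")
    write.csv(rc, outputs$restitution, row.names = FALSE)
    metrics <- list(min_captured_pcl = min(rc$pcl[rc$captured]),
                    apd90_longest_pcl = rc$apd90[1])
  } else if (cfg$kind == "cable-cv") {
    grid <- config_grid(cfg)
    grid$sigma_l <- cfg$grid$sigma_l %||% 0.15
    grid$sigma_t <- cfg$grid$sigma_t %||% 0.07
    cal <- calibrate_conductivities(grid, target_cv = cfg$target_cv %||% 60)
    rc <- cv_restitution_cable(cal, iso = iso,
                               n_s1 = cfg$n_s1 %||% 20,
                               curves = curves, mods = mods)
    outputs$cv <- file.path(outdir, "cv_restitution.csv")
    write.csv(rc, outputs$cv, row.names = FALSE)
    metrics <- list(calibrated_cv = attr(cal, "cv"),
                    multiplier = attr(cal, "multiplier"),
                    cv_plateau = max(rc$cv[rc$captured], na.rm = TRUE),
                    cv_min = min(rc$cv[rc$captured], na.rm = TRUE))
  } else if (cfg$kind == "substrate") {
    grid <- config_grid(cfg, default_nx = 150, default_ny = 150)
    map <- if (!is.null(cfg$delta))
      assign_bars_gradient(grid, cfg$delta, seed = seed, iso = iso)
    else assign_bars_density(grid, cfg$density %||% 0.05, seed = seed,
                             iso = iso)
    outputs$map <- file.path(outdir, "bars_map.csv")
    write_bars_map(map, outputs$map)
    metrics <- list(n_flagged = sum(map$flag),
                    map_digest = unname(tools::md5sum(outputs$map)))
  } else if (cfg$kind == "rotor") {
    grid <- config_grid(cfg, default_nx = 150, default_ny = 150)
    map <- if (!is.null(cfg$map_path)) read_bars_map(cfg$map_path)
      else if (!is.null(cfg$density))
        assign_bars_density(grid, cfg$density, seed = seed, iso = iso)
      else NULL
    rec <- induce_rotor_s1s2(grid, barsmap = map, iso = iso,
                             duration_post_s2 = cfg$duration_post_s2 %||% 5000,
                             curves = curves, mods = mods)
    flags$reentry <- attr(rec, "reentry")
    metrics <- list(s2_delay_ms = attr(rec, "s2_delay"),
                    reentry = attr(rec, "reentry"))
    if (isTRUE(attr(rec, "reentry"))) {
      pf <- phase_frames(rec)
      tracks <- track_singularities(pf)
      win <- cfg$analysis_window %||% 4000
      if (length(tracks)) {
        metrics$angular_speed_hz <-
          suppressWarnings(angular_speed(tracks[[1]], rec, window = win))
        metrics$localization_area_mm2 <-
          suppressWarnings(as.numeric(localization_area(tracks[[1]],
                                                        window = win)))
        metrics$wavelet_count <- count_wavelets(tracks, times = pf$time)
      }
      if (length(tracks)) {
        outputs$tracks <- file.path(outdir, "ps_tracks.csv")
        write_ps_tracks(tracks, outputs$tracks)
      }
    }
  }

  resolved <- cfg
  resolved$mods <- unclass(mods)
  resolved$seed <- seed
  resolved$iso <- iso
  outputs$config <- file.path(outdir, "resolved_config.json")
  jsonlite::write_json(resolved, outputs$config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  outputs$metrics <- file.path(outdir, "metrics.json")
  jsonlite::write_json(metrics, outputs$metrics, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(kind = cfg$kind, outputs = outputs, metrics = metrics,
                   flags = flags, config = resolved)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
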
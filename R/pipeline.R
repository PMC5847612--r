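#' Pipeline configuration
#'
#' Nested configuration for the end-to-end run: a `sim` section (any
#' [sim_config()] argument), `kymo` (`band_halfwidth_px`), `border`
#' (`n_levels`), `steps` ([detect_change_points()] parameters) and
#' `track` (`sigma_um`, `min_intensity`, `max_disp_um`, `tol_um`,
#' `n_boundary_seeds`). Unknown keys are rejected. A `regime` preset
#' (`"control"` / `"clockless"`) seeds the `sim` section with the
#' printed study parameters before overrides are applied.
#'
#' @param seed mandatory integer seed (no wall-clock seeding).
#' @param regime optional [regime_preset()] name.
#' @param sim,kymo,border,steps,track per-stage override lists.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(seed, regime = NULL, sim = list(),
                            kymo = list(), border = list(), steps = list(),
                            track = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  allowed <- list(
    sim = names(formals(sim_config)),
    kymo = "band_halfwidth_px",
    border = "n_levels",
    steps = c("window_frames", "polyorder", "prominence_frac", "sign"),
    track = c("sigma_um", "min_intensity", "max_disp_um", "tol_um",
              "n_boundary_seeds")
  )
  sections <- list(sim = sim, kymo = kymo, border = border, steps = steps,
                   track = track)
  for (nm in names(sections)) {
    bad <- setdiff(names(sections[[nm]]), allowed[[nm]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in section '%s': %s", nm,
                   paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(regime)) {
    regime <- match.arg(regime, c("control", "clockless"))
  }
  defaults <- list(
    # boundary-seeded cells are the retrograde-tracking readout, so the
    # pipeline simulates them unless overridden
    sim = list(cells_on_boundaries = TRUE),
    kymo = list(band_halfwidth_px = 8L),
    border = list(n_levels = 9L),
    steps = list(window_frames = 5L, polyorder = 2L, prominence_frac = 0.25,
                 sign = "negative"),
    track = list(sigma_um = 2, min_intensity = 1, max_disp_um = 10,
                 tol_um = 5, n_boundary_seeds = 6L)
  )
  for (nm in names(defaults)) {
    merged <- defaults[[nm]]
    merged[names(sections[[nm]])] <- sections[[nm]]
    sections[[nm]] <- merged
  }
  structure(
    c(list(seed = as.integer(seed), regime = regime), sections),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML (or JSON)
#' @param path YAML or JSON config file with the [pipeline_config()]
#'   fields; `seed` is mandatory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$seed)) stop("config must specify a seed")
  do.call(pipeline_config, raw)
}

format_hhmm <- function(minutes) {
  m <- round(minutes)
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

sig9 <- function(x) {
  if (is.numeric(x)) signif(x, 9) else x
}

write_csv_sig <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), sig9))
  readr::write_csv(df, path)
  path
}

#' Run the full analysis pipeline on a simulated embryo
#'
#' Executes simulation, channel rendering, ratio computation, median
#' filtering, kymograph construction, isoline border extraction,
#' change-point detection, interval statistics, retrograde boundary-cell
#' tracking, border-overlap scoring, somite-size measurement and the
#' interval-size fit, writing every stage's tabular output (with
#' unit-bearing column names, values at 9 significant digits) plus a
#' reproducibility manifest to `out_dir`.
#'
#' @param config a [pipeline_config()] or a YAML/JSON path.
#' @param out_dir output directory (created).
#' @param write_movies also write the ratio and nuclei movies as 32-bit
#'   TIFF.
#' @return A `stepkymo_run` list with the stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, write_movies = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  cfg <- stage("simulate", {
    sim_args <- config$sim
    if (!is.null(config$regime)) {
      do.call(regime_preset, c(list(regime = config$regime), sim_args))
    } else {
      do.call(sim_config, sim_args)
    }
  })
  truth <- stage("ground_truth", build_truth(cfg, config$seed))
  channels <- stage("render", render_channels(truth, cfg))
  ratio <- stage("ratio", compute_ratio(channels$ypet, channels$cfp))
  filtered <- stage("median_filter", median_filter_frames(ratio, 15L))
  loi <- midline_loi(filtered, config$kymo$band_halfwidth_px)
  kym <- stage("kymograph", build_kymograph(filtered, loi))
  iso <- stage("isolines",
               extract_isolines(kym, kymo_levels(kym, config$border$n_levels)))
  border <- stage("border", select_border(iso))
  cps <- stage("change_points", do.call(detect_change_points,
    c(list(traj = border), config$steps)))
  dist <- stage("intervals", all_pairs_intervals(cps))
  seq_int <- sequential_intervals(cps)
  stats_seq <- interval_stats(seq_int)
  periodicity <- tryCatch(periodicity_estimate(dist), error = function(e) NULL)

  tk <- config$track
  seeds <- stage("seeds", {
    n_b <- min(tk$n_boundary_seeds,
               length(unique(truth$cell_tracks$cell_id)))
    final_frame <- max(truth$cell_tracks$frame)
    truth$cell_tracks |>
      dplyr::filter(.data$frame == final_frame) |>
      dplyr::slice_head(n = n_b) |>
      dplyr::select("x_um", "y_um")
  })
  detections <- stage("spots",
    detect_spots_movie(channels$nuclei, tk$sigma_um, tk$min_intensity))
  tracks <- stage("tracking",
    retrograde_track(detections, seeds, tk$max_disp_um))
  overlaps <- stage("overlap", border_overlap(tracks, border, tk$tol_um))
  somites <- stage("somites", somite_sizes_from_border(border, cps))
  fit <- tryCatch(interval_size_correlation(somites), error = function(e) NULL)

  stage("write", {
    write_truth(truth, out_dir)
    if (write_movies) {
      write_movie(ratio, file.path(out_dir, "ratio_movie.tif"))
      write_movie(channels$nuclei, file.path(out_dir, "nuclei_movie.tif"))
    }
    write_csv_sig(
      tibble::tibble(t_min = kym$t_min) |>
        dplyr::bind_cols(tibble::as_tibble(kym$data,
                                           .name_repair = ~ paste0(
                                             "pos_", kym$position_um, "_um"))),
      file.path(out_dir, "kymograph.csv"))
    write_csv_sig(
      border |>
        dplyr::mutate(time_label = format_hhmm(.data$t_min)) |>
        dplyr::rename(position_um = "position_um",
                      velocity_um_per_min = "velocity_um_min"),
      file.path(out_dir, "border_trajectory.csv"))
    write_csv_sig(
      cps |> dplyr::mutate(time_label = format_hhmm(.data$time_min)),
      file.path(out_dir, "change_points.csv"))
    write_csv_sig(dplyr::rename(dist, lag_steps = "lag"),
                  file.path(out_dir, "intervals_all_pairs.csv"))
    write_csv_sig(tibble::as_tibble(tracks), file.path(out_dir, "tracks.csv"))
    write_csv_sig(dplyr::select(overlaps, -"windows"),
                  file.path(out_dir, "overlaps.csv"))
    write_csv_sig(somites, file.path(out_dir, "somites.csv"))
    stats_out <- list(
      border_level = sig9(attr(border, "level")),
      border_velocity_variance = sig9(attr(border, "velocity_variance")),
      sequential_intervals = list(
        mean_min = sig9(stats_seq$mean_min), sd_min = sig9(stats_seq$sd_min),
        cv = sig9(stats_seq$cv), n = stats_seq$n),
      periodicity = if (!is.null(periodicity)) lapply(as.list(periodicity), sig9),
      somite_size = if (nrow(somites) >= 2) {
        ss <- interval_stats(somites$size_um)
        list(mean_um = sig9(ss$mean_min), sd_um = sig9(ss$sd_min),
             cv = sig9(ss$cv), n = ss$n)
      },
      interval_size_fit = if (!is.null(fit)) list(
        slope_um_per_min = sig9(fit$slope), intercept_um = sig9(fit$intercept),
        pearson_r = sig9(fit$pearson_r), n = fit$n)
    )
    jsonlite::write_json(stats_out[!vapply(stats_out, is.null, logical(1))],
                         file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    TRUE
  })

  resolved <- unclass(config)
  resolved$sim <- unclass(cfg)
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    tool = "stepkymo",
    version = as.character(utils::packageVersion("stepkymo")),
    seed = config$seed,
    regime = config$regime,
    outputs = as.list(unname(tools::md5sum(file.path(out_dir, outputs)))) |>
      stats::setNames(outputs),
    timings_s = lapply(timings, function(x) round(x, 3))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(
    list(config = config, sim_config = cfg, truth = truth, kymograph = kym,
         isolines = iso, border = border, change_points = cps,
         intervals = dist, interval_stats = stats_seq,
         periodicity = periodicity, tracks = tracks, overlaps = overlaps,
         somites = somites, fit = fit, manifest = manifest,
         out_dir = out_dir),
    class = "stepkymo_run"
  )
}

#' @export
print.stepkymo_run <- function(x, ...) {
  cat(sprintf(
    "<stepkymo_run> %d change-points, interval mean %.1f min (CV %.2f), %d somites\n",
    nrow(x$change_points), x$interval_stats$mean_min, x$interval_stats$cv,
    nrow(x$somites)))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
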
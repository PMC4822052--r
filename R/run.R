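#' Read a JSON run configuration
#'
#' @param path JSON file with at least an `assay` field
#'   (`simulate|golgi|perox|sliding|smtracks|compare`) and the assay's
#'   parameters.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

assay_defaults <- list(
  golgi = list(extend_px = 10, region = "full", sd_type = "population",
               channels = c("golgi", "nucleus")),
  perox = list(window_px = 15L, min_size_px = 4L, t_treat_s = 0),
  sliding = list(min_points = 4L),
  smtracks = list(min_lifetime_s = 0.5, overlap_tol_px = 1L, r_min_nm = 250,
                  n_boot = 2000L, truncation = "shifted")
)

merge_config <- function(config, defaults) {
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

write_manifest <- function(config, out_dir) {
  jsonlite::write_json(config, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run an assay pipeline from a configuration
#'
#' Single entry point binding every assay: validates the configuration,
#' executes the pipeline, writes result files into `out_dir` and echoes the
#' merged configuration (defaults filled in) into `manifest.json` beside
#' them, so that any output is reproducible from its manifest alone.
#'
#' Assays and their required fields:
#' \describe{
#'   \item{simulate}{`scenario` (`golgi|perox|sliding|trajectories`), `seed`;
#'     generator parameters are passed through `params`. Writes TIFF/CSV
#'     data plus a `truth.json` sidecar.}
#'   \item{golgi}{`image`, `pixel_size_nm`, `roi` (CSV of polygon vertices
#'     `col,row`, rasterized even-odd). Writes `golgi.csv`.}
#'   \item{perox}{`movie`, `pixel_size_nm`, `frame_interval_s`, `centre_nm`
#'     (`c(x, y)`), `t_treat_s`. Writes `perox_series.csv`.}
#'   \item{sliding}{`movie`, `pixel_size_nm`, `frame_interval_s`. Writes
#'     `sliding_series.csv` and `sliding_rate.csv`.}
#'   \item{smtracks}{`tracks` (CSV), `mt_mask` (TIFF), `pixel_size_nm`,
#'     `duration_min`, `seed`. Writes `event_stats.csv` and `events.csv`.}
#'   \item{compare}{`freqs_minus`, `freqs_plus` (numeric vectors). Writes
#'     `comparison.json`.}
#' }
#'
#' @param config named list (see [read_run_config()]).
#' @param out_dir output directory, created if missing.
#' @return the computed result object, invisibly.
#' @export
run_assay <- function(config, out_dir = config$out_dir) {
  if (is.null(config$assay)) stop("config must name an assay", call. = FALSE)
  if (is.null(out_dir)) stop("config must name an output directory", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  result <- switch(
    config$assay,
    simulate = run_simulate(config, out_dir),
    golgi = run_golgi(config, out_dir),
    perox = run_perox(config, out_dir),
    sliding = run_sliding(config, out_dir),
    smtracks = run_smtracks(config, out_dir),
    compare = run_compare(config, out_dir),
    stop(sprintf("unknown assay '%s'", config$assay), call. = FALSE)
  )
  invisible(result)
}

run_simulate <- function(config, out_dir) {
  scenario <- config$scenario
  seed <- config$seed %||% 1L
  params <- config$params %||% list()
  if (is.null(scenario)) stop("simulate needs a scenario", call. = FALSE)
  if (scenario == "golgi") {
    res <- do.call(gen_golgi_scene, c(params, list(seed = seed)))
    write_image_stack(res$stack, file.path(out_dir, "scene.tif"))
  } else if (scenario == "perox") {
    res <- do.call(gen_perox_movie, c(params, list(seed = seed)))
    write_image_stack(res$stack, file.path(out_dir, "movie.tif"))
  } else if (scenario == "sliding") {
    res <- do.call(gen_sliding_movie, c(params, list(seed = seed)))
    write_image_stack(res$stack, file.path(out_dir, "movie.tif"))
  } else if (scenario == "trajectories") {
    res <- do.call(gen_trajectories, c(params, list(seed = seed)))
    write_trajectory_table(res$tset, file.path(out_dir, "tracks.csv"))
    write_mask(res$mt_mask, file.path(out_dir, "mt_mask.tif"))
  } else {
    stop(sprintf("unknown scenario '%s'", scenario), call. = FALSE)
  }
  write_truth(res$truth, file.path(out_dir, "truth.json"))
  config$params <- params
  config$seed <- seed
  write_manifest(config, out_dir)
  res
}

#' Rasterize a polygon ROI file
#'
#' Reads a CSV with columns `col,row` (polygon vertices in pixel units) and
#' rasterizes it even-odd onto a grid.
#'
#' @param path vertex CSV.
#' @param dim_rc `c(rows, cols)` of the target plane.
#' @return a [BinaryMask].
#' @export
read_roi_polygon <- function(path, dim_rc) {
  v <- utils::read.csv(path)
  if (!all(c("col", "row") %in% names(v))) {
    stop("ROI file needs columns col,row", call. = FALSE)
  }
  BinaryMask(rasterize_polygon(cbind(v$row, v$col), dim_rc), "roi")
}

run_golgi <- function(config, out_dir) {
  config <- merge_config(config, assay_defaults$golgi)
  stack <- read_image_stack(config$image, config$pixel_size_nm,
                            channel_names = config$channels)
  roi <- read_roi_polygon(config$roi, dim(stack$data)[3:4])
  meas <- golgi_dispersion(stack, roi, cell_id = config$cell_id %||% "cell",
                           extend_px = config$extend_px,
                           region = config$region, sd_type = config$sd_type,
                           golgi_channel = config$channels[1],
                           nucleus_channel = config$channels[2])
  write_table(list(meas), file.path(out_dir, "golgi.csv"))
  write_manifest(config, out_dir)
  meas
}

run_perox <- function(config, out_dir) {
  config <- merge_config(config, assay_defaults$perox)
  movie <- read_image_stack(config$movie, config$pixel_size_nm,
                            config$frame_interval_s, c("561", "488"))
  series <- perox_time_series(movie, unlist(config$centre_nm),
                              window_px = config$window_px,
                              offset = config$offset,
                              min_size_px = config$min_size_px,
                              t_treat_s = config$t_treat_s)
  write_table(as.data.frame(series), file.path(out_dir, "perox_series.csv"))
  write_manifest(config, out_dir)
  series
}

run_sliding <- function(config, out_dir) {
  config <- merge_config(config, assay_defaults$sliding)
  movie <- read_image_stack(config$movie, config$pixel_size_nm,
                            config$frame_interval_s, "photoconverted")
  zone <- if (!is.null(config$zone)) read_mask(config$zone, "initial_zone")
  series <- sliding_pipeline(movie, initial_zone = zone,
                             min_points = config$min_points)
  write_table(as.data.frame(series), file.path(out_dir, "sliding_series.csv"))
  write_table(data.frame(rate_pct_per_min = series$rate_pct_per_min,
                         r2 = series$r2, window_start = series$window[1],
                         window_end = series$window[2],
                         n_points = series$n_points),
              file.path(out_dir, "sliding_rate.csv"))
  write_manifest(config, out_dir)
  series
}

run_smtracks <- function(config, out_dir) {
  config <- merge_config(config, assay_defaults$smtracks)
  if (is.null(config$seed)) stop("smtracks needs a seed for the bootstrap",
                                 call. = FALSE)
  tset <- read_trajectory_table(config$tracks,
                                movie_duration_s = config$duration_min * 60,
                                pixel_size_nm = config$pixel_size_nm)
  mask <- read_mask(config$mt_mask, "microtubule")
  kept <- filter_tracks(tset, mask, config$min_lifetime_s,
                        config$overlap_tol_px)
  events <- classify_events(kept, r_min_nm = config$r_min_nm)
  mt_um <- mt_total_length(mask, config$pixel_size_nm)
  stats <- summarize_events(events, mt_um, config$duration_min,
                            n_boot = config$n_boot, seed = config$seed,
                            r_min_nm = config$r_min_nm,
                            truncation = config$truncation)
  write_table(events, file.path(out_dir, "events.csv"))
  write_table(as.data.frame(stats), file.path(out_dir, "event_stats.csv"))
  write_manifest(config, out_dir)
  stats
}

run_compare <- function(config, out_dir) {
  cmp <- compare_conditions(unlist(config$freqs_minus),
                            unlist(config$freqs_plus),
                            config$per_cell_minus, config$per_cell_plus)
  jsonlite::write_json(unclass(cmp), file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, out_dir)
  cmp
}
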
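#' Pipeline configuration
#'
#' Bundles acquisition constants and per-stage parameters for
#' [run_pipeline()]. Defaults are the standard analysis settings: 2 Hz
#' acquisition, 30 s baseline, F0 over the first 10 frames, 2 SD amplitude
#' threshold with a < 1 s rise time, and NH4Cl pool counting with overlap
#' correction.
#'
#' @param stim stimulation protocol ([stim_protocol()]).
#' @param nh4cl_window `(start_s, end_s)` of the ammonium pulse.
#' @param pre_window pre-pulse reference window for pool detection; defaults
#'   to the baseline before stimulation.
#' @param n_baseline_frames frames averaged into F0.
#' @param roi_size ROI side, pixels (odd).
#' @param smoothing_sigma,min_separation,roi_threshold_sd [place_rois()]
#'   parameters.
#' @param threshold_sd,max_rise,median_prefilter,sigma_floor
#'   [detect_events()] parameters.
#' @param dog_sigmas,pool_threshold_sd,area_range [detect_puncta()]
#'   parameters.
#' @param rng_seed seed recorded in the manifest.
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(stim = stim_protocol(),
                            nh4cl_window = c(100, 120),
                            pre_window = NULL,
                            n_baseline_frames = 10, roi_size = 3,
                            smoothing_sigma = 1, min_separation = 4,
                            roi_threshold_sd = 5,
                            threshold_sd = 2, max_rise = 1,
                            median_prefilter = 3, sigma_floor = 0.01,
                            dog_sigmas = c(1, 3), pool_threshold_sd = 4,
                            area_range = c(4, 400), rng_seed = 1) {
  if (is.null(pre_window)) pre_window <- c(0, stim$start_time)
  stopifnot(threshold_sd > 0, max_rise > 0, roi_threshold_sd > 0,
            pool_threshold_sd > 0, roi_size %% 2 == 1,
            nh4cl_window[1] < nh4cl_window[2])
  if (nh4cl_window[1] < stim$start_time + stim_span(stim))
    warning("NH4Cl window begins before stimulation ends")
  structure(list(stim = stim, nh4cl_window = nh4cl_window,
                 pre_window = pre_window,
                 n_baseline_frames = n_baseline_frames, roi_size = roi_size,
                 smoothing_sigma = smoothing_sigma,
                 min_separation = min_separation,
                 roi_threshold_sd = roi_threshold_sd,
                 threshold_sd = threshold_sd, max_rise = max_rise,
                 median_prefilter = median_prefilter,
                 sigma_floor = sigma_floor, dog_sigmas = dog_sigmas,
                 pool_threshold_sd = pool_threshold_sd,
                 area_range = area_range, rng_seed = rng_seed),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()] and
#' [stim_protocol()] (the latter nested under `stim:`). Unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  stim_args <- raw$stim %||% list()
  bad <- setdiff(names(stim_args), names(formals(stim_protocol)))
  if (length(bad)) stop("unknown stim config keys: ",
                        paste(bad, collapse = ", "))
  raw$stim <- NULL
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config,
          c(list(stim = do.call(stim_protocol, stim_args)), raw))
}

#' Run the fusion-and-pool pipeline on one neuron's movie
#'
#' Orchestrates ROI placement, trace extraction, event detection, the
#' per-neuron summary, NH4Cl pool counting with overlap correction, and the
#' released fraction. The released fraction uses the evoked events — those
#' whose peak falls inside the stimulation window — since DCV fusion in this
#' assay is stimulation-locked and detections outside that window are
#' overwhelmingly noise. When `out_dir` is given, writes `events.csv`,
#' `pool.csv`, `summary.json` and a `manifest.json` recording the package
#' version, configuration and seed so the run is reproducible from its
#' outputs alone.
#'
#' @param movie a [Movie], or a path to a TIFF stack readable by
#'   [read_stack()].
#' @param config a [pipeline_config()].
#' @param rois optional matrix of 0-based `(row, col)` ROI centers,
#'   bypassing [place_rois()].
#' @param out_dir optional output directory.
#' @return list with `rois`, `events` (with `roi_id`), `summary`, `pool`
#'   (a `PoolEstimate`), and `released` (a `ReleasedFraction`, or `NULL`
#'   with a `note` when the pool is empty).
#' @export
run_pipeline <- function(movie, config = pipeline_config(), rois = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.character(movie)) movie <- read_stack(movie)
  stage <- "place_rois"
  res <- tryCatch({
    if (is.null(rois))
      rois <- place_rois(movie, config$stim, config$smoothing_sigma,
                         config$min_separation, config$roi_threshold_sd,
                         config$roi_size)
    stage <- "detect_events"
    ev_list <- lapply(seq_len(nrow(rois)), function(i) {
      tr <- extract_trace(movie, rois[i, ], config$roi_size,
                          config$n_baseline_frames)
      ev <- detect_events(tr, c(0, config$stim$start_time),
                          config$threshold_sd, config$max_rise,
                          config$median_prefilter, config$sigma_floor,
                          search_window = c(0, config$nh4cl_window[1]))
      if (nrow(ev)) cbind(roi_id = i, ev) else NULL
    })
    events <- do.call(rbind, ev_list)
    if (is.null(events)) events <- cbind(roi_id = integer(), empty_events())
    stage <- "summarize_events"
    summ <- summarize_events(events, n_frames(movie), config$stim,
                             frame_interval(movie))
    stage <- "detect_puncta"
    pool <- detect_puncta(movie, config$nh4cl_window, config$pre_window,
                          config$dog_sigmas, config$pool_threshold_sd,
                          config$area_range)
    stage <- "corrected_pool_count"
    pool <- corrected_pool_count(pool)
    stage <- "released_fraction"
    n_evoked <- unname(summ$events_per_window["stim"])
    released <- if (pool$corrected_count > 0)
      released_fraction(n_evoked, pool$corrected_count) else NULL
    list(rois = rois, events = events, summary = summ, pool = pool,
         released = released,
         note = if (is.null(released)) "empty pool: no released fraction"
                else NULL)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir)
  res
}

write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(res$pool$components, file.path(out_dir, "pool.csv"),
                   row.names = FALSE)
  summary <- list(
    n_events = res$summary$n_events,
    mean_peak_ratio = res$summary$mean_peak_ratio,
    events_per_window = as.list(res$summary$events_per_window),
    pool_raw = res$pool$raw_count,
    pool_corrected = res$pool$corrected_count,
    released_fraction = if (!is.null(res$released))
      res$released$fraction else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg_plain <- unclass(config)
  cfg_plain$stim <- unclass(cfg_plain$stim)
  manifest <- list(
    package = "dcvflux",
    version = as.character(utils::packageVersion("dcvflux")),
    rng_seed = config$rng_seed,
    config = cfg_plain,
    config_hash = unname(config_hash(cfg_plain)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  as.character(tools::md5sum(f))
}
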
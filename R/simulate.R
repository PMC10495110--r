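#' Electric-field stimulation protocol
#'
#' Describes a train-burst stimulation paradigm. The default reproduces the
#' standard DCV-fusion paradigm: 16 trains of 50 pulses at 50 Hz, trains
#' separated by 500 ms, starting after 30 s of baseline.
#'
#' @param n_trains number of trains.
#' @param pulses_per_train pulses per train.
#' @param pulse_frequency pulse frequency within a train, Hz.
#' @param inter_train_interval gap between trains, seconds.
#' @param start_time stimulation onset, seconds from recording start.
#' @return a `StimProtocol` object with a `stim_span()` in seconds.
#' @examples
#' sp <- stim_protocol()
#' stim_span(sp)   # 16 * 1 s + 15 * 0.5 s = 23.5 s
#' @export
stim_protocol <- function(n_trains = 16, pulses_per_train = 50,
                          pulse_frequency = 50, inter_train_interval = 0.5,
                          start_time = 30) {
  stopifnot(n_trains > 0, pulses_per_train > 0, pulse_frequency > 0,
            inter_train_interval > 0, start_time > 0)
  structure(list(n_trains = n_trains, pulses_per_train = pulses_per_train,
                 pulse_frequency = pulse_frequency,
                 inter_train_interval = inter_train_interval,
                 start_time = start_time),
            class = "StimProtocol")
}

#' @rdname stim_protocol
#' @param x a `StimProtocol`.
#' @return `stim_span()`: total stimulation duration in seconds.
#' @export
stim_span <- function(x) {
  x$n_trains * (x$pulses_per_train / x$pulse_frequency) +
    (x$n_trains - 1) * x$inter_train_interval
}

#' @rdname stim_protocol
#' @return `stim_window()`: `(start_s, end_s)` of the stimulation period.
#' @export
stim_window <- function(x) c(x$start_time, x$start_time + stim_span(x))

#' Simulation configuration for pHluorin fusion movies
#'
#' Collects the acquisition constants and the scene description for
#' [simulate_fusion_movie()]. Defaults mirror the live-imaging conditions the
#' pipeline targets: 2 Hz acquisition for 2 min, 30 s baseline, then the
#' train-burst stimulation of [stim_protocol()].
#'
#' @param image_shape `(rows, cols)` in pixels.
#' @param frame_interval seconds per frame.
#' @param n_frames number of frames.
#' @param pixel_size micrometers per pixel.
#' @param stim stimulation protocol ([stim_protocol()]); its `start_time` is
#'   the baseline duration.
#' @param n_puncta number of pHluorin puncta scattered on the neurite.
#' @param punctum_sigma Gaussian spot width, pixels.
#' @param punctum_amplitude peak brightness of a punctum above background, a.u.
#' @param background uniform background level, a.u.
#' @param puncta_positions optional matrix of 0-based `(row, col)` centers;
#'   randomly placed with `min_separation` otherwise.
#' @param min_separation minimum center-to-center distance for random
#'   placement, pixels.
#' @param event_table data frame with columns `punctum_id` (1-based index
#'   into the puncta), `onset_s`, `peak_ratio` (>= 1), `rise_s`,
#'   `decay_tau_s`. May have zero rows.
#' @param nh4cl_window `(start_s, end_s)` of the NH4Cl dequench pulse, or
#'   `NULL` for none.
#' @param dequench_factor multiplicative brightening of every punctum during
#'   the NH4Cl window (>= 1).
#' @param noise_gaussian_sd additive Gaussian (read) noise SD, a.u.
#' @param noise_poisson_scale Poisson (shot) noise scale, a.u.; 0 disables.
#'   The noisy signal is `rpois(signal / scale) * scale`.
#' @param rng_seed integer seed; the same config and seed give bit-identical
#'   stacks.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(image_shape = c(64, 64), frame_interval = 0.5,
                       n_frames = 240, pixel_size = 0.2,
                       stim = stim_protocol(),
                       n_puncta = 20, punctum_sigma = 1.2,
                       punctum_amplitude = 600, background = 10,
                       puncta_positions = NULL, min_separation = 5,
                       event_table = NULL,
                       nh4cl_window = NULL, dequench_factor = 2,
                       noise_gaussian_sd = 0, noise_poisson_scale = 0,
                       rng_seed = 1) {
  stopifnot(frame_interval > 0, n_frames > 1, dequench_factor >= 1,
            punctum_sigma > 0, punctum_amplitude >= 0, background >= 0,
            noise_gaussian_sd >= 0, noise_poisson_scale >= 0)
  if (is.null(event_table))
    event_table <- data.frame(punctum_id = integer(), onset_s = numeric(),
                              peak_ratio = numeric(), rise_s = numeric(),
                              decay_tau_s = numeric())
  total_s <- n_frames * frame_interval
  if (nrow(event_table)) {
    need <- c("punctum_id", "onset_s", "peak_ratio", "rise_s", "decay_tau_s")
    stopifnot(all(need %in% names(event_table)))
    if (any(event_table$punctum_id < 1 | event_table$punctum_id > n_puncta))
      stop("event references unknown punctum id")
    if (any(event_table$onset_s < 0 | event_table$onset_s >= total_s))
      stop("event onset outside the recording")
    if (any(event_table$rise_s >= total_s))
      stop("event rise time exceeds the recording")
    if (any(event_table$peak_ratio < 1)) stop("peak_ratio must be >= 1")
  }
  if (!is.null(nh4cl_window)) {
    stopifnot(length(nh4cl_window) == 2, nh4cl_window[1] < nh4cl_window[2])
    if (nrow(event_table)) {
      decay_end <- event_table$onset_s + event_table$rise_s +
        3 * event_table$decay_tau_s
      if (any(decay_end > nh4cl_window[1]))
        warning("NH4Cl window overlaps an event decay; simulation proceeds")
    }
  }
  structure(list(image_shape = image_shape, frame_interval = frame_interval,
                 n_frames = n_frames, pixel_size = pixel_size, stim = stim,
                 n_puncta = n_puncta, punctum_sigma = punctum_sigma,
                 punctum_amplitude = punctum_amplitude,
                 background = background,
                 puncta_positions = puncta_positions,
                 min_separation = min_separation,
                 event_table = event_table, nh4cl_window = nh4cl_window,
                 dequench_factor = dequench_factor,
                 noise_gaussian_sd = noise_gaussian_sd,
                 noise_poisson_scale = noise_poisson_scale,
                 rng_seed = rng_seed),
            class = "SimConfig")
}

# Random (row, col) centers with a minimum pairwise distance, kept away from
# the image border so a 3x3 ROI always fits. 0-based.
place_puncta <- function(shape, n, min_sep, margin = 3) {
  pos <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(pos) < n && tries < 20000) {
    cand <- c(stats::runif(1, margin, shape[1] - 1 - margin),
              stats::runif(1, margin, shape[2] - 1 - margin))
    if (nrow(pos) == 0 ||
        min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >= min_sep)
      pos <- rbind(pos, cand)
    tries <- tries + 1
  }
  if (nrow(pos) < n)
    stop("could not place ", n, " puncta with min_separation ", min_sep)
  dimnames(pos) <- NULL
  pos
}

# Rows x cols Gaussian spot image, unit peak amplitude, 0-based center.
gaussian_spot <- function(shape, center, sigma) {
  r <- outer((seq_len(shape[1]) - 1 - center[1])^2,
             (seq_len(shape[2]) - 1 - center[2])^2, "+")
  exp(-r / (2 * sigma^2))
}

# Per-frame brightness multiplier of one punctum: 1 at rest, a linear ramp
# of duration rise_s up to peak_ratio at event onset, then exponential decay
# of the increment with decay_tau_s. Multiple events add their increments.
event_profile <- function(times, events) {
  m <- rep(1, length(times))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    dt <- times - e$onset_s
    inc <- numeric(length(times))
    if (e$rise_s > 0) {
      ramp <- dt > 0 & dt < e$rise_s
      inc[ramp] <- (e$peak_ratio - 1) * dt[ramp] / e$rise_s
    }
    post <- dt >= e$rise_s
    inc[post] <- (e$peak_ratio - 1) * exp(-(dt[post] - e$rise_s) /
                                            e$decay_tau_s)
    m <- m + inc
  }
  m
}

add_camera_noise <- function(arr, gaussian_sd, poisson_scale) {
  if (poisson_scale > 0)
    arr[] <- stats::rpois(length(arr), pmax(arr, 0) / poisson_scale) *
      poisson_scale
  if (gaussian_sd > 0)
    arr[] <- arr + stats::rnorm(length(arr), 0, gaussian_sd)
  pmax(arr, 0)
}

#' Simulate an NPY-pHluorin fusion movie with known ground truth
#'
#' Renders sparse Gaussian puncta on a dim background. Each fusion event
#' multiplies its punctum's brightness by `peak_ratio` through a linear ramp
#' of duration `rise_s`, followed by exponential decay of the increment with
#' `decay_tau_s`. During the NH4Cl window every punctum is additionally
#' multiplied by `dequench_factor` (the ammonium pulse neutralizes all
#' vesicle lumina at once). Shot noise (Poisson) is applied to the signal,
#' then additive Gaussian read noise.
#'
#' @param config a [sim_config()].
#' @return list with `movie` (a [Movie]) and `truth`, itself a list of
#'   `puncta` (`punctum_id`, 0-based `row`, `col`) and `events` (the realized
#'   event table).
#' @examples
#' cfg <- sim_config(n_puncta = 5, n_frames = 40, noise_gaussian_sd = 0)
#' sim <- simulate_fusion_movie(cfg)
#' sim$movie
#' @export
simulate_fusion_movie <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$rng_seed)
  shape <- config$image_shape
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  pos <- config$puncta_positions
  if (is.null(pos) && config$n_puncta > 0)
    pos <- place_puncta(shape, config$n_puncta, config$min_separation)
  n_p <- if (is.null(pos)) 0L else nrow(pos)

  # spots as an (npx x P) matrix so every frame is one matrix product
  S <- matrix(0, prod(shape), n_p)
  for (p in seq_len(n_p))
    S[, p] <- as.vector(gaussian_spot(shape, pos[p, ], config$punctum_sigma))

  Fmat <- matrix(1, n_p, config$n_frames)   # per-punctum, per-frame factor
  ev <- config$event_table
  for (p in seq_len(n_p)) {
    evp <- ev[ev$punctum_id == p, , drop = FALSE]
    if (nrow(evp)) Fmat[p, ] <- event_profile(times, evp)
  }
  if (!is.null(config$nh4cl_window)) {
    inw <- times >= config$nh4cl_window[1] & times < config$nh4cl_window[2]
    Fmat[, inw] <- Fmat[, inw] * config$dequench_factor
  }
  arr <- array(config$background, c(shape, config$n_frames))
  if (n_p > 0)
    arr <- arr + array(config$punctum_amplitude * (S %*% Fmat),
                       c(shape, config$n_frames))
  arr <- add_camera_noise(arr, config$noise_gaussian_sd,
                          config$noise_poisson_scale)
  truth <- list(
    puncta = data.frame(punctum_id = seq_len(n_p),
                        row = if (n_p) pos[, 1] else numeric(),
                        col = if (n_p) pos[, 2] else numeric()),
    events = ev)
  movie <- Movie(arr, config$frame_interval, config$pixel_size)
  attr(movie, "nh4cl_window") <- config$nh4cl_window
  list(movie = movie, truth = truth)
}

#' Simulate a RUSH Golgi-flux movie
#'
#' The Golgi region is a Gaussian blob whose mean intensity, normalized to
#' the pre-biotin baseline, follows: 1 before biotin addition (t <= 0), a
#' linear rise to `peak_value` at `t_peak_true`, then
#' `peak_value * (plateau + (1 - plateau) * exp(-k_true * (t - t_peak_true)))`
#' — i.e. a first-order decay from the peak toward `plateau` (expressed as a
#' fraction of the peak). The whole frame can drift laterally by a constant
#' per-frame translation, emulating stage drift over a 2 h recording.
#'
#' @param k_true export rate constant, per minute (> 0).
#' @param t_peak_true time-to-peak, minutes after biotin addition.
#' @param plateau residual fraction of the peak retained at t -> Inf,
#'   in `[0, 1)`.
#' @param peak_value peak intensity in baseline-normalized units (> 1).
#' @param n_frames total frames including baseline.
#' @param frame_interval_min minutes per frame.
#' @param n_baseline_frames frames acquired before biotin addition.
#' @param drift `(rows, cols)` pixels per frame of lateral drift; frames are
#'   translated by the cumulative (rounded) drift.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param rng_seed integer seed.
#' @param image_shape frame size in pixels.
#' @param golgi_sigma Gaussian width of the Golgi blob, pixels.
#' @param amplitude baseline brightness of the blob peak, a.u.
#' @return list with `movie` (frame interval stored in seconds), `golgi_mask`
#'   (logical matrix in undrifted coordinates), `biotin_frame` (index of the
#'   first post-biotin frame) and `truth` (`k_true`, `t_peak_true`,
#'   `plateau`, `peak_value`, per-frame `shifts`).
#' @export
simulate_rush_movie <- function(k_true, t_peak_true, plateau = 0,
                                peak_value = 4, n_frames = 25,
                                frame_interval_min = 5,
                                n_baseline_frames = 3, drift = c(0, 0),
                                noise_sd = 0, rng_seed = 1,
                                image_shape = c(64, 64), golgi_sigma = 5,
                                amplitude = 400) {
  stopifnot(k_true > 0, plateau >= 0, plateau < 1, peak_value > 1,
            n_frames > n_baseline_frames + 4, t_peak_true > 0)
  set.seed(rng_seed)
  t_min <- (seq_len(n_frames) - n_baseline_frames - 1) * frame_interval_min
  g <- ifelse(t_min <= 0, 1,
       ifelse(t_min <= t_peak_true, 1 + (peak_value - 1) * t_min / t_peak_true,
              peak_value * (plateau + (1 - plateau) *
                              exp(-k_true * (t_min - t_peak_true)))))
  center <- (image_shape - 1) / 2
  blob <- gaussian_spot(image_shape, center, golgi_sigma)
  mask <- blob > 0.2
  shifts <- matrix(0L, n_frames, 2)
  arr <- array(0, c(image_shape, n_frames))
  for (i in seq_len(n_frames)) {
    fr <- amplitude * g[i] * blob
    if (noise_sd > 0) fr <- fr + stats::rnorm(length(fr), 0, noise_sd)
    sh <- round((i - 1) * drift)
    shifts[i, ] <- as.integer(sh)
    arr[, , i] <- translate_int(pmax(fr, 0), sh[1], sh[2])
  }
  list(movie = Movie(arr, frame_interval_min * 60, 0.2),
       golgi_mask = mask,
       biotin_frame = n_baseline_frames + 1L,
       truth = list(k_true = k_true, t_peak_true = t_peak_true,
                    plateau = plateau, peak_value = peak_value,
                    shifts = shifts))
}

#' Simulate an axonal-transport movie for kymograph analysis
#'
#' Particles are Gaussian spots moving at constant signed velocity along a
#' straight horizontal path (soma at position 0, so positive velocity is
#' anterograde). Particles whose position leaves the path are truncated.
#'
#' @param velocities signed particle velocities, micrometers/second; one
#'   particle per element. Zero velocity gives a stationary particle.
#' @param pixel_size micrometers per pixel.
#' @param frame_interval seconds per frame.
#' @param n_frames number of frames.
#' @param path_length_um length of the straight path, micrometers.
#' @param start_um optional starting positions along the path (micrometers);
#'   defaults to positions drawn uniformly with >= 5 um spacing.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param rng_seed integer seed.
#' @param spot_sigma Gaussian spot width, pixels.
#' @param amplitude spot peak brightness, a.u.
#' @param strip_rows image height in pixels; the path runs along the middle
#'   row.
#' @return list with `movie`, `path` (0-based polyline, soma end first) and
#'   `truth` (`particle_id`, `velocity_um_s`, `start_um`).
#' @export
simulate_kymo_movie <- function(velocities, pixel_size = 0.2,
                                frame_interval = 2, n_frames = 90,
                                path_length_um = 60, start_um = NULL,
                                noise_sd = 0, rng_seed = 1,
                                spot_sigma = 1.2, amplitude = 500,
                                strip_rows = 15) {
  set.seed(rng_seed)
  n_part <- length(velocities)
  margin <- 5
  path_px <- round(path_length_um / pixel_size)
  shape <- c(strip_rows, path_px + 2 * margin)
  if (is.null(start_um) && n_part > 0) {
    # spaced starts so sparse axonal traffic is emulated without collisions
    # at t = 0; crossings during the recording remain possible
    start_um <- sort(stats::runif(n_part, 0.05, 0.95)) * path_length_um
    while (n_part > 1 && min(diff(start_um)) < 5)
      start_um <- sort(stats::runif(n_part, 0.05, 0.95)) * path_length_um
  }
  r0 <- (strip_rows - 1) / 2
  arr <- array(0, c(shape, n_frames))
  for (i in seq_len(n_frames)) {
    t <- (i - 1) * frame_interval
    fr <- matrix(0, shape[1], shape[2])
    for (p in seq_len(n_part)) {
      x_um <- start_um[p] + velocities[p] * t
      if (x_um < 0 || x_um > path_length_um) next   # truncated at the ends
      fr <- fr + amplitude *
        gaussian_spot(shape, c(r0, margin + x_um / pixel_size), spot_sigma)
    }
    if (noise_sd > 0) fr <- fr + stats::rnorm(length(fr), 0, noise_sd)
    arr[, , i] <- pmax(fr, 0)
  }
  path <- cbind(row = c(r0, r0), col = c(margin, margin + path_px))
  list(movie = Movie(arr, frame_interval, pixel_size),
       path = path,
       truth = data.frame(particle_id = seq_len(n_part),
                          velocity_um_s = as.numeric(velocities),
                          start_um = if (n_part) start_um else numeric()))
}

#' Write a simulation to disk (TIFF + ground-truth CSV + sidecar)
#'
#' @param sim result of [simulate_fusion_movie()].
#' @param dir output directory, created if needed.
#' @param stem file-name stem.
#' @return the directory, invisibly.
#' @export
write_fusion_sim <- function(sim, dir, stem = "fusion") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(sim$movie, file.path(dir, paste0(stem, ".tif")),
              nh4cl_window = attr(sim$movie, "nh4cl_window"))
  utils::write.csv(sim$truth$puncta,
                   file.path(dir, paste0(stem, "_puncta.csv")),
                   row.names = FALSE)
  utils::write.csv(sim$truth$events,
                   file.path(dir, paste0(stem, "_events.csv")),
                   row.names = FALSE)
  invisible(dir)
}

# integer-pixel translation with zero fill; positive dr moves content down
translate_int <- function(img, dr, dc) {
  out <- matrix(0, nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}
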
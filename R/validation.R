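#' Ground-truth evaluation suites
#'
#' These functions generate synthetic data under the package's reference
#' study conditions (the acquisition settings of the live-imaging assays the
#' pipeline targets), run the corresponding analysis stage, and score it
#' against the known ground truth. They are used by the analysis scripts and
#' the package's validation tests; all randomness derives from `seed`.
#'
#' @name validation-suites
NULL

# standard fusion-movie noise: read noise 15 a.u., shot noise scale 2 a.u.;
# gives a baseline F/F0 SD of ~0.025 on a 3x3 ROI trace at default punctum
# brightness
FUSION_NOISE <- list(gaussian_sd = 15, poisson_scale = 2)

#' @rdname validation-suites
#' @details `eval_detection_performance()` measures single-trace event
#'   detection at the standard 2 Hz / 240-frame acquisition. Recall movies
#'   carry 5 frame-aligned events each (peak ratios 1.15-3, i.e. amplitudes
#'   from ~4.5 baseline SD upward, sub-frame rise, 3 s decay); a detection
#'   within 2 s of a true event's onset at its punctum counts as a hit.
#'   Specificity movies carry puncta but no events; every detection on them
#'   is a false positive.
#' @param n_movies simulated movies per condition.
#' @param seed base seed.
#' @return `eval_detection_performance()`: list with `recall` and
#'   `fp_per_trace`.
#' @export
eval_detection_performance <- function(n_movies = 50, seed = 1) {
  hits <- total <- 0
  fp <- numeric(n_movies)
  for (i in seq_len(n_movies)) {
    s <- seed + i
    set.seed(s)
    n_ev <- 5
    ev <- data.frame(punctum_id = sample(1:8, n_ev),
                     onset_s = sort(round(stats::runif(n_ev, 31, 95) / 0.5) *
                                      0.5),
                     peak_ratio = stats::runif(n_ev, 1.15, 3),
                     rise_s = 0.4, decay_tau_s = 3)
    sim <- simulate_fusion_movie(sim_config(
      n_puncta = 8, event_table = ev,
      noise_gaussian_sd = FUSION_NOISE$gaussian_sd,
      noise_poisson_scale = FUSION_NOISE$poisson_scale, rng_seed = s))
    for (k in seq_len(n_ev)) {
      tr <- extract_trace(sim$movie,
        round(unlist(sim$truth$puncta[ev$punctum_id[k], c("row", "col")])))
      det <- detect_events(tr)
      hits <- hits + any(abs(det$peak_s - ev$onset_s[k]) < 2)
      total <- total + 1
    }
    # noise-only twin: same scene, no events
    sim0 <- simulate_fusion_movie(sim_config(
      n_puncta = 6, noise_gaussian_sd = FUSION_NOISE$gaussian_sd,
      noise_poisson_scale = FUSION_NOISE$poisson_scale, rng_seed = s))
    fp[i] <- mean(vapply(seq_len(6), function(j) {
      tr <- extract_trace(sim0$movie,
        round(unlist(sim0$truth$puncta[j, c("row", "col")])))
      nrow(detect_events(tr))
    }, numeric(1)))
  }
  list(recall = hits / total, fp_per_trace = mean(fp))
}

#' @rdname validation-suites
#' @details `eval_released_fraction_recovery()` runs the full
#'   fusion-and-pool pipeline on simulated neurons (128 x 128 px, 100
#'   labeled vesicles, 8 evoked events during the stimulation window, so a
#'   configured released fraction of 0.08, NH4Cl pulse at 100-118 s) and
#'   compares the recovered fraction with the configured one.
#' @param n_neurons simulated neurons.
#' @return `eval_released_fraction_recovery()`: list with `target_fraction`,
#'   per-seed `fractions`, `mean_fraction`, `mean_rel_error` (of the mean),
#'   `median_rel_error` (per seed).
#' @export
eval_released_fraction_recovery <- function(n_neurons = 20, seed = 1) {
  n_p <- 100; n_ev <- 8
  target <- n_ev / n_p
  fr <- vapply(seq_len(n_neurons), function(i) {
    s <- seed + i
    set.seed(s)
    ev <- data.frame(punctum_id = sample(n_p, n_ev),
                     onset_s = sort(round(stats::runif(n_ev, 31, 52) / 0.5) *
                                      0.5),
                     peak_ratio = stats::runif(n_ev, 1.6, 3),
                     rise_s = 0.4, decay_tau_s = 3)
    sim <- simulate_fusion_movie(sim_config(
      image_shape = c(128, 128), n_puncta = n_p, event_table = ev,
      nh4cl_window = c(100, 118),
      noise_gaussian_sd = FUSION_NOISE$gaussian_sd,
      noise_poisson_scale = FUSION_NOISE$poisson_scale, rng_seed = s))
    out <- suppressWarnings(
      run_pipeline(sim$movie, pipeline_config(nh4cl_window = c(100, 118))))
    if (is.null(out$released)) NA_real_ else out$released$fraction
  }, numeric(1))
  list(target_fraction = target, fractions = fr,
       mean_fraction = mean(fr, na.rm = TRUE),
       mean_rel_error = abs(mean(fr, na.rm = TRUE) - target) / target,
       median_rel_error = stats::median(abs(fr - target) / target,
                                        na.rm = TRUE))
}

#' @rdname validation-suites
#' @details `eval_rush_recovery()` simulates RUSH Golgi traces (25 frames at
#'   5 min/frame, k = 0.08/min, time-to-peak 45 min, 10% plateau, Gaussian
#'   noise at 5% of the peak intensity), fits the export kinetics and scores
#'   parameter recovery.
#' @param n_traces simulated traces.
#' @return `eval_rush_recovery()`: list with `k_true`, `t_peak_true`,
#'   `median_k_rel_error`, `median_t_peak_error_min`, `max_t_peak_error_min`.
#' @export
eval_rush_recovery <- function(n_traces = 50, seed = 1) {
  k_true <- 0.08; tp_true <- 45; peak <- 4; amp <- 400
  res <- vapply(seq_len(n_traces), function(i) {
    sim <- simulate_rush_movie(k_true = k_true, t_peak_true = tp_true,
                               plateau = 0.1, peak_value = peak,
                               noise_sd = 0.05 * peak * amp,
                               amplitude = amp, rng_seed = seed + i)
    tr <- golgi_trace(sim$movie, sim$golgi_mask, sim$biotin_frame)
    fit <- fit_golgi_kinetics(tr)
    c(abs(fit$k - k_true) / k_true, abs(fit$t_peak - tp_true))
  }, numeric(2))
  list(k_true = k_true, t_peak_true = tp_true,
       median_k_rel_error = stats::median(res[1, ]),
       median_t_peak_error_min = stats::median(res[2, ]),
       max_t_peak_error_min = max(res[2, ]))
}

#' @rdname validation-suites
#' @details `eval_kymo_recovery()` simulates single-particle transport
#'   movies (0.5 Hz, 3 min, 60 um path) with a 2:1 anterograde:retrograde
#'   split and speeds of 0.5-1.5 um/s, traces each movie's kymograph and
#'   scores the longest recovered track's direction and speed. Starting
#'   positions are drawn so the particle traverses the imaged segment
#'   (anterograde particles enter proximally, retrograde distally), matching
#'   how sparse axonal traffic appears in short recordings; the greedy
#'   tracer does not preserve identity through particle crossings, so
#'   recovery is scored on crossing-free traffic.
#' @param n_movies simulated single-particle movies.
#' @return `eval_kymo_recovery()`: list with `anterograde_fraction_true`,
#'   `anterograde_fraction`, `median_speed_rel_error`, `mean_speed_true`,
#'   `mean_speed`, `n_tracked`.
#' @export
eval_kymo_recovery <- function(n_movies = 30, seed = 1) {
  set.seed(seed)
  dirs <- rep(c(1, 1, -1), length.out = n_movies)   # 2:1 anterograde
  speeds <- stats::runif(n_movies, 0.5, 1.5)
  starts <- ifelse(dirs > 0, stats::runif(n_movies, 0.1, 0.4),
                   stats::runif(n_movies, 0.6, 0.9)) * 60
  dir_rec <- character(n_movies)
  speed_rec <- rep(NA_real_, n_movies)
  for (i in seq_len(n_movies)) {
    km <- simulate_kymo_movie(velocities = dirs[i] * speeds[i],
                              start_um = starts[i], noise_sd = 10,
                              rng_seed = seed + i)
    ky <- build_kymograph(km$movie, km$path)
    cl <- classify_tracks(trace_tracks(ky), ky)
    if (nrow(cl$tracks) == 0) { dir_rec[i] <- "missed"; next }
    best <- cl$tracks[order(-cl$tracks$n_frames), ][1, ]
    dir_rec[i] <- best$direction
    speed_rec[i] <- best$speed_um_s
  }
  moving <- dir_rec %in% c("anterograde", "retrograde")
  list(anterograde_fraction_true = mean(dirs > 0),
       anterograde_fraction = mean(dir_rec[moving] == "anterograde"),
       median_speed_rel_error =
         stats::median(abs(speed_rec - speeds) / speeds, na.rm = TRUE),
       mean_speed_true = mean(speeds),
       mean_speed = mean(speed_rec, na.rm = TRUE),
       n_tracked = sum(moving))
}

#' @rdname validation-suites
#' @details `eval_superplot_type1()` simulates nested null data (two groups,
#'   3 biological replicates each, 15 units per replicate, with
#'   between-replicate and within-replicate variability but no group
#'   effect) and reports the fraction of replicate-mean t-tests rejecting at
#'   alpha = 0.05.
#' @param n_sim simulated experiments.
#' @param alpha nominal level.
#' @return `eval_superplot_type1()`: list with `type1_rate` and `n_sim`.
#' @export
eval_superplot_type1 <- function(n_sim = 1000, seed = 1, alpha = 0.05) {
  set.seed(seed)
  rej <- vapply(seq_len(n_sim), function(i) {
    d <- do.call(rbind, lapply(c("a", "b"), function(g) {
      do.call(rbind, lapply(1:3, function(r) {
        mu_r <- stats::rnorm(1, 0, 0.5)      # replicate (culture) effect
        data.frame(group = g, replicate = r, unit = 1:15,
                   value = stats::rnorm(15, 10 + mu_r, 1))
      }))
    }))
    superplot_compare(d, "a", "b")$p_value < alpha
  }, logical(1))
  list(type1_rate = mean(rej), n_sim = n_sim)
}

#' @rdname validation-suites
#' @details `eval_ddct_recovery()` simulates paired qRT-PCR Ct tables with a
#'   known true fold change (0.7) and 0.2-cycle Ct noise across 8 sample
#'   pairs, and reports the recovered geometric-mean fold change averaged
#'   over experiments.
#' @param n_experiments simulated experiments.
#' @return `eval_ddct_recovery()`: list with `fc_true` and `mean_fc`.
#' @export
eval_ddct_recovery <- function(n_experiments = 50, seed = 1) {
  fc_true <- 0.7
  fcs <- vapply(seq_len(n_experiments), function(i) {
    set.seed(seed + i)
    n_pairs <- 8
    rows <- list()
    for (p in seq_len(n_pairs)) {
      ct_ref <- 18 + stats::rnorm(1, 0, 0.5)
      ct_t_ctrl <- 24 + stats::rnorm(1, 0, 0.5)
      rows[[length(rows) + 1]] <- data.frame(
        sample = paste0(p, c("c", "c", "k", "k")), pair = p,
        condition = rep(c("ctrl", "ko"), each = 2),
        gene = rep(c("Tgt", "Gapdh"), 2),
        ct = c(ct_t_ctrl + stats::rnorm(1, 0, 0.2),
               ct_ref + stats::rnorm(1, 0, 0.2),
               ct_t_ctrl - log2(fc_true) + stats::rnorm(1, 0, 0.2),
               ct_ref + stats::rnorm(1, 0, 0.2)))
    }
    ddct_fold_change(do.call(rbind, rows), "Tgt", "Gapdh",
                     "ctrl")$geometric_mean_fc
  }, numeric(1))
  list(fc_true = fc_true, mean_fc = mean(fcs))
}
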
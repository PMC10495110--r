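#!/usr/bin/env Rscript
# Generate one example dataset per assay with known ground truth and write
# it to results/simulated/: an NPY-pHluorin fusion movie (2 Hz, 2 min,
# train-burst stimulation at 30 s, NH4Cl pulse at 100-118 s), a RUSH
# Golgi-flux movie (5 min/frame, 2 h) and a single-particle transport movie
# (0.5 Hz, 3 min). These files are the inputs for the downstream scripts'
# worked examples; the recovery statistics in scripts 02-06 regenerate their
# own ensembles.

library(dcvflux)
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

set.seed(1)
ev <- data.frame(punctum_id = sample(50, 4),
                 onset_s = c(33, 38.5, 44, 50),
                 peak_ratio = c(2, 2.5, 3, 2), rise_s = 0.4, decay_tau_s = 3)
sim <- simulate_fusion_movie(sim_config(image_shape = c(96, 96),
  n_puncta = 50, event_table = ev, nh4cl_window = c(100, 118),
  noise_gaussian_sd = 15, noise_poisson_scale = 2, rng_seed = 1))
write_fusion_sim(sim, out, stem = "fusion")
message("fusion movie: 50 puncta, 4 evoked events -> ", out, "/fusion.tif")

rush <- simulate_rush_movie(k_true = 0.08, t_peak_true = 45, plateau = 0.1,
                            noise_sd = 40, rng_seed = 1)
write_stack(rush$movie, file.path(out, "rush.tif"))
utils::write.csv(data.frame(k_true = 0.08, t_peak_true = 45, plateau = 0.1),
                 file.path(out, "rush_truth.csv"), row.names = FALSE)
message("RUSH movie: k = 0.08/min, t_peak = 45 min -> ", out, "/rush.tif")

kymo <- simulate_kymo_movie(velocities = c(1, -0.8), start_um = c(12, 48),
                            noise_sd = 10, rng_seed = 1)
write_stack(kymo$movie, file.path(out, "kymo.tif"))
utils::write.csv(kymo$truth, file.path(out, "kymo_truth.csv"),
                 row.names = FALSE)
message("transport movie: +1 and -0.8 um/s -> ", out, "/kymo.tif")
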
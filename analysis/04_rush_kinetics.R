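#!/usr/bin/env Rscript
# Fit first-order Golgi-export kinetics to simulated RUSH traces (25 frames
# at 5 min/frame, 5% peak noise, k = 0.08/min, time-to-peak 45 min) and
# score parameter recovery. Also demonstrates drift registration on a
# drifting movie.

library(dcvflux)
dir.create("results", showWarnings = FALSE)

rec <- eval_rush_recovery(n_traces = 50, seed = 1)
message(sprintf("median |k_hat - k|/k:   %.3f (target < 0.05)",
                rec$median_k_rel_error))
message(sprintf("median t_peak error:    %.1f min (target <= 5, one frame)",
                rec$median_t_peak_error_min))

# drift round trip: registration restores the drift-free trace
drifted <- simulate_rush_movie(k_true = 0.08, t_peak_true = 45,
                               drift = c(1, 0), rng_seed = 2)
reg <- register_movie(drifted$movie)
fit <- fit_golgi_kinetics(
  golgi_trace(reg$movie, drifted$golgi_mask, drifted$biotin_frame))
message(sprintf("after registering 1 px/frame drift: k_hat = %.4f/min", fit$k))

utils::write.csv(
  data.frame(metric = c("median_k_rel_error", "median_t_peak_error_min",
                        "k_after_registration"),
             value = c(rec$median_k_rel_error, rec$median_t_peak_error_min,
                       fit$k)),
  "results/rush_recovery.csv", row.names = FALSE)
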
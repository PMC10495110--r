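test_that("stimulation protocol span matches the train arithmetic", {
  sp <- stim_protocol()
  expect_equal(stim_span(sp), 16 * (50 / 50) + 15 * 0.5)
  expect_equal(stim_window(sp), c(30, 53.5))
})

test_that("event-free noise-free movies are constant over time", {
  sim <- simulate_fusion_movie(sim_config(n_puncta = 5, n_frames = 40,
                                          rng_seed = 3))
  m <- unclass(sim$movie)
  expect_equal(nrow(sim$truth$puncta), 5)
  expect_equal(nrow(sim$truth$events), 0)
  for (f in 2:40) expect_equal(m[, , f], m[, , 1])
})

test_that("an event reaches its configured peak ratio within one frame", {
  ev <- data.frame(punctum_id = 1, onset_s = 40, peak_ratio = 3,
                   rise_s = 0.5, decay_tau_s = 4)
  sim <- simulate_fusion_movie(sim_config(n_puncta = 1, background = 0,
                                          event_table = ev, rng_seed = 1))
  p <- round(unlist(sim$truth$puncta[1, c("row", "col")]))
  tr <- extract_trace(sim$movie, p)
  expect_equal(max(tr$R), 3, tolerance = 0.01)
  # reaches 3x baseline within one frame of the end of the rise
  i_on <- 40 / 0.5 + 1
  expect_gte(tr$R[i_on + 2], 3 * exp(-0.5 / 4) * 0.99)
})

test_that("NH4Cl dequench multiplies punctum intensity by the factor", {
  cfg <- sim_config(n_puncta = 4, n_frames = 60, background = 0,
                    nh4cl_window = c(25, 30), dequench_factor = 2,
                    rng_seed = 2)
  sim <- simulate_fusion_movie(cfg)
  p <- round(unlist(sim$truth$puncta[1, c("row", "col")]))
  tr <- extract_trace(sim$movie, p, n_baseline_frames = 10)
  pre <- mean(tr$F[1:50])
  inw <- mean(tr$F[51:60])
  expect_equal(inw / pre, 2, tolerance = 1e-9)
})

test_that("identical config and seed give bit-identical stacks", {
  ev <- data.frame(punctum_id = 1, onset_s = 35, peak_ratio = 2,
                   rise_s = 0.5, decay_tau_s = 3)
  cfg <- sim_config(n_puncta = 3, n_frames = 100, event_table = ev,
                    noise_gaussian_sd = 10, noise_poisson_scale = 2,
                    rng_seed = 11)
  a <- simulate_fusion_movie(cfg)
  b <- simulate_fusion_movie(cfg)
  expect_identical(unclass(a$movie), unclass(b$movie))
  expect_identical(a$truth, b$truth)
})

test_that("events referencing unknown puncta are a configuration error", {
  ev <- data.frame(punctum_id = 7, onset_s = 35, peak_ratio = 2,
                   rise_s = 0.5, decay_tau_s = 3)
  expect_error(sim_config(n_puncta = 3, event_table = ev),
               "unknown punctum")
})

test_that("an NH4Cl window overlapping an event decay warns but proceeds", {
  ev <- data.frame(punctum_id = 1, onset_s = 95, peak_ratio = 2,
                   rise_s = 0.5, decay_tau_s = 10)
  expect_warning(cfg <- sim_config(n_puncta = 2, event_table = ev,
                                   nh4cl_window = c(100, 118)),
                 "overlaps an event decay")
  expect_s3_class(cfg, "SimConfig")
})

test_that("noise-free RUSH trace follows the closed-form decay", {
  sim <- simulate_rush_movie(k_true = 0.05, t_peak_true = 40, plateau = 0)
  tr <- golgi_trace(sim$movie, sim$golgi_mask, sim$biotin_frame)
  i_pk <- which(tr$times_min == 40)
  i_20 <- which(tr$times_min == 60)   # t_peak + 20 min = 1/k after the peak
  expect_equal(tr$intensity_norm[i_20] / tr$intensity_norm[i_pk],
               exp(-1), tolerance = 1e-9)
})

test_that("kymograph particles advance by velocity * dt / pixel size", {
  km <- simulate_kymo_movie(velocities = 1, pixel_size = 0.2,
                            frame_interval = 2, start_um = 10, n_frames = 10)
  ky <- build_kymograph(km$movie, km$path)
  pk <- apply(ky$image, 1, which.max)
  expect_equal(unique(diff(pk)), 10)   # +1 um/s at 0.2 um/px, 2 s/frame
})

test_that("opposite velocities give opposite net displacements", {
  km <- simulate_kymo_movie(velocities = c(1, -1), start_um = c(15, 45),
                            n_frames = 40, rng_seed = 5)
  ky <- build_kymograph(km$movie, km$path)
  cl <- classify_tracks(trace_tracks(ky), ky)
  expect_equal(sort(sign(cl$tracks$net_displacement_um)), c(-1, 1))
})

test_that("zero particles give a valid empty movie", {
  km <- simulate_kymo_movie(velocities = numeric(0), n_frames = 10)
  expect_equal(nrow(km$truth), 0)
  expect_true(all(unclass(km$movie) == 0))
})
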
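test_that("ROI placement finds single and multiple event sites", {
  ev1 <- data.frame(punctum_id = 1, onset_s = 35, peak_ratio = 3,
                    rise_s = 0.5, decay_tau_s = 3)
  pos <- rbind(c(20, 30))
  sim <- simulate_fusion_movie(sim_config(n_puncta = 1, background = 0,
    puncta_positions = pos, event_table = ev1, rng_seed = 1))
  ro <- place_rois(sim$movie)
  expect_equal(nrow(ro), 1)
  expect_lt(max(abs(ro[1, ] - c(20, 30))), 1.01)

  ev3 <- data.frame(punctum_id = 1:3, onset_s = c(35, 40, 45),
                    peak_ratio = 3, rise_s = 0.5, decay_tau_s = 3)
  sim3 <- simulate_fusion_movie(sim_config(n_puncta = 3, background = 0,
    min_separation = 15, event_table = ev3, rng_seed = 4))
  ro3 <- place_rois(sim3$movie)
  expect_equal(nrow(ro3), 3)
  for (i in 1:3) {
    d <- sqrt((ro3[, 1] - sim3$truth$puncta$row[i])^2 +
              (ro3[, 2] - sim3$truth$puncta$col[i])^2)
    expect_lt(min(d), 1.01)
  }
})

test_that("ROI placement returns nothing without events or signal", {
  sim <- simulate_fusion_movie(sim_config(n_puncta = 3, background = 0,
                                          rng_seed = 2))
  expect_equal(nrow(place_rois(sim$movie)), 0)
})

test_that("trace extraction normalizes to the first-10-frame baseline", {
  m <- Movie(array(100, c(9, 9, 30)), frame_interval = 0.5)
  tr <- extract_trace(m, c(4, 4))
  expect_equal(tr$R, rep(1, 30))

  arr <- array(10, c(9, 9, 15))
  arr[, , 11:15] <- 30
  tr2 <- extract_trace(Movie(arr, 0.5), c(4, 4))
  expect_equal(tr2$F0, 10)
  expect_equal(tr2$R[15], 3)
})

test_that("a clipped ROI is an error naming the ROI", {
  m <- Movie(array(1, c(9, 9, 12)), frame_interval = 0.5)
  expect_error(extract_trace(m, c(0, 4)), "\\(0, 4\\).*clipped")
})

test_that("detector agrees with a brute-force frame scan on step traces", {
  tr <- make_step_trace(level = 2, rise_frames = 1)
  ora <- brute_force_events(tr$R, 0.5, 1:60)
  det <- detect_events(tr)
  expect_equal(nrow(det), 1)
  expect_equal(nrow(det), nrow(ora))
  expect_equal(det$peak_frame, unname(ora[, "peak"]))
  expect_equal(det$rise_s, 0.5)

  # parameterised over amplitude and hold length
  for (level in c(1.5, 2.5)) for (hold in c(2, 6)) {
    trp <- make_step_trace(level = level, hold_frames = hold, seed = level * hold)
    orap <- brute_force_events(trp$R, 0.5, 1:60)
    detp <- detect_events(trp)
    expect_equal(nrow(detp), if (is.null(orap)) 0L else nrow(orap))
    if (!is.null(orap)) expect_equal(detp$peak_frame, unname(orap[, "peak"]))
  }
})

test_that("a rise spread over four frames is rejected", {
  tr <- make_step_trace(level = 2, rise_frames = 4)
  expect_equal(nrow(detect_events(tr)), 0)
})

test_that("a flat trace yields no events even with the sigma floor", {
  tr <- structure(list(center = c(0, 0), roi_size = 3, F = rep(1, 240),
                       F0 = 1, R = rep(1, 240), frame_interval = 0.5),
                  class = "RoiTrace")
  expect_warning(det <- detect_events(tr), "sigma_floor")
  expect_equal(nrow(det), 0)
})

test_that("detection is invariant to scaling the whole movie", {
  ev <- data.frame(punctum_id = 1:2, onset_s = c(35, 45), peak_ratio = 2.5,
                   rise_s = 0.4, decay_tau_s = 3)
  sim <- simulate_fusion_movie(sim_config(n_puncta = 4, event_table = ev,
    noise_gaussian_sd = 10, rng_seed = 6))
  p <- round(unlist(sim$truth$puncta[1, c("row", "col")]))
  tr1 <- extract_trace(sim$movie, p)
  m2 <- Movie(unclass(sim$movie) * 7.3, frame_interval(sim$movie))
  tr2 <- extract_trace(m2, p)
  expect_equal(detect_events(tr1), detect_events(tr2))
})

test_that("summaries count cumulatively and split by stimulation window", {
  ev <- data.frame(onset_frame = c(69, 79, 89), peak_frame = c(70, 80, 90),
                   onset_s = c(34, 39, 44), peak_s = c(34.5, 39.5, 44.5),
                   peak_ratio = c(2, 3, 4), amplitude = c(1, 2, 3),
                   rise_s = 0.5)
  s <- summarize_events(ev, 240, stim_protocol(), 0.5)
  expect_equal(s$n_events, 3)
  expect_equal(s$cumulative_counts[240], 3)
  expect_true(all(diff(s$cumulative_counts) >= 0))
  expect_equal(s$cumulative_counts[70], 1)
  expect_equal(s$cumulative_counts[69], 0)
  expect_equal(unname(s$events_per_window), c(0, 3, 0))
  expect_equal(s$mean_peak_ratio, 3)

  s0 <- summarize_events(empty_events(), 240, stim_protocol(), 0.5)
  expect_equal(s0$n_events, 0)
  expect_true(all(s0$cumulative_counts == 0))
  expect_true(is.na(s0$mean_peak_ratio))
})

test_that("per-neuron event counts average to the simulated rate", {
  # 100 neurons with Poisson(5) events each, counted via the summary
  set.seed(123)
  n <- sapply(1:100, function(i) {
    k <- rpois(1, 5)
    if (k == 0) return(summarize_events(empty_events(), 240)$n_events)
    pf <- sort(sample(61:107, k))
    ev <- data.frame(onset_frame = pf - 1, peak_frame = pf,
                     onset_s = (pf - 2) * 0.5, peak_s = (pf - 1) * 0.5,
                     peak_ratio = 2, amplitude = 1, rise_s = 0.5)
    summarize_events(ev, 240, stim_protocol(), 0.5)$n_events
  })
  expect_equal(mean(n), 5, tolerance = 0.1)
})
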
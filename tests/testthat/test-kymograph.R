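test_that("kymograph geometry: static spots are vertical, uniform is flat", {
  km <- simulate_kymo_movie(velocities = 0, start_um = 30, n_frames = 20)
  ky <- build_kymograph(km$movie, km$path)
  pk <- apply(ky$image, 1, which.max)
  expect_equal(length(unique(pk)), 1)

  m <- Movie(array(5, c(15, 60, 8)), frame_interval = 2, pixel_size = 0.2)
  ky2 <- build_kymograph(m, cbind(c(7, 7), c(5, 50)))
  expect_true(all(abs(ky2$image - 5) < 1e-9))

  expect_error(build_kymograph(m, cbind(c(7, 7), c(5, 5.5))), "shorter")
})

test_that("single particles produce one track covering most frames", {
  km <- simulate_kymo_movie(velocities = 0.25, start_um = 10, rng_seed = 2)
  ky <- build_kymograph(km$movie, km$path)
  tp <- trace_tracks(ky)
  expect_equal(length(unique(tp$track_id)), 1)
  expect_gte(nrow(tp), 0.9 * n_frames(km$movie))
})

test_that("a blank kymograph yields no tracks", {
  m <- Movie(array(0, c(15, 60, 10)), frame_interval = 2, pixel_size = 0.2)
  ky <- build_kymograph(m, cbind(c(7, 7), c(5, 50)))
  expect_equal(nrow(trace_tracks(ky)), 0)
})

test_that("two well-separated parallel particles stay distinct", {
  km <- simulate_kymo_movie(velocities = c(0.5, 0.5), start_um = c(5, 35),
                            rng_seed = 3)
  ky <- build_kymograph(km$movie, km$path)
  cl <- classify_tracks(trace_tracks(ky), ky)
  expect_equal(nrow(cl$tracks), 2)
  expect_true(all(cl$tracks$direction == "anterograde"))
  expect_equal(cl$tracks$speed_um_s, c(0.5, 0.5), tolerance = 0.02)
})

test_that("direction and speed arithmetic is as stated", {
  pts <- data.frame(track_id = 1, frame = 1:11,
                    position_px = seq(0, 50, by = 5))   # +10 um over 20 s
  ky <- structure(list(image = matrix(0, 11, 60), pixel_size = 0.2,
                       frame_interval = 2, path = cbind(c(7, 7), c(0, 59)),
                       line_width = 3), class = "Kymograph")
  cl <- classify_tracks(pts, ky)
  expect_equal(cl$tracks$direction, "anterograde")
  expect_equal(cl$tracks$speed_um_s, 0.5)

  pts0 <- data.frame(track_id = 1, frame = 1:11, position_px = rep(20, 11))
  expect_equal(classify_tracks(pts0, ky)$tracks$direction, "stationary")
  expect_equal(classify_tracks(pts0, ky)$tracks$speed_um_s, 0)
})

test_that("reversing the path swaps anterograde and retrograde exactly", {
  # divergent particles: their paths never cross, so the greedy tracer
  # keeps identities
  km <- simulate_kymo_movie(velocities = c(0.8, -0.6), start_um = c(35, 25),
                            rng_seed = 4, noise_sd = 5)
  fwd <- build_kymograph(km$movie, km$path)
  rev <- build_kymograph(km$movie, km$path[2:1, ])
  cf <- classify_tracks(trace_tracks(fwd), fwd)
  cr <- classify_tracks(trace_tracks(rev), rev)
  expect_equal(sort(cf$tracks$direction), sort(c("anterograde", "retrograde")))
  tab_f <- table(cf$tracks$direction)
  tab_r <- table(cr$tracks$direction)
  expect_equal(unname(tab_f["anterograde"]), unname(tab_r["retrograde"]))
  expect_equal(unname(tab_f["retrograde"]), unname(tab_r["anterograde"]))
})

test_that("direction fractions sum to one", {
  km <- simulate_kymo_movie(velocities = c(1, -0.8, 0),
                            start_um = c(10, 50, 30), rng_seed = 5)
  ky <- build_kymograph(km$movie, km$path)
  cl <- classify_tracks(trace_tracks(ky), ky)
  expect_equal(sum(cl$fractions_all), 1)
  if (!is.null(cl$fractions_moving))
    expect_equal(sum(cl$fractions_moving), 1)
})

test_that("noise-free constant-velocity speeds are recovered within 10%", {
  for (v in c(0.5, 1, 1.5)) {
    km <- simulate_kymo_movie(velocities = v, start_um = 5, rng_seed = 6)
    ky <- build_kymograph(km$movie, km$path)
    cl <- classify_tracks(trace_tracks(ky), ky)
    best <- cl$tracks[order(-cl$tracks$n_frames), ][1, ]
    expect_equal(best$speed_um_s, v, tolerance = 0.1)
  }
})
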
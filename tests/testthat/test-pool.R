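make_pool_movie <- function(n_puncta, min_sep = 6, seed = 1, noise = 0,
                            shape = c(96, 96)) {
  simulate_fusion_movie(sim_config(image_shape = shape, n_puncta = n_puncta,
    min_separation = min_sep, nh4cl_window = c(100, 118),
    dequench_factor = 2, noise_gaussian_sd = noise, rng_seed = seed))
}

test_that("well-separated dequenched puncta are counted exactly", {
  sim <- make_pool_movie(20)
  est <- detect_puncta(sim$movie, c(100, 118), c(0, 30))
  expect_equal(est$raw_count, 20)
  est <- corrected_pool_count(est)
  expect_equal(est$corrected_count, 20)   # non-overlapping: corrected = raw
})

test_that("a blank movie yields an empty pool", {
  m <- Movie(array(0, c(32, 32, 240)), frame_interval = 0.5)
  est <- detect_puncta(m, c(100, 118), c(0, 30))
  expect_equal(est$raw_count, 0)
  expect_equal(corrected_pool_count(est)$corrected_count, 0)
})

test_that("two merged puncta are recovered by the area-quotient correction", {
  # 19 isolated puncta plus one close pair that fuses into one component
  set.seed(7)
  pos <- place_puncta(c(96, 96), 19, 7)
  pos <- rbind(pos, pos[1, ] + c(0, 3.5))   # pair close enough to merge
  sim <- simulate_fusion_movie(sim_config(image_shape = c(96, 96),
    n_puncta = 20, puncta_positions = pos, nh4cl_window = c(100, 118),
    rng_seed = 7))
  est <- detect_puncta(sim$movie, c(100, 118), c(0, 30))
  expect_equal(est$raw_count, 19)
  est <- corrected_pool_count(est)
  expect_equal(est$corrected_count, 20)
})

test_that("area-quotient arithmetic follows the stated rule", {
  fake <- structure(list(raw_count = 5, components = data.frame(
    component_id = 1:5, row = 1:5, col = 1:5, area_px = c(10, 10, 10, 10, 10)),
    single_punctum_area = NA, corrected_count = NA,
    nh4cl_image = matrix(0, 2, 2)), class = "PoolEstimate")
  expect_equal(corrected_pool_count(fake)$corrected_count, 5)
  fake$components$area_px <- c(10, 10, 10, 10, 20)
  expect_equal(corrected_pool_count(fake)$corrected_count, 6)
})

test_that("corrected counts are invariant to intensity scaling", {
  sim <- make_pool_movie(15, seed = 3, noise = 10)
  m2 <- Movie(unclass(sim$movie) * 4.2, frame_interval(sim$movie))
  a <- corrected_pool_count(detect_puncta(sim$movie, c(100, 118), c(0, 30)))
  b <- corrected_pool_count(detect_puncta(m2, c(100, 118), c(0, 30)))
  expect_equal(a$corrected_count, b$corrected_count)
})

test_that("adding an isolated punctum raises the corrected count by one", {
  set.seed(11)
  pos <- place_puncta(c(96, 96), 12, 8)
  for (n in c(11, 12)) {
    sim <- simulate_fusion_movie(sim_config(image_shape = c(96, 96),
      n_puncta = n, puncta_positions = pos[seq_len(n), , drop = FALSE],
      nh4cl_window = c(100, 118), rng_seed = 11))
    est <- corrected_pool_count(detect_puncta(sim$movie, c(100, 118),
                                              c(0, 30)))
    if (n == 11) n11 <- est$corrected_count else n12 <- est$corrected_count
  }
  expect_equal(n12, n11 + 1)
})

test_that("overlap correction moves counts toward the truth", {
  res <- t(sapply(1:15, function(s) {
    sim <- simulate_fusion_movie(sim_config(image_shape = c(96, 96),
      n_puncta = 40, min_separation = 2.5, nh4cl_window = c(100, 118),
      noise_gaussian_sd = 10, noise_poisson_scale = 2, rng_seed = s))
    est <- corrected_pool_count(detect_puncta(sim$movie, c(100, 118),
                                              c(0, 30)))
    c(raw = est$raw_count, corr = est$corrected_count)
  }))
  improved <- abs(res[, "corr"] - 40) <= abs(res[, "raw"] - 40)
  expect_gte(mean(improved), 0.9)
})

test_that("released fraction is events over pool with guard rails", {
  expect_equal(released_fraction(8, 100)$fraction, 0.08)
  expect_equal(released_fraction(0, 50)$fraction, 0)
  expect_error(released_fraction(3, 0), "positive")
  expect_warning(rf <- released_fraction(12, 10), "undercounted")
  expect_equal(rf$fraction, 1.2)
})

test_that("8-connected labeling joins diagonal contacts", {
  m <- matrix(0, 6, 6)
  m[2, 2] <- 1; m[3, 3] <- 1          # diagonal pair: one component
  m[5, 5] <- 1                        # isolated
  lab <- label_components_8(m > 0)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[2, 2])
})
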
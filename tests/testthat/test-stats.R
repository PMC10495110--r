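test_that("replicate-mean t-test matches the closed-form pooled t", {
  # hand oracle: means 2 vs 5, pooled variance 1, se = sqrt(2/3)
  res <- superplot_compare(nested_df(c(1, 2, 3), c(4, 5, 6)), "a", "b")
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(unname(res$grand_means), c(2, 5))
})

test_that("identical groups give t = 0 and p = 1", {
  res <- superplot_compare(nested_df(c(3, 4, 5), c(3, 4, 5)), "a", "b")
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
})

test_that("comparison is invariant to unit order and unit-level structure", {
  set.seed(2)
  d <- do.call(rbind, lapply(c("a", "b"), function(g)
    do.call(rbind, lapply(1:3, function(r)
      data.frame(group = g, replicate = r, unit = 1:10,
                 value = rnorm(10, ifelse(g == "a", 5, 6)))))))
  r1 <- superplot_compare(d, "a", "b")
  r2 <- superplot_compare(d[sample(nrow(d)), ], "a", "b")
  expect_equal(r1$t, r2$t)
  expect_equal(r1$p_value, r2$p_value)
  # collapsing units to their means preserves replicate means, hence t
  dm <- aggregate(value ~ group + replicate + unit, d, mean)
  expect_equal(superplot_compare(dm, "a", "b")$t, r1$t)
})

test_that("ddCt arithmetic reproduces textbook fold changes", {
  tab <- data.frame(sample = c("c1", "c1", "k1", "k1"), pair = 1,
                    condition = rep(c("ctrl", "ko"), each = 2),
                    gene = rep(c("Tgt", "Gapdh"), 2),
                    ct = c(21, 15, 22, 15))
  res <- ddct_fold_change(tab, "Tgt", "Gapdh", "ctrl")
  expect_equal(res$pairs$ddct, 1)
  expect_equal(res$pairs$fc, 0.5)
  expect_equal(res$geometric_mean_fc, 0.5)
})

test_that("a gene measured against itself has fold change exactly 1", {
  tab <- data.frame(sample = rep(c("c1", "k1", "c2", "k2"), each = 1),
                    pair = c(1, 1, 2, 2),
                    condition = rep(c("ctrl", "ko"), 2),
                    gene = "Gapdh", ct = c(18.2, 18.9, 17.5, 18.1))
  res <- ddct_fold_change(tab, "Gapdh", "Gapdh", "ctrl")
  expect_true(all(res$pairs$fc == 1))
  expect_true(res$zero_variance)
  expect_true(is.na(res$t))
})

test_that("pairs missing a reference Ct are dropped with a warning", {
  tab <- data.frame(sample = c("c1", "c1", "k1", "k1", "c2", "k2"),
                    pair = c(1, 1, 1, 1, 2, 2),
                    condition = c("ctrl", "ctrl", "ko", "ko", "ctrl", "ko"),
                    gene = c("Tgt", "Gapdh", "Tgt", "Gapdh", "Tgt", "Tgt"),
                    ct = c(21, 15, 22, 15, 20, 21))
  expect_warning(res <- ddct_fold_change(tab, "Tgt", "Gapdh", "ctrl"),
                 "dropped")
  expect_equal(nrow(res$pairs), 1)
})

test_that("volume and relative-change derivations match the printed values", {
  res <- morphometry_derive(71.52, 65.01, p_control = 17, p_test = 12)
  expect_equal(res$volume_change_pct, 100 * (1 - (65.01 / 71.52)^3))
  expect_equal(round(res$volume_change_pct), 25)
  expect_equal(res$relative_change_pct, 100 * (1 - 12 / 17))
  expect_equal(round(res$relative_change_pct / 10) * 10, 30)
  expect_equal(morphometry_derive(70, 70)$volume_change_pct, 0)
  expect_error(morphometry_derive(0, 65), "positive")
})

test_that("volume change decreases strictly in the test diameter", {
  d <- seq(50, 90, by = 5)
  v <- sapply(d, function(x) morphometry_derive(70, x)$volume_change_pct)
  expect_true(all(diff(v) < 0))
  expect_equal(v[d == 70], 0)
})

test_that("diameter bins are half-open and fractions sum to one", {
  res <- morphometry_derive(70, 65, diameters = c(40, 45, 49.99, 50, 65),
                            bin_edges = seq(40, 70, by = 10))
  expect_equal(unname(res$bin_fractions),
               c(3 / 5, 1 / 5, 1 / 5))   # 50 falls in [50, 60)
  expect_equal(sum(res$bin_fractions), 1)
})
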
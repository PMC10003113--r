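# Generators: determinism, conservation laws, and parameter recovery.

test_that("generators are bytewise deterministic under a fixed seed", {
  a <- gen_mito_image(fragmentation = 0.4, seed = 11, dim = c(96L, 96L),
                      total_length = 60)
  b <- gen_mito_image(fragmentation = 0.4, seed = 11, dim = c(96L, 96L),
                      total_length = 60)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$trees, b$truth$trees)

  expect_identical(gen_micropattern_image(6, seed = 3)$image$data,
                   gen_micropattern_image(6, seed = 3)$image$data)
  expect_identical(gen_stain_image(0.3, seed = 4)$image$data,
                   gen_stain_image(0.3, seed = 4)$image$data)
  expect_identical(gen_melatonin_series(0.5, seed = 5),
                   gen_melatonin_series(0.5, seed = 5))
  expect_identical(gen_conversion_curve(seed = 6),
                   gen_conversion_curve(seed = 6))
  # a generator call does not disturb the caller's RNG stream
  set.seed(42); r1 <- runif(1)
  set.seed(42); invisible(gen_stain_image(0.2, seed = 9)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("mito generator: fragmentation 0 gives one tree, polylines stay in bounds", {
  g <- gen_mito_image(fragmentation = 0, seed = 7)
  expect_length(g$truth$trees, 1L)
  pts <- do.call(rbind, unlist(g$truth$trees, recursive = FALSE))
  expect_true(all(pts[, 1] >= 0 & pts[, 1] <= g$truth$dim[2] * 0.3))
  expect_true(all(pts[, 2] >= 0 & pts[, 2] <= g$truth$dim[1] * 0.3))
  # realized truth length matches the budget closely
  expect_equal(truth_total_length(g$truth), 450, tolerance = 0.05)
  expect_error(gen_mito_image(0.5, seed = 1, dim = c(8L, 8L)),
               "too small")
})

test_that("mito generator: mean truth tree count strictly increases with fragmentation", {
  frags <- seq(0, 1, by = 0.25)
  mean_trees <- vapply(frags, function(f) {
    mean(vapply(1:10, function(s)
      length(gen_mito_image(f, seed = s, dim = c(96L, 96L),
                            total_length = 80, noise = 0)$truth$trees),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_trees) > 0))
})

test_that("micropattern generator conserves area and supports empty fields", {
  g <- gen_micropattern_image(1, seed = 2, mean_area = 2000, sd_area = 0,
                              p_empty = 0, p_doublet = 0, noise = 0)
  expect_equal(sum(g$image$data > 0.5), 2000, tolerance = 0.02)
  e <- gen_micropattern_image(0, seed = 2)
  expect_equal(sum(e$image$data > 0.5), 0)
  expect_equal(nrow(e$truth), 0L)
  expect_error(gen_micropattern_image(4, seed = 1, p_empty = 0.7,
                                      p_doublet = 0.4), "exceed")
})

test_that("micropattern generator: mean area of 100 cells recovered within 3%", {
  g <- gen_micropattern_image(100, seed = 31, mean_area = 1900,
                              p_empty = 0, p_doublet = 0)
  rec <- detect_cells(g$image, g$layout)
  m <- spreading_metrics(rec)
  truth_mean <- mean(g$truth$area)
  expect_equal(m$mean_area_um2, truth_mean, tolerance = 0.03)
  expect_equal(m$n_cells, 100L)
})

test_that("stain generator hits the exact stained fraction at the extremes", {
  g0 <- gen_stain_image(0, seed = 5)
  expect_equal(sum(select_stain_pixels(g0$image) & g0$roi), 0)
  g1 <- gen_stain_image(1, seed = 5)
  expect_equal(sum(select_stain_pixels(g1$image) & g1$roi), sum(g1$roi))
  expect_error(gen_stain_image(0.5, seed = 1,
                               roi = matrix(FALSE, 10, 10)), "ROI")
  g <- gen_stain_image(0.4, seed = 6)
  expect_equal(g$truth$n_stained, floor(0.4 * sum(g$roi)))
})

test_that("melatonin generator: night bump behaves at the suppression extremes", {
  s0 <- gen_melatonin_series(0, seed = 8, noise = 0)
  d1 <- s0[s0$day == 1, ]
  base <- d1$value[d1$offset_h < 0]
  expect_true(all(d1$value[d1$offset_h >= 0] > max(base)))
  ind0 <- night_induction(s0, day_index = 1)
  expect_equal(mean(ind0$induction), 20, tolerance = 1e-12)

  s1 <- gen_melatonin_series(1, seed = 8, noise = 0)
  ind1 <- night_induction(s1, day_index = 1)
  expect_equal(ind1$induction, rep(0, nrow(ind1)), tolerance = 1e-12)
  expect_error(gen_melatonin_series(0.3, seed = 1, amplitude = -2),
               "amplitude")
})

test_that("melatonin suppression 0.6 is recovered within 0.1 from 200 noisy replicates", {
  s <- gen_melatonin_series(0.6, seed = 12, n_replicates = 200)
  expect_lt(abs(estimate_suppression(s, amplitude = 20) - 0.6), 0.1)
})

test_that("conversion generator: boundary values and exact molar balance", {
  k <- gen_conversion_curve(seed = 2, cv = 0)
  expect_equal(k$crocetin_mM[k$time_h == 0], 0)
  expect_equal(k$crocin_mM[k$time_h == 0], 1.79)
  expect_lt(k$crocin_mM[nrow(k)], 0.01 * 1.79)
  expect_true(all(diff(k$crocin_true_mM) <= 0))
  expect_true(all(diff(k$crocetin_true_mM) >= 0))
  expect_equal(k$crocin_true_mM + k$crocetin_true_mM,
               rep(1.79, nrow(k)), tolerance = 1e-9)
  expect_error(gen_conversion_curve(c0 = -1, seed = 1), ">= 0")
  expect_error(gen_conversion_curve(seed = 1, rate = 0), "> 0")
})
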
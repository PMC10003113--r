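# Cell detection on patterns, area measurement, spreading summary.

test_that("detection yields one record per pattern and excludes doublets", {
  g <- gen_micropattern_image(10, seed = 17, p_empty = 0, p_doublet = 0)
  rec <- detect_cells(g$image, g$layout)
  expect_equal(nrow(rec), 10)
  expect_true(all(rec$status == "ok"))

  gd <- gen_micropattern_image(12, seed = 23, p_empty = 0.2, p_doublet = 0.5)
  recd <- detect_cells(gd$image, gd$layout)
  truth <- gd$truth
  expect_true(all(recd$status[truth$occupancy == "doublet"] == "multiple"))
  expect_true(all(recd$status[truth$occupancy == "empty"] == "empty"))
  expect_error(detect_cells(g$image, NULL), "layout")
})

test_that("singleton patterns are recovered in at least 95% of cases", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    g <- gen_micropattern_image(8, seed = 200 + s)
    rec <- detect_cells(g$image, g$layout)
    singles <- g$truth$occupancy == "single"
    hits <- hits + sum(rec$status[singles] == "ok")
    total <- total + sum(singles)
  }
  expect_gte(hits / total, 0.95)
})

test_that("cell area is pixel count times squared pixel size", {
  m <- matrix(FALSE, 60, 60); m[1:40, 1:50] <- TRUE
  expect_equal(cell_area(m, 1), 2000)
  m2 <- matrix(FALSE, 30, 30); m2[1:20, 1:25] <- TRUE
  expect_equal(cell_area(m2, 2), 2000)
  expect_error(cell_area(matrix(FALSE, 5, 5), 1), "empty")
  g <- gen_micropattern_image(1, seed = 3, mean_area = 2100, sd_area = 0,
                              p_empty = 0, p_doublet = 0, noise = 0)
  rec <- detect_cells(g$image, g$layout)
  expect_equal(rec$area_um2, g$truth$area, tolerance = 0.02)
})

test_that("spreading metrics count strictly above the threshold", {
  rec <- data.frame(area_um2 = c(2000, 1500, 1900))
  m <- spreading_metrics(rec, threshold = 1800)
  expect_equal(m$mean_area_um2, 1800)
  expect_equal(m$pct_spread, 100 * 2 / 3)
  expect_equal(spreading_metrics(data.frame(area_um2 = 1800))$pct_spread, 0)
  expect_equal(spreading_metrics(data.frame(area_um2 = c(1900, 2400)))$pct_spread,
               100)
  expect_error(spreading_metrics(data.frame(area_um2 = numeric(0))),
               "no measurable")
})

test_that("percentage spread is invariant to relabeling and monotone in the threshold", {
  set.seed(5)
  areas <- runif(40, 1200, 2600)
  a <- spreading_metrics(data.frame(area_um2 = areas))
  b <- spreading_metrics(data.frame(area_um2 = sample(areas)))
  expect_equal(a, b)
  ths <- seq(1000, 2800, by = 200)
  pct <- vapply(ths, function(t)
    spreading_metrics(data.frame(area_um2 = areas), t)$pct_spread,
    numeric(1))
  expect_true(all(diff(pct) <= 0))
})

test_that("mean area is stable under pixel-size-consistent re-rendering", {
  g1 <- gen_micropattern_image(20, seed = 9, pixel_size = 1,
                               p_empty = 0, p_doublet = 0)
  g2 <- gen_micropattern_image(20, seed = 9, pixel_size = 0.5,
                               p_empty = 0, p_doublet = 0)
  m1 <- spreading_metrics(detect_cells(g1$image, g1$layout))
  m2 <- spreading_metrics(detect_cells(g2$image, g2$layout))
  expect_equal(m1$mean_area_um2, m2$mean_area_um2, tolerance = 0.02)
})
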
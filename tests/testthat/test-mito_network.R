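# Segmentation, thinning, skeleton-graph decomposition and network metrics.

test_that("segmentation rejects flat images and honors the invert flag", {
  expect_error(segment_mitochondria(matrix(0.5, 32, 32)), "no contrast")
  g <- gen_mito_image(0.3, seed = 4, dim = c(96L, 96L), total_length = 60,
                      noise = 0)
  m1 <- segment_mitochondria(g$image)
  m2 <- segment_mitochondria(raster_image(max(g$image$data) - g$image$data,
                                          0.3), invert = TRUE)
  expect_identical(m1, m2)
})

test_that("noise-free segmentation covers the rendered filament pixels", {
  g <- gen_mito_image(0.3, seed = 4, dim = c(128L, 128L), total_length = 80,
                      noise = 0)
  mask <- segment_mitochondria(g$image)
  # centerline pixels of the generating polylines
  px <- lapply(unlist(g$truth$trees, recursive = FALSE), function(p) {
    seg <- diff(p)
    pts <- NULL
    for (s in seq_len(nrow(seg))) {
      tt <- seq(0, 1, length.out = 20)
      pts <- rbind(pts, cbind(p[s, 1] + tt * seg[s, 1],
                              p[s, 2] + tt * seg[s, 2]))
    }
    pts
  })
  px <- do.call(rbind, px)
  rr <- base::pmin(base::pmax(round(px[, 2] / 0.3 + 0.5), 1), 128)
  cc <- base::pmin(base::pmax(round(px[, 1] / 0.3 + 0.5), 1), 128)
  covered <- mean(mask[cbind(rr, cc)])
  expect_gte(covered, 0.99)
})

test_that("segmentation overlaps the truth mask under the full noise model", {
  jac <- c()
  for (s in 1:3) {
    noisy <- gen_mito_image(0.3, seed = s + 60, noise = 1)
    clean <- gen_mito_image(0.3, seed = s + 60, noise = 0)
    truth_mask <- segment_mitochondria(clean$image, blur_sigma = 0)
    mask <- segment_mitochondria(noisy$image)
    jac <- c(jac, sum(mask & truth_mask) / sum(mask | truth_mask))
  }
  expect_true(all(jac >= 0.8))
})

test_that("thinning gives the medial axis of a solid bar and keeps components", {
  bar <- matrix(0, 7, 15); bar[3:5, 3:13] <- 1
  sk <- skeletonize(bar)
  expect_equal(which(sk, arr.ind = TRUE),
               cbind(row = rep(4L, 11), col = 3:13), ignore_attr = TRUE)
  expect_equal(sum(skeletonize(matrix(0, 10, 10))), 0)
  set.seed(14)
  for (i in 1:50) {
    m <- matrix(rbinom(400, 1, 0.4), 20, 20)
    m <- EBImage::imageData(EBImage::dilate(EBImage::Image(m),
                                            EBImage::makeBrush(3, "box")))
    sk <- skeletonize(m)
    expect_equal(max(label_components(sk)), max(label_components(m)))
  }
})

test_that("graph construction matches forced decompositions of simple shapes", {
  fx <- raster_fixtures()
  g <- build_graph(fx$line, pixel_size = 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)
  expect_equal(sum(g$nodes$kind == "junction"), 0)
  expect_length(g$edges, 1)
  expect_equal(g$edges[[1]]$length_um, 10)

  g <- build_graph(fx$tee, pixel_size = 1)
  expect_equal(sum(g$nodes$kind == "junction"), 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 3)
  expect_length(g$edges, 3)

  g <- build_graph(fx$isolated, pixel_size = 1)
  expect_equal(g$nodes$kind, "isolated")
  expect_length(g$edges, 0)
})

test_that("trees are connected components with conserved lengths", {
  fx <- raster_fixtures()
  expect_length(decompose_trees(build_graph(fx$two_components, 1)), 2)
  tee <- decompose_trees(build_graph(fx$tee, 1))
  expect_length(tee, 1)
  expect_length(tee[[1]]$branch_lengths, 3)
  expect_length(decompose_trees(build_graph(matrix(0, 5, 5), 1)), 0)
  # conservation at 1e-9 on random skeletons
  for (sk in random_skeletons(10, seed = 7)) {
    trees <- decompose_trees(build_graph(sk, 0.3))
    for (tr in trees)
      expect_equal(tr$length_um, sum(tr$branch_lengths), tolerance = 1e-9)
    met <- network_metrics(trees)
    expect_equal(met$network_total_length,
                 sum(vapply(trees, `[[`, numeric(1), "length_um")),
                 tolerance = 1e-9)
  }
})

test_that("network metrics follow the arithmetic definitions", {
  trees <- list(list(branch_lengths = c(4, 3, 3), length_um = 10))
  m <- network_metrics(trees)
  expect_equal(m$network_total_length, 10)
  expect_equal(m$avg_branch_length, 10 / 3)
  expect_equal(m$max_branch_length, 4)
  expect_equal(m$trees_per_length, 1 / 10)
  expect_equal(m$branches_per_length, 3 / 10)

  m0 <- network_metrics(list())
  expect_equal(m0$network_total_length, 0)
  expect_true(is.na(m0$avg_tree_length))
  expect_true(is.na(m0$trees_per_length))
})

test_that("tracing equals the exhaustive pixel-graph census", {
  fx <- raster_fixtures()
  for (nm in names(fx))
    expect_census_equal(graph_census(fx[[nm]], 1),
                        skeleton_census(fx[[nm]], 1), label = nm)
  for (sk in random_skeletons(20, seed = 21))
    expect_census_equal(graph_census(sk, 0.3), skeleton_census(sk, 0.3))
})

test_that("length measurement is calibrated on axial and diagonal segments", {
  for (n in c(5, 11)) {
    ax <- matrix(0, 15, 15); ax[4, 2:(n + 1)] <- 1
    di <- matrix(0, 15, 15); di[cbind(2:(n + 1), 2:(n + 1))] <- 1
    expect_equal(graph_census(ax, 0.5)$total_length, (n - 1) * 0.5)
    expect_equal(graph_census(di, 0.5)$total_length,
                 (n - 1) * sqrt(2) * 0.5)
  }
})

test_that("detected metrics recover the ground truth within 10% at zero noise", {
  fields <- c("network_total_length", "trees_per_length", "avg_tree_length",
              "branches_per_length", "avg_branch_length")
  for (frag in c(0.3, 0.6)) {
    rel <- matrix(0, 6, length(fields))
    for (i in 1:6) {
      g <- gen_mito_image(frag, seed = i + 40, noise = 0)
      tm <- truth_network_metrics(g$truth)
      det <- analyze_mito_cell(g$image)
      rel[i, ] <- as.numeric(det[1, fields]) / as.numeric(tm[1, fields])
    }
    expect_equal(colMeans(rel), rep(1, length(fields)), tolerance = 0.1)
  }
})

test_that("well aggregation is the unweighted mean over cells", {
  one <- data.frame(network_total_length = 120, n_trees = 4L)
  expect_equal(aggregate_well(one)$network_total_length, 120)
  two <- data.frame(network_total_length = c(100, 300), n_trees = c(2L, 6L))
  agg <- aggregate_well(two)
  expect_equal(agg$network_total_length, 200)
  expect_equal(agg$n_cells, 2L)
  expect_error(aggregate_well(two[0, ]), "no cells")
})
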
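# Small skeleton rasters with known decompositions, all <= 15x15.

raster_fixtures <- function() {
  line <- matrix(0, 15, 15); line[8, 3:13] <- 1
  diagonal <- matrix(0, 15, 15); diagonal[cbind(3:11, 3:11)] <- 1
  tee <- matrix(0, 15, 15); tee[2, 3:7] <- 1; tee[2:8, 5] <- 1
  why <- matrix(0, 15, 15); why[5:9, 5] <- 1
  for (k in 1:3) { why[5 - k, 5 - k] <- 1; why[5 - k, 5 + k] <- 1 }
  plus <- matrix(0, 15, 15); plus[8, 4:12] <- 1; plus[4:12, 8] <- 1
  ring <- matrix(0, 15, 15)
  ring[4, 4:8] <- 1; ring[8, 4:8] <- 1; ring[4:8, 4] <- 1; ring[4:8, 8] <- 1
  diamond <- matrix(0, 15, 15)
  diamond[rbind(c(3, 7), c(4, 8), c(5, 9), c(6, 10), c(7, 9), c(8, 8),
                c(9, 7), c(8, 6), c(7, 5), c(6, 4), c(5, 5), c(4, 6))] <- 1
  two <- matrix(0, 15, 15); two[3, 2:6] <- 1; two[10:14, 10] <- 1
  iso <- matrix(0, 15, 15); iso[7, 7] <- 1
  list(line = line, diagonal = diagonal, tee = tee, why = why, plus = plus,
       ring = ring, diamond = diamond, two_components = two,
       isolated = iso)
}

# random thinned blob rasters for property tests
random_skeletons <- function(n, seed = 99, size = 20L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- matrix(stats::rbinom(size^2, 1, 0.4), size, size)
    m <- EBImage::imageData(EBImage::dilate(EBImage::Image(m),
                                            EBImage::makeBrush(3, "box")))
    skeletonize(m) * 1
  })
}

expect_census_equal <- function(a, b, label = "") {
  expect_equal(a$n_endpoints, b$n_endpoints, info = label)
  expect_equal(a$n_junctions, b$n_junctions, info = label)
  expect_equal(a$n_isolated, b$n_isolated, info = label)
  expect_equal(a$n_trees, b$n_trees, info = label)
  expect_equal(a$n_branches, b$n_branches, info = label)
  expect_equal(a$branch_lengths, b$branch_lengths, tolerance = 1e-12,
               info = label)
  expect_equal(a$tree_lengths, b$tree_lengths, tolerance = 1e-12,
               info = label)
}
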
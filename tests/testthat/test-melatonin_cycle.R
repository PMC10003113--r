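# Phase alignment, night induction, and condition comparison for the
# cyclized co-culture series.

test_that("phase alignment round-trips generator labels and is order invariant", {
  s <- gen_melatonin_series(0.4, seed = 19)
  raw <- s[, c("condition", "replicate", "time_h", "value")]
  lab <- phase_align(raw)
  expect_equal(lab$day, s$day)
  expect_equal(lab$offset_h, s$offset_h)
  expect_equal(lab$phase, s$phase)

  shuffled <- raw[sample(nrow(raw)), ]
  lab2 <- phase_align(shuffled)
  expect_equal(lab2[order(lab2$replicate, lab2$time_h), ]$offset_h,
               lab[order(lab$replicate, lab$time_h), ]$offset_h)

  empty <- phase_align(raw[0, ])
  expect_equal(nrow(empty), 0)
  bad <- raw; bad$time_h[3] <- 99.9
  expect_error(phase_align(bad), "99.9")
})

test_that("induction estimator is exact at zero noise and tightens with replicates", {
  s <- gen_melatonin_series(0.25, seed = 7, noise = 0)
  ind <- night_induction(s, 1)
  expect_equal(ind$induction, rep(20 * 0.75, nrow(ind)), tolerance = 1e-12)
  expect_error(night_induction(s[s$offset_h > 0, ], 1), "baseline")

  err_for_n <- function(n) {
    ests <- vapply(1:12, function(seed)
      estimate_suppression(gen_melatonin_series(0.5, seed = seed,
                                                n_replicates = n),
                           amplitude = 20), numeric(1))
    stats::sd(ests)
  }
  e8 <- err_for_n(8); e128 <- err_for_n(128)
  expect_lt(e128, e8 / 2)  # consistent with 1/sqrt(n): expect a 4x drop
})

test_that("condition comparison flags suppression and tolerates self-comparison", {
  a <- gen_melatonin_series(0, seed = 31, n_replicates = 8,
                            condition = "untreated")
  b <- gen_melatonin_series(0.9, seed = 32, n_replicates = 8,
                            condition = "blue light")
  cmp <- compare_conditions(rbind(a, b), reference = "blue light")
  expect_equal(cmp$group, "untreated")
  expect_lt(cmp$p, 0.05)
  expect_gt(cmp$effect_pct, 0)

  self <- rbind(a, transform(a, condition = "copy"))
  cmp2 <- compare_conditions(self, reference = "untreated")
  expect_equal(cmp2$p, 1, tolerance = 1e-6)

  small <- rbind(a[a$replicate <= 2, ], b[b$replicate <= 2, ])
  expect_error(compare_conditions(small, reference = "blue light"),
               "replicates")
})

test_that("blue-light suppression is detected reliably at low noise", {
  hits <- 0L
  for (s in 1:20) {
    a <- gen_melatonin_series(0, seed = 2 * s, n_replicates = 6, noise = 1,
                              condition = "untreated")
    b <- gen_melatonin_series(1, seed = 2 * s + 1, n_replicates = 6,
                              noise = 1, condition = "blue light")
    cmp <- compare_conditions(rbind(a, b), reference = "blue light")
    hits <- hits + (cmp$p < 0.05)
  }
  expect_gte(hits / 20, 0.95)
})
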
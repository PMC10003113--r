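# Dose arithmetic, molar conversions, conversion balance, spectrum summary.

test_that("cumulative dose reproduces the exposure schedules", {
  expect_equal(cumulative_dose(63.75, 4), 255)
  expect_equal(cumulative_dose(20, 1), 20)
  expect_equal(cumulative_dose(17.3, 0), 0)
  expect_error(cumulative_dose(-1, 2), "must be")
  expect_error(cumulative_dose(10, 2.5), "integer")
  # additivity in the exposure count
  expect_equal(cumulative_dose(63.75, 3) + cumulative_dose(63.75, 1),
               cumulative_dose(63.75, 4))
})

test_that("molar content converts mass fraction to mmol/kg", {
  expect_equal(round(molar_content(0.35, MOLAR_MASS["crocin"])), 358,
               ignore_attr = TRUE)
  expect_equal(molar_content(0, 123), 0)
  expect_equal(round(molar_content(1, MOLAR_MASS["crocetin"])), 3045,
               ignore_attr = TRUE)
  expect_error(molar_content(0.2, 0), "positive")
  # homogeneity: doubling the fraction doubles the content, exactly
  expect_identical(molar_content(0.4, 976.97), 2 * molar_content(0.2, 976.97))
})

test_that("conversion balance holds for generator output and flags completion", {
  k <- gen_conversion_curve(seed = 3, cv = 0)
  bal <- conversion_balance(k)
  expect_equal(bal$balance, rep(1, nrow(k)), tolerance = 1e-9)
  expect_equal(bal$completion_time_h, 210)
  expect_true(bal$plateaued)

  trunc <- k[k$time_h <= 60, ]
  expect_true(is.na(conversion_balance(trunc)$completion_time_h))
  expect_error(conversion_balance(data.frame(time_h = 0, crocin_mM = 0,
                                             crocetin_mM = 0)), "positive")
})

test_that("balance stays near one under 5% measurement noise", {
  means <- vapply(1:20, function(s)
    conversion_balance(gen_conversion_curve(seed = s, cv = 0.05))$mean_balance,
    numeric(1))
  expect_true(all(abs(means - 1) < 0.05))
})

test_that("spectrum summary finds the peak and the blue-band fraction", {
  wl <- seq(350, 600, by = 1)
  gauss <- exp(-(wl - 430)^2 / (2 * 30^2))
  s <- spectrum_summary(wl, gauss)
  expect_equal(s$lambda_max_nm, 430)
  flat <- spectrum_summary(wl, rep(1, length(wl)))
  expect_equal(flat$blue_fraction, 90 / 250, tolerance = 1e-12)
  # band edges are interpolated: a misaligned grid gives the same fraction
  wl2 <- c(350, seq(351.3, 598.7, by = 7), 600)
  expect_equal(spectrum_summary(wl2, rep(1, length(wl2)))$blue_fraction,
               90 / 250, tolerance = 1e-12)
  expect_error(spectrum_summary(wl, rep(0, length(wl))), "no absorbance")
  expect_error(spectrum_summary(seq(420, 600), rep(1, 181)), "cover")
})
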
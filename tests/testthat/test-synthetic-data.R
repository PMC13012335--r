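test_that("simulated IRFs are normalized, single-peaked and have the requested width", {
  ax <- bench_axis()
  irf <- simulate_irf(ax, fwhm = 0.25, center = 2.0)
  expect_equal(sum(irf$weights), 1)
  # empirical FWHM within one bin of the requested 250 ps
  half <- max(irf$weights) / 2
  above <- which(irf$weights >= half)
  emp_fwhm <- (max(above) - min(above) + 1) * ax$bin_width
  expect_lt(abs(emp_fwhm - 0.25), ax$bin_width)
  # narrow limit: fwhm of one bin concentrates the mass in <= 3 bins
  narrow <- simulate_irf(ax, fwhm = ax$bin_width, center = 2.0)
  top3 <- sum(sort(narrow$weights, decreasing = TRUE)[1:3])
  expect_gt(top3, 0.99)
  expect_error(simulate_irf(ax, fwhm = 0), "fwhm")
  expect_error(simulate_irf(ax, fwhm = ax$period / 2), "fwhm")
})

test_that("decay simulation is Poisson-consistent, seeded and handles the empty case", {
  ax <- small_axis(n = 256)
  irf <- simulate_irf(ax, fwhm = 0.25, center = 1.0)
  empty <- simulate_decay(decay_params(2.0, 0, background = 0), irf, ax, seed = 1)
  expect_true(all(empty$counts == 0))
  d1 <- simulate_decay(decay_params(2.0, 1e5), irf, ax, seed = 99)
  d2 <- simulate_decay(decay_params(2.0, 1e5), irf, ax, seed = 99)
  expect_identical(d1$counts, d2$counts)
  # mean of total counts over 200 seeded replicates within 3 SE of the budget
  totals <- vapply(1:200, function(s) {
    sum(simulate_decay(decay_params(2.0, 1e5), irf, ax, seed = s)$counts)
  }, numeric(1))
  se <- sqrt(1e5 / 200)
  expect_lt(abs(mean(totals) - 1e5), 3 * se)
})

test_that("re-emission cascade has mean tau/(1-p) and reduces to the monoexp kernel", {
  long_ax <- time_axis(0.05, 4000, 200)  # span >> tau/(1-p), wrap negligible
  expect_equal(simulate_reemission_decay(2.0, reemission_params(0), long_ax),
               monoexp_kernel(2.0, long_ax))
  t <- bin_centers(long_ax)
  means <- sapply(c(0.1, 0.3, 0.5), function(p) {
    k <- simulate_reemission_decay(2.0, reemission_params(p), long_ax)
    sum(k * t)
  })
  expect_equal(means, 2.0 / (1 - c(0.1, 0.3, 0.5)), tolerance = 0.01)
  expect_true(all(diff(means) > 0))
  expect_error(reemission_params(1.0), "p must")
})

test_that("quadrant and bar-target layouts have the specified geometry", {
  lay <- make_quadrant_layout(c(4, 4))
  expect_equal(as.vector(table(lay$name)[phantom_specs()$name]), rep(4L, 4))
  expect_equal(lay$tau[1, 1], 0.80)          # top-left purple
  expect_equal(lay$tau[4, 4], 3.61)          # bottom-right orange
  bar <- make_bar_target_layout(c(8, 32), bar_period_px = 8, blur_sigma_px = 0)
  expect_true(all(bar$intensity %in% c(0, phantom_specs()$relative_intensity[4])))
  # blur shrinks the modulation depth of the layout
  depth <- sapply(c(0, 1, 2, 4), function(s) {
    b <- make_bar_target_layout(c(8, 32), bar_period_px = 8, blur_sigma_px = s)
    max(b$intensity) - min(b$intensity)
  })
  expect_true(all(diff(depth) < 0))
  expect_error(make_bar_target_layout(c(8, 32), bar_period_px = 1), "bar_period_px")
})

test_that("FLIM cube generation respects photon budget, mask and seed", {
  lay <- make_quadrant_layout(c(8, 8))
  zero <- simulate_flim_cube(lay, photons_per_pixel = 0, seed = 1)
  expect_true(all(zero$counts == 0))
  mask <- matrix(FALSE, 8, 8); mask[1:2, ] <- TRUE   # 16 defective pixels
  cube <- simulate_flim_cube(lay, photons_per_pixel = 200, seed = 5,
                             defect_mask = mask)
  expect_equal(sum(!cube$valid_mask), 16)
  cube2 <- simulate_flim_cube(lay, photons_per_pixel = 200, seed = 5,
                              defect_mask = mask)
  expect_identical(cube$counts, cube2$counts)
  # per-pixel totals track intensity: orange quadrant ~2.29x brighter budget
  orange_px <- lay$name == "orange"
  totals <- apply(cube$counts, c(1, 2), sum)
  expect_gt(mean(totals[orange_px]), mean(totals[lay$name == "purple"]))
})

test_that("dye-quantity map saturates and stays below p_max", {
  p <- dye_quantity_to_p(c(0, 80, 160, 320, 640))
  expect_equal(p[1], 0)
  expect_true(all(diff(p) > 0))
  expect_true(all(p < 0.3))
  expect_equal(dye_quantity_to_p(320), 0.15)  # half-saturation
})

test_that("photostability series honors trends, replicates and the half-life law", {
  flat <- simulate_photostability_series(3.61, 2.29, hours = 0:10,
                                         noise_cv_lifetime = 0, noise_cv_intensity = 0)
  expect_equal(nrow(flat), 11 * 4)  # 3 lifetime + 1 intensity per point
  expect_true(all(flat$value[flat$quantity == "lifetime"] == 3.61))
  expect_true(all(flat$value[flat$quantity == "intensity"] == 2.29))
  expect_equal(flat$dose[flat$time_h == 10][1], 48.6)
  # bleach rate ln(2)/D_half halves the intensity at D_half
  d_half <- cumulative_dose(1.35, 5)
  bl <- simulate_photostability_series(3.61, 2.0, hours = 0:10,
                                       bleach_rate = log(2) / d_half,
                                       noise_cv_lifetime = 0, noise_cv_intensity = 0)
  i5 <- bl$value[bl$quantity == "intensity" & bl$time_h == 5]
  expect_equal(i5, 1.0)
  expect_error(simulate_photostability_series(3.61, 2.29, hours = c(-1, 0)))
})

test_that("a stable dye preset shows single-digit percent variation under default noise", {
  changes <- vapply(1:100, function(s) {
    ser <- simulate_photostability_series(3.61, 2.29, seed = 1000 + s)
    m <- photostability_metrics(ser)
    m$change_pct[m$quantity == "intensity"]
  }, numeric(1))
  expect_lte(stats::median(changes), 8)
})
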
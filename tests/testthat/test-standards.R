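# Replicates with an exact mean m and sample SD s: {m - s, m, m + s}.
triplet <- function(m, s) c(m - s, m, m + s)

test_that("replicate summaries compute mean, sample SD and CV%", {
  tab <- data.frame(material = "x", value = triplet(0.80, 0.01))
  s <- summarize_replicates(tab)
  expect_equal(s$mean, 0.80)
  expect_equal(s$sd, 0.01)
  expect_equal(s$cv_pct, 1.25)
  ident <- data.frame(material = "y", value = c(2, 2, 2))
  s2 <- summarize_replicates(ident)
  expect_equal(s2$sd, 0)
  expect_equal(s2$cv_pct, 0)
  zero <- data.frame(material = "z", value = c(-1, 1))
  expect_true(is.na(summarize_replicates(zero)$cv_pct))
  expect_error(summarize_replicates(data.frame(material = "w", value = 1)),
               ">= 2 values")
})

test_that("relative intensity follows the inverse-power law", {
  expect_equal(relative_intensity(1.0), 1.0)
  expect_equal(relative_intensity(0.5), 2 * relative_intensity(1.0))
  expect_equal(relative_intensity(0.25) / relative_intensity(0.5), 2.0)
  expect_equal(relative_intensity(0.5, k = 7) / relative_intensity(0.25, k = 7), 0.5)
  expect_error(relative_intensity(0), "positive")
})

test_that("cumulative dose converts irradiance and time and is additive", {
  expect_equal(cumulative_dose(0, 5), 0)
  expect_equal(cumulative_dose(1.35, 1), 4.86)
  expect_equal(cumulative_dose(1.35, 10), 48.6)
  expect_equal(cumulative_dose(1.35, 3) + cumulative_dose(1.35, 7),
               cumulative_dose(1.35, 10))
  expect_error(cumulative_dose(-1, 1), "non-negative")
})

test_that("photostability metrics report min/max variation with exclusions", {
  ser <- data.frame(time_h = 0:1, dose = c(0, 4.86),
                    quantity = "lifetime", value = c(3.53, 3.60))
  m <- photostability_metrics(ser)
  expect_equal(m$change_pct, 100 * (3.60 - 3.53) / 3.53)
  expect_equal(round(m$change_pct, 2), 1.98)
  # alternative denominator
  m_max <- photostability_metrics(ser, denominator = "max")
  expect_equal(m_max$change_pct, 100 * (3.60 - 3.53) / 3.60)
  # constant series
  const <- data.frame(time_h = 0:3, dose = 0:3, quantity = "q", value = 5)
  expect_equal(photostability_metrics(const)$change_pct, 0)
  # excluding the outlying maximum point
  out <- data.frame(time_h = 0:2, dose = 0:2, quantity = "intensity",
                    value = c(1, 2, 1.1))
  expect_equal(photostability_metrics(out, exclude_points = 1)$change_pct, 10,
               tolerance = 1e-12)
  # invariance to ordering and to points inside the existing range
  shuffled <- out[c(3, 1, 2), ]
  expect_equal(photostability_metrics(shuffled), photostability_metrics(out))
  inner <- rbind(out, data.frame(time_h = 3, dose = 3, quantity = "intensity",
                                 value = 1.5))
  expect_equal(photostability_metrics(inner)$change_pct,
               photostability_metrics(out)$change_pct)
  expect_error(photostability_metrics(out, exclude_points = c(0, 2)), "2 time points")
})

test_that("fabrication comparison reports per-batch summaries and the range of means", {
  batches <- list(
    data.frame(value = triplet(3.70, 0.03)),
    data.frame(value = triplet(3.62, 0.02)),
    data.frame(value = triplet(3.61, 0.02))
  )
  cmp <- compare_fabrications(batches)
  expect_equal(cmp$per_batch$mean, c(3.70, 3.62, 3.61))
  expect_equal(cmp$between_batch_range, 0.09)
  same <- compare_fabrications(list(data.frame(value = c(1, 2)),
                                    data.frame(value = c(1, 2))))
  expect_equal(same$between_batch_range, 0)
  expect_error(compare_fabrications(list(data.frame(value = c(1, 2)))),
               ">= 2 batches")
})

test_that("dye-quantity trend flags monotone intensity and flat lifetimes", {
  const <- data.frame(quantity_mg = c(80, 160, 320, 640),
                      tau_bulk = 3.6, tau_confocal = 3.0,
                      intensity = c(1, 2, 3, 4))
  tr <- dye_quantity_trend(const)
  expect_true(tr$intensity_increasing)
  expect_false(tr$tau_bulk_increasing)
  expect_true(tr$tau_bulk_flat)
  expect_true(tr$tau_confocal_flat)
  rising <- const
  rising$tau_bulk <- c(3.6, 3.8, 4.1, 4.5)
  tr2 <- dye_quantity_trend(rising)
  expect_true(tr2$tau_bulk_increasing)
  expect_false(tr2$tau_bulk_flat)
  # duplicates averaged, unsorted input sorted
  dup <- rbind(rising, rising[2, ])
  dup <- dup[sample(nrow(dup)), ]
  expect_equal(dye_quantity_trend(dup)$means, tr2$means)
  expect_error(dye_quantity_trend(rising[1:2, ]), ">= 3")
})
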
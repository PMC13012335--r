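uniform_cube <- function(tau = 2.0, photons = 3000, size = c(8, 8), seed = 21) {
  specs <- data.frame(name = "uni", tau = tau, relative_intensity = 1)
  lay <- make_quadrant_layout(size, specs[rep(1, 4), ])
  simulate_flim_cube(lay, photons_per_pixel = photons, seed = seed)
}

test_that("uniform cubes fit back to a spatially constant lifetime", {
  cube <- uniform_cube(tau = 2.0, photons = 10000)
  img <- fit_cube(cube, min_photons = 100)
  expect_true(all(is.finite(img$tau_map)))
  expect_lt(abs(mean(img$tau_map) - 2.0) / 2.0, 0.03)
  expect_equal(img$intensity_map, apply(cube$counts, c(1, 2), sum))
})

test_that("min_photons semantics leave under-exposed pixels undefined", {
  cube <- uniform_cube(photons = 200)
  expect_warning(img <- fit_cube(cube, min_photons = 1e9), "no pixel")
  expect_true(all(!is.finite(img$tau_map)))
})

test_that("cube fitting equals independent per-pixel tail fits bit for bit", {
  cube <- uniform_cube(photons = 2000, size = c(4, 4))
  img <- fit_cube(cube, min_photons = 10)
  for (i in 1:4) for (j in 1:4) {
    f <- fit_tail(decay_histogram(cube$counts[i, j, ], cube$axis))
    expect_identical(img$tau_map[i, j], f$tau)
  }
})

test_that("masked pixels never contaminate fits or summaries", {
  cube <- uniform_cube(photons = 2000, size = c(6, 6))
  mask <- matrix(TRUE, 6, 6); mask[1, ] <- FALSE
  # poison the masked pixels with absurd sentinel counts
  cube$counts[1, , ] <- 9e6
  poisoned <- flim_cube(cube$counts, cube$axis, valid_mask = mask)
  img <- fit_cube(poisoned, min_photons = 10)
  expect_true(all(!is.finite(img$tau_map[1, ])))
  h <- lifetime_histogram(img)
  expect_equal(h$n, 30)
  expect_lt(abs(h$mean - 2.0), 0.1)
})

test_that("quadrant cubes produce four contiguous lifetime plateaus", {
  lay <- make_quadrant_layout(c(12, 12))
  cube <- simulate_flim_cube(lay, photons_per_pixel = 20000, seed = 8)
  img <- fit_cube(cube, min_photons = 100)
  per_quad <- tapply(img$tau_map, lay$name, mean, na.rm = TRUE)
  truth <- stats::setNames(phantom_specs()$tau, phantom_specs()$name)
  for (nm in names(truth)) {
    expect_lt(abs(per_quad[[nm]] - truth[[nm]]) / truth[[nm]], 0.05)
  }
})

test_that("lifetime histogram statistics match closed forms", {
  img <- structure(list(tau_map = matrix(3.0, 4, 4),
                        intensity_map = matrix(10, 4, 4),
                        chi2_map = matrix(1, 4, 4)),
                   class = "lifetime_image")
  h <- lifetime_histogram(img)
  expect_equal(h$mean, 3.0)
  expect_equal(h$sd, 0)
  # two equal groups at 1 and 3 ns: mean 2, population SD 1 (weighted mode)
  img2 <- structure(list(tau_map = matrix(c(1, 1, 3, 3), 2, 2),
                         intensity_map = matrix(5, 2, 2),
                         chi2_map = matrix(1, 2, 2)),
                    class = "lifetime_image")
  h2 <- lifetime_histogram(img2, weights = "intensity")
  expect_equal(h2$mean, 2.0)
  expect_equal(h2$sd, 1.0)
  hu <- lifetime_histogram(img2)
  expect_equal(hu$mean, 2.0)
  expect_equal(hu$sd, stats::sd(c(1, 1, 3, 3)))
  expect_equal(sum(h2$histogram$weight), sum(img2$intensity_map))
  img_empty <- structure(list(tau_map = matrix(NA_real_, 2, 2),
                              intensity_map = matrix(0, 2, 2),
                              chi2_map = matrix(NA_real_, 2, 2)),
                         class = "lifetime_image")
  expect_error(lifetime_histogram(img_empty), "no defined")
})

test_that("intensity-weighted rendering is deterministic and scale invariant", {
  img <- structure(list(tau_map = matrix(2.0, 4, 4),
                        intensity_map = matrix(stats::runif(16, 10, 100), 4, 4),
                        chi2_map = matrix(1, 4, 4)),
                   class = "lifetime_image")
  r1 <- render_intensity_weighted(img, c(1, 3))
  img2 <- img; img2$intensity_map <- 2 * img$intensity_map
  r2 <- render_intensity_weighted(img2, c(1, 3))
  expect_equal(r1, r2)   # 99th-percentile normalization
  # zero intensity renders black
  img0 <- img; img0$intensity_map <- matrix(0, 4, 4)
  expect_true(all(render_intensity_weighted(img0, c(1, 3)) == 0))
  # constant tau at midpoint: constant hue -> every pixel's RGB proportional
  midhue <- render_intensity_weighted(img, c(1, 3))
  bright <- apply(midhue, c(1, 2), max)
  norm <- sweep(midhue, c(1, 2), pmax(bright, 1e-12), "/")
  expect_lt(max(apply(norm, 3, function(ch) diff(range(ch)))), 1e-6)
  expect_error(render_intensity_weighted(img, c(3, 1)), "tau_range")
})
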
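# KDE-based oscillatory band delimitation.

test_that("pool_centers concatenates peak centers per condition", {
  f1 <- fixture_fit(data.frame(a = c(2, 2), mu = c(6, 15), sigma = c(1, 2)))
  f2 <- fixture_fit(data.frame(a = 2, mu = 15, sigma = 2))
  pooled <- pool_centers(list(vehicle = list(f1), compound = list(f2)))
  expect_equal(pooled$vehicle, c(6, 15))
  expect_equal(pooled$compound, 15)
  # order-invariant
  pooled2 <- pool_centers(list(vehicle = list(f2, f1)))
  expect_equal(pooled2$vehicle, sort(c(6, 15, 15)))
  # bookkeeping across many fits
  fits <- replicate(16, fixture_fit(data.frame(a = 2, mu = c(6, 15), sigma = c(1, 2))),
                    simplify = FALSE)
  expect_equal(attr(pool_centers(list(vehicle = fits)), "counts")[["vehicle"]], 32L)
  empty <- fixture_fit(data.frame(a = numeric(0), mu = numeric(0), sigma = numeric(0)))
  expect_error(pool_centers(list(vehicle = list(empty))), "zero fitted peaks")
})

test_that("kde_density is a normalized Gaussian-kernel density", {
  kd <- kde_density(rep(10, 50), bandwidth = 0.5)
  expect_equal(kd$grid[which.max(kd$density)], 10, tolerance = 0.1)
  expect_true(all(kd$density >= 0))
  expect_equal(oracle_trapz(kd$grid, kd$density), 1, tolerance = 0.01)

  set.seed(8)
  centers <- c(rnorm(100, 10, 0.5), rnorm(100, 40, 2))
  kd2 <- kde_density(centers, bandwidth = 1)
  sch <- derive_band_limits(kd2)
  # two modes within one grid step of 10 and 40
  modes <- kd2$grid[order(kd2$density, decreasing = TRUE)[1]]
  dens_at <- function(f0) kd2$density[which.min(abs(kd2$grid - f0))]
  expect_gt(dens_at(10), dens_at(25))
  expect_gt(dens_at(40), dens_at(25))
  expect_equal(length(sch$limits), 1L)

  expect_error(kde_density(5), ">= 2")
  expect_error(kde_density(c(5, 6), bandwidth = 0), "> 0")
})

test_that("derive_band_limits places boundaries at mixture valleys", {
  kd <- kde_density(rep(10, 40), bandwidth = 1)
  uni <- derive_band_limits(kd)
  expect_equal(length(uni$limits), 0L)
  expect_equal(uni$n_bands, 1L)

  # trimodal mixture with valleys constructed at 5 and 20 Hz
  centers <- rep(c(2.5, 7.5, 32.5), each = 50)
  kd3 <- kde_density(centers, bandwidth = 1)
  tri <- derive_band_limits(kd3)
  expect_equal(length(tri$limits), 2L)
  expect_lt(abs(tri$limits[1] - 5), 0.11)
  expect_lt(abs(tri$limits[2] - 20), 0.11)

  # inflection method brackets each valley with two boundaries
  infl <- derive_band_limits(kd3, method = "inflection")
  expect_gte(length(infl$limits), 2L)
  expect_true(any(infl$limits < 5) && any(infl$limits > 5 & infl$limits < 20))
})

test_that("band limits are equivariant under translation and center permutation", {
  set.seed(9)
  centers <- c(rnorm(60, 20, 1.5), rnorm(60, 50, 3))
  l1 <- derive_band_limits(kde_density(centers, bandwidth = 1))$limits
  l2 <- derive_band_limits(kde_density(sample(centers), bandwidth = 1))$limits
  expect_identical(l1, l2)
  l3 <- derive_band_limits(kde_density(centers + 10, bandwidth = 1))$limits
  expect_equal(l3, l1 + 10, tolerance = 0.11)
})

test_that("seven bands get the canonical ascending labels", {
  cents <- rep(vehicle_mode_centers(), each = 100)
  sch <- derive_band_limits(kde_density(cents, bandwidth = 1), condition = "vehicle")
  expect_equal(sch$labels, canonical_band_labels())
  expect_equal(sch$limits, vehicle_limits, tolerance = 0.101)
  tab <- format_band_scheme(sch)
  expect_equal(tab$range[1], sprintf("<%.1f", sch$limits[1]))
  expect_equal(tab$range[7], sprintf(">%.1f", sch$limits[6]))
  # non-seven-band schemes use generic names
  gen <- band_scheme(c(10, 20))
  expect_equal(gen$labels, c("band1", "band2", "band3"))
  expect_error(band_scheme(c(10, 5)), "increasing")
})
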
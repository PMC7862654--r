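test_that("bilinear upsampling multiplies the grid, preserves constants, averages corners", {
  st <- tiny_stack(n_slices = 2, n_channels = 1, n_px = 8)
  up <- upsample(st, 3)
  expect_equal(dim(up$counts)[3:4], c(24L, 24L))
  expect_equal(pixel_size_nm(up$geometry)$dx_nm,
               pixel_size_nm(st$geometry)$dx_nm / 3)

  const <- ion_stack(array(5, dim = c(1, 1, 8, 8)), st$geometry)
  expect_equal(max(abs(upsample(const, 3)$counts - 5)), 0)

  # 2x2 checkerboard: the field value midway between the four pixel centers
  # is the mean of the corners; the nearest upsampled pixel (input coordinate
  # 1.25) evaluates the hand bilinear formula 0.75^2 + 0.25^2 = 0.625
  g2 <- acq_geometry(0.1, 0.1, n_pixels_x = 2L)
  cb <- ion_stack(array(c(1, 0, 0, 1), dim = c(1, 1, 2, 2)), g2)
  up2 <- upsample(cb, 2)
  center <- iontomo:::bilinear_interp(get_slice(cb, 1, 1), 1.5, 1.5)
  expect_equal(center, mean(c(1, 0, 0, 1)))
  expect_equal(up2$counts[1, 1, 2, 2], 0.625, tolerance = 1e-12)

  expect_error(upsample(st, 0), ">= 1")
  expect_identical(upsample(st, 1), st)
})

test_that("an all-zero slice yields an empty localization list", {
  g <- small_geom()
  loc <- detect_and_localize(matrix(0, 64, 64), g, psf_model(100))
  expect_s3_class(loc, "data.frame")
  expect_equal(nrow(loc), 0L)
})

test_that("a noiseless sub-pixel spot is localized within a tenth of a raw pixel", {
  g <- small_geom()
  truth <- c(x = 1615, y = 1630)  # +0.3 / +0.6 px off pixel centers
  obj <- point_object(truth[["x"]], truth[["y"]], rate = 3000)
  st <- simulate_stack(obj, psf_model(100), NULL, g, 1)
  up <- upsample(st, 3)
  loc <- detect_and_localize(get_slice(up, 1, 1), up$geometry, psf_model(100))
  expect_equal(nrow(loc), 1L)
  expect_lt(abs(loc$x_nm - truth[["x"]]), 5)  # 0.1 raw px = 5 nm
  expect_lt(abs(loc$y_nm - truth[["y"]]), 5)
})

test_that("two spots separated by five PSF widths give exactly two localizations", {
  g <- small_geom()
  obj <- object_volume(points = data.frame(
    x_nm = c(1100, 1600), y_nm = c(1600, 2100), z_nm = NA,
    rate = 2000, channel = 1L))
  st <- simulate_stack(obj, psf_model(100), NULL, g, 1)
  up <- upsample(st, 3)
  loc <- detect_and_localize(get_slice(up, 1, 1), up$geometry, psf_model(100))
  expect_equal(nrow(loc), 2L)
})

test_that("SILM rendering conserves mass and is invariant to localization order", {
  g <- small_geom()
  loc <- data.frame(x_nm = c(800, 1900, 2400), y_nm = c(700, 1500, 2900),
                    slice_index = c(1L, 2L, 3L), counts = c(10, 25, 7),
                    precision_nm = 5, fit_kind = "gaussian-fit")
  img <- render_silm(loc, g, render_sigma_nm = 20)
  expect_equal(sum(img$image), sum(loc$counts), tolerance = 1e-6)
  perm <- render_silm(loc[c(3, 1, 2), ], g, render_sigma_nm = 20)
  expect_identical(img$image, perm$image)

  one <- render_silm(loc[2, ], g, render_sigma_nm = 20)
  pk <- which(one$image == max(one$image), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(30, 38))  # (1500, 1900) nm at 50 nm px
  expect_equal(sum(one$image), 25, tolerance = 1e-6)

  empty <- render_silm(loc[0, ], g, render_sigma_nm = 20)
  expect_true(all(empty$image == 0))

  # window filtering
  win <- render_silm(loc, g, render_sigma_nm = 20, window = c(2, 3))
  expect_equal(sum(win$image), 32, tolerance = 1e-6)
})

test_that("unit-weight rendering counts each localization once", {
  g <- small_geom()
  loc <- data.frame(x_nm = c(800, 1900), y_nm = c(700, 1500),
                    slice_index = 1L, counts = c(10, 90),
                    precision_nm = 5, fit_kind = "gaussian-fit")
  uw <- render_silm(loc, g, render_sigma_nm = 20, unit_weight = TRUE)
  expect_equal(sum(uw$image), 2, tolerance = 1e-6)
})

test_that("an identical noiseless spot repeated across slices has near-zero precision", {
  g <- small_geom()
  obj <- point_object(1615, 1630, rate = 3000)
  st <- simulate_stack(obj, psf_model(100), NULL, g, 20)
  up <- upsample(st, 3)
  loc <- localize_stack(up, 1, psf_model(100))
  expect_equal(nrow(loc), 20L)
  pr <- localization_precision(loc, psf_model(100))
  expect_equal(nrow(pr$clusters), 1L)
  expect_lt(pr$median_precision_nm, 0.01 * 50)  # 0.01 raw px
})

test_that("median localization scatter stays below 25 nm at sub-10-count tag brightness", {
  g <- acq_geometry(3.2, 3.2, n_pixels_x = 64L, beam_width_nm = 100,
                    z_step_nm = 5)
  psf <- psf_model(100)
  spot_sigma <- sqrt(fwhm_to_sigma(100)^2 + (109.8 / 4)^2)
  for (seed in 1:3) {
    obj <- nanotag_fixture(g, 3, seed = seed)
    st <- simulate_stack(obj, psf, noise_model(seed = seed + 100), g, 45)
    # paper-like operating point: typical nonzero pixels below 10 counts
    expect_lte(median(st$counts[st$counts > 0]), 10)
    up <- upsample(st, 3)
    loc <- localize_stack(up, 1, psf, k_sigma = 4, min_counts = 20,
                          spot_sigma_nm = spot_sigma, counts_scale = 9)
    pr <- localization_precision(loc, psf)
    expect_lte(pr$median_precision_nm, 25)
    expect_gte(min(pr$clusters$n), 3)
  }
})

test_that("the documented precision estimator agrees with empirical scatter within 2x", {
  g <- acq_geometry(3.2, 3.2, n_pixels_x = 64L, beam_width_nm = 100,
                    z_step_nm = 5)
  psf <- psf_model(100)
  spot_sigma <- sqrt(fwhm_to_sigma(100)^2 + (109.8 / 4)^2)
  for (seed in 1:3) {
    obj <- nanotag_fixture(g, 3, seed = seed)
    st <- simulate_stack(obj, psf, noise_model(seed = seed + 100), g, 45)
    up <- upsample(st, 3)
    loc <- localize_stack(up, 1, psf, k_sigma = 4, min_counts = 20,
                          spot_sigma_nm = spot_sigma, counts_scale = 9)
    pr <- localization_precision(loc, psf)
    est <- median(loc$precision_nm)
    emp <- pr$median_precision_nm
    expect_lt(max(est / emp, emp / est), 2)
  }
})

test_that("halving the render sigma never merges distinct maxima on a noiseless pair", {
  g <- small_geom()
  loc <- data.frame(x_nm = c(1400, 1800), y_nm = 1600, slice_index = 1L,
                    counts = 10, precision_nm = 5, fit_kind = "gaussian-fit")
  n_big <- nrow(image_maxima(render_silm(loc, g, 60)$image, frac = 0.5))
  n_small <- nrow(image_maxima(render_silm(loc, g, 30)$image, frac = 0.5))
  expect_gte(n_small, n_big)
})
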
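test_that("delta-like PSF and no noise reproduce the rasterized object scaled by efficiency", {
  g <- small_geom()
  # pixel-center position: pixel (33, 21) center is (20.5 * 50, 32.5 * 50)
  obj <- point_object(x_nm = 20.5 * 50, y_nm = 32.5 * 50, rate = 400)
  st <- suppressWarnings(  # delta PSF: undersampling warning is expected
    simulate_stack(obj, psf_model(1e-4), NULL, g, n_slices = 3,
                   efficiency = 0.03))
  for (s in 1:3) {
    img <- get_slice(st, s, 1)
    expect_equal(img[33, 21], 0.03 * 400, tolerance = 1e-12)
    expect_equal(sum(img), 0.03 * 400, tolerance = 1e-9)
  }
})

test_that("simulation is a pure function of inputs and seed", {
  g <- small_geom()
  obj <- six_point_fixture(g, rate = 500)
  a <- simulate_stack(obj, psf_model(120), noise_model(seed = 7), g, 4)
  b <- simulate_stack(obj, psf_model(120), noise_model(seed = 7), g, 4)
  expect_identical(a$counts, b$counts)
  c2 <- simulate_stack(obj, psf_model(120), noise_model(seed = 8), g, 4)
  expect_false(identical(a$counts, c2$counts))
})

test_that("expected total counts match efficiency x emitted within Monte-Carlo error", {
  g <- acq_geometry(1.6, 1.6, n_pixels_x = 32L, beam_width_nm = 100)
  obj <- point_object(x_nm = 800, y_nm = 800, rate = 600)
  n_rep <- 200
  totals <- vapply(seq_len(n_rep), function(s) {
    sum(simulate_stack(obj, psf_model(100),
                       noise_model(seed = s, extraction_efficiency = 0.03),
                       g, 1)$counts)
  }, 0)
  expected <- 0.03 * 600
  se <- sd(totals) / sqrt(n_rep)
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("gamma factors have unit mean and variance 1/k over replicates", {
  set.seed(10)
  k <- 3
  draws <- rgamma(2e5, shape = k, scale = 1 / k)
  expect_equal(mean(draws), 1, tolerance = 0.01)
  expect_equal(var(draws), 1 / k, tolerance = 0.02)
})

test_that("six-point fixture places six collinear sources 200 nm apart, centered", {
  g <- six_point_geometry()
  obj <- six_point_fixture(g)
  pts <- obj$points
  expect_equal(nrow(pts), 6)
  expect_equal(diff(sort(pts$x_nm)), rep(200, 5))
  expect_equal(max(pts$x_nm) - min(pts$x_nm), 1000)
  expect_equal(length(unique(pts$y_nm)), 1L)
  expect_equal(mean(pts$x_nm), 500 * g$scan_area_x_um)
  # noiseless profile symmetric about the field center
  st <- simulate_stack(obj, psf_model(120), NULL, g, 1)
  prof <- get_slice(st, 1, 1)[g$n_pixels_y / 2, ]
  expect_equal(prof, rev(prof), tolerance = 1e-9)
  # field too small
  expect_error(six_point_fixture(acq_geometry(1, 1, n_pixels_x = 20L)),
               "too small")
})

test_that("edge fixture is a column-wise step under a delta PSF", {
  g <- small_geom()
  obj <- edge_fixture(g, edge_x_nm = 1600, rate = 50)
  st <- suppressWarnings(
    simulate_stack(obj, psf_model(1e-4), NULL, g, 1, efficiency = 1))
  img <- get_slice(st, 1, 1)
  expect_true(all(img[, 1:32] == 0))
  expect_true(all(img[, 33:64] == 50))
})

test_that("nanotag channels share identical ground-truth geometry and stated diameters", {
  g <- small_geom()
  obj <- nanotag_fixture(g, 5, channels = 2, seed = 2)
  s1 <- obj$spheres[obj$spheres$channel == 1, c("x_nm", "y_nm", "diameter_nm")]
  s2 <- obj$spheres[obj$spheres$channel == 2, c("x_nm", "y_nm", "diameter_nm")]
  expect_equal(unname(as.matrix(s1)), unname(as.matrix(s2)))
  # noiseless rasterized densities identical across channels
  st <- simulate_stack(obj, psf_model(100), NULL, g, 2)
  expect_equal(st$counts[, 1, , ], st$counts[, 2, , ])
  # diameter sampling matches the stated distribution
  big <- acq_geometry(40, 40, n_pixels_x = 128L)
  d <- nanotag_fixture(big, 500, seed = 4)$spheres
  d <- d$diameter_nm[d$channel == 1]
  expect_lt(abs(mean(d) - 109.8), 3 * 17.6 / sqrt(500))
})

test_that("overcrowded tag placement errors out", {
  g <- acq_geometry(0.6, 0.6, n_pixels_x = 12L)
  expect_error(nanotag_fixture(g, 50, seed = 1, max_tries = 200),
               "non-overlapping")
})

test_that("zero drift is the identity and integer drift inverts on the interior", {
  st <- tiny_stack(n_slices = 4, n_channels = 1, n_px = 16)
  zero <- drift_trace(rep(0, 4), rep(0, 4))
  expect_equal(apply_drift(st, zero)$counts, st$counts)

  fwd <- drift_trace(c(0, 3, 3, 3), c(0, -2, -2, -2))
  bwd <- drift_trace(c(0, -3, -3, -3), c(0, 2, 2, 2))
  round_trip <- apply_drift(apply_drift(st, fwd), bwd)
  interior_r <- 4:13; interior_c <- 4:13
  for (s in 1:4) {
    expect_equal(round_trip$counts[s, 1, interior_r, interior_c],
                 st$counts[s, 1, interior_r, interior_c])
  }
  expect_error(drift_trace(c(1, 0), c(0, 0)), "must be")
  expect_error(apply_drift(st, drift_trace(c(0, 100, 0, 0), rep(0, 4))),
               "larger than the field")
})

test_that("injected fiducial disc area matches the analytic disc within 10%", {
  g <- acq_geometry(6.4, 6.4, n_pixels_x = 128L)
  st <- ion_stack(array(0, dim = c(2, 1, 128, 128)), g)
  dr <- apply_drift(st, drift_trace(c(0, 0), c(0, 0)),
                    fiducial_diameter_um = 2)
  disc_px <- sum(get_slice(dr, 1, "fiducial") > 0)
  expected <- pi * 1000^2 / (50 * 50)
  expect_lt(abs(disc_px - expected) / expected, 0.1)
})

test_that("pulse-chase fixture shares the stated fraction of source positions", {
  g <- small_geom()
  obj <- pulse_chase_fixture(g, n_sources = 40, shared_frac = 0.8, seed = 3)
  p1 <- obj$points[obj$points$channel == 1, ]
  p2 <- obj$points[obj$points$channel == 2, ]
  shared <- sum(p2$x_nm %in% p1$x_nm & p2$y_nm %in% p1$y_nm)
  expect_equal(shared, 32)
})

test_that("negative emission rates are rejected", {
  expect_error(object_volume(points = data.frame(
    x_nm = 1, y_nm = 1, z_nm = NA, rate = -1, channel = 1)), "negative")
})
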
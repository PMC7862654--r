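# Literal transcription of the global-statistics structural-similarity
# formula, used as an independent oracle.
ssim_literal <- function(a, b, k1 = 0.01, k2 = 0.03) {
  nrm <- function(x) (x - min(x)) / (max(x) - min(x))
  x <- nrm(a); y <- nrm(b)
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  vxy <- sum((x - mx) * (y - my)) / n
  C1 <- k1^2; C2 <- k2^2
  ((2 * mx * my + C1) * (2 * vxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

test_that("cc2d satisfies its exact identities and rejects constant images", {
  set.seed(1)
  img <- matrix(runif(100), 10, 10)
  expect_equal(cc2d(img, img)$r, 1)
  expect_equal(cc2d(img, max(img) - img)$r, -1)
  expect_equal(cc2d(img, 3 * img + 7)$r, 1, tolerance = 1e-12)
  flip <- matrix(runif(100), 10, 10)
  expect_equal(cc2d(img, flip)$r, cc2d(flip, img)$r)
  expect_error(cc2d(img, matrix(2, 10, 10)), "constant")
})

test_that("independent noise fields are uncorrelated at fixed seed", {
  set.seed(11)
  a <- matrix(rgamma(256^2, 3, 3), 256, 256)
  b <- matrix(rgamma(256^2, 3, 3), 256, 256)
  expect_lt(abs(cc2d(a, b)$r), 0.05)
})

test_that("colocalization series tracks per-depth overlap and Wilcoxon separates conditions", {
  g <- small_geom()
  psf <- psf_model(100)
  short <- simulate_stack(pulse_chase_fixture(g, 40, 0.8, seed = 1),
                          psf, noise_model(seed = 21), g, 100)
  long <- simulate_stack(pulse_chase_fixture(g, 40, 0.1, seed = 2),
                         psf, noise_model(seed = 22), g, 100)
  cs_short <- colocalization_series(short, 1, 2)
  cs_long <- colocalization_series(long, 1, 2)
  expect_gt(cs_short$summary$median, cs_long$summary$median)
  w <- compare_conditions(cs_short, cs_long)
  expect_lt(w$p.value, 0.01)

  # identical stacks: every slice correlates perfectly
  same <- colocalization_series(short, 1, 1)
  expect_true(all(same$series$r == 1))

  # a series against itself is not distinguishable
  p_self <- compare_conditions(cs_short$series$r, cs_short$series$r)$p.value
  expect_gt(p_self, 0.99)

  expect_error(compare_conditions(1:5, 1:20), "at least 10")
})

test_that("constant slices are skipped and counted in the series", {
  st <- tiny_stack(n_slices = 4, n_channels = 2, n_px = 8, seed = 2)
  st$counts[2, 1, , ] <- 5
  cs <- colocalization_series(st, 1, 2)
  expect_equal(cs$n_skipped, 1L)
  expect_equal(nrow(cs$series), 3L)
})

test_that("ssim matches a literal transcription and satisfies its identities", {
  set.seed(5)
  a <- matrix(runif(400), 20, 20)
  b <- matrix(runif(400), 20, 20)
  expect_equal(ssim(a, b)$value, ssim_literal(a, b), tolerance = 1e-10)
  expect_equal(ssim(a, a)$value, 1, tolerance = 1e-9)
  s_ab <- ssim(a, b)$value
  s_ba <- ssim(b, a)$value
  expect_equal(s_ab, s_ba, tolerance = 1e-12)
  # image vs its normalized negative: below 1
  expect_lt(ssim(a, 1 - a)$value, 1)
  # constant-after-normalization pair stabilized, no error
  expect_no_error(ssim(matrix(2, 12, 12), matrix(5, 12, 12)))
  # windowed value reported alongside the global one
  big <- matrix(runif(144), 12, 12)
  expect_true(is.finite(ssim(big, big)$windowed))
})

test_that("the 88-12%% criterion recovers 2.34998 sigma on analytic blurred edges", {
  z88 <- qnorm(0.88)
  x <- seq(0, 2000, by = 10)
  for (sigma in c(25, 60)) {
    prof <- 5 + 40 * pnorm((x - 1000) / sigma)
    fit <- edge_resolution(x, prof)
    expect_lt(abs(fit$resolution_nm - 2 * z88 * sigma) / (2 * z88 * sigma),
              0.005)
    expect_equal(fit$center_nm, 1000, tolerance = 1)
  }
  # amplitude/offset invariance
  f1 <- edge_resolution(x, 5 + 40 * pnorm((x - 1000) / 50))$resolution_nm
  f2 <- edge_resolution(x, 100 + 900 * pnorm((x - 1000) / 50))$resolution_nm
  expect_equal(f1, f2, tolerance = 1e-6)
  # falling edges fit equally well
  f3 <- edge_resolution(x, 50 - 40 * pnorm((x - 1000) / 50))$resolution_nm
  expect_equal(f3, f1, tolerance = 1e-6)
})

test_that("an ideal step resolves to within one sample spacing", {
  x <- seq(0, 500, by = 10)
  prof <- ifelse(x < 250, 0, 100)
  fit <- edge_resolution(x, prof)
  expect_lte(fit$resolution_nm, 10)
})

test_that("noisy edge profiles average to the closed-form resolution within 5%", {
  sigma <- 50
  x <- seq(0, 2000, by = 25)
  clean <- 10 + 80 * pnorm((x - 1000) / sigma)
  set.seed(31)
  res <- vapply(1:50, function(i) {
    noisy <- clean * rgamma(length(x), shape = 400, scale = 1 / 400)  # 5% noise
    edge_resolution(x, noisy)$resolution_nm
  }, 0)
  expected <- 2 * qnorm(0.88) * sigma
  expect_lt(abs(mean(res) - expected) / expected, 0.05)
})

test_that("degenerate profiles are rejected", {
  expect_error(edge_resolution(1:5, rnorm(5)), "")
  expect_error(edge_resolution(seq(0, 100, 10), rep(3, 11)), "plateau")
})

test_that("edge_profile extracts the column-mean scan with pixel-center positions", {
  g <- small_geom()
  st <- simulate_stack(edge_fixture(g, 1600, 100), psf_model(100), NULL, g, 1)
  ep <- edge_profile(st, 1, 1)
  expect_equal(length(ep$position_nm), 64L)
  expect_equal(ep$position_nm[1], 25)
  fit <- edge_resolution(ep$position_nm, ep$intensity)
  expect_equal(fit$center_nm, 1600, tolerance = 10)
})
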
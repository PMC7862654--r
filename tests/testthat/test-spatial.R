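test_that("fuzzy C-means recovers three planted intensity modes", {
  set.seed(42)
  x <- c(rnorm(600, 0.1, 0.02), rnorm(600, 0.5, 0.02), rnorm(600, 0.9, 0.02))
  truth <- rep(1:3, each = 600)
  sm <- fcm_states(x, C = 3)
  expect_gte(mean(sm$labels == truth), 0.99)
  expect_true(all(abs(sm$centroids - c(0.1, 0.5, 0.9)) < 0.05))
  expect_equal(sm$state_names, c("very-low", "decondensed", "compacted"))
  # membership rows form a probability simplex
  expect_true(all(sm$membership >= 0 & sm$membership <= 1))
  expect_equal(rowSums(sm$membership), rep(1, length(x)), tolerance = 1e-9)
})

test_that("FCM hard labels are invariant to positive affine rescaling", {
  set.seed(8)
  x <- c(rnorm(200, 10, 2), rnorm(200, 50, 2), rnorm(200, 90, 2))
  a <- fcm_states(x, C = 3)
  b <- fcm_states(10 * x + 3, C = 3)
  expect_identical(a$labels, b$labels)
})

test_that("FCM rejects constant volumes and agrees with an established implementation", {
  expect_error(fcm_states(rep(2, 100), C = 3), "degenerate")
  skip_if_not_installed("e1071")
  set.seed(42)
  x <- c(rnorm(300, 0.1, 0.02), rnorm(300, 0.5, 0.02), rnorm(300, 0.9, 0.02))
  mine <- fcm_states(x, C = 3)
  ref <- e1071::cmeans(matrix(x), centers = matrix(mine$centroids), m = 2)
  expect_equal(sort(as.vector(ref$centers)), mine$centroids, tolerance = 1e-3)
})

test_that("K-means recovers planted single-channel blobs and is deterministic", {
  set.seed(1)
  n <- 200
  X <- do.call(rbind, lapply(1:6, function(k) {
    m <- rep(0, 3); m[(k - 1) %% 3 + 1] <- k
    matrix(rnorm(n * 3, rep(m, each = n), 0.05), n, 3)
  }))
  truth <- rep(1:6, each = n)
  kr <- kmeans3d(X, C = 6, seed = 3)
  idx <- seq(1, nrow(X), by = 4)
  expect_gte(rand_index(kr$cluster[idx], truth[idx]), 0.95)
  expect_identical(kr$cluster, kmeans3d(X, C = 6, seed = 3)$cluster)
  expect_equal(dim(kr$zscore_heatmap), c(6L, 3L))
  # cross-check against the reference implementation on the same features
  km <- stats::kmeans(scale(X) |> apply(2, iontomo:::minmax01),
                      centers = 6, nstart = 25)
  expect_gte(rand_index(km$cluster[idx], kr$cluster[idx]), 0.95)
})

test_that("C = 1 clustering puts all voxels together with near-zero z-score means", {
  st <- tiny_stack(n_slices = 2, n_channels = 3, n_px = 8, seed = 4)
  kr <- kmeans3d(st, C = 1, seed = 1)
  expect_true(all(kr$cluster == 1))
  expect_true(all(abs(kr$zscore_heatmap) < 1e-9))
})

test_that("block peak detection counts planted spots and drops edge blocks", {
  img <- matrix(0, 45, 45)  # 2x2 full blocks of 20 px, edges dropped
  spots <- rbind(c(5, 5), c(10, 30), c(30, 10), c(35, 35))
  for (i in seq_len(nrow(spots))) img[spots[i, 1], spots[i, 2]] <- 50
  img <- img + matrix(runif(45 * 45, 0, 0.5), 45, 45)
  ps <- block_peaks(img, block = 20)
  expect_equal(ps$n_blocks, 4L)
  expect_gt(ps$n_dropped, 0)
  expect_equal(nrow(ps$peaks), 4L)
  expect_equal(ps$peaks_per_block, 1.0)
  # flat image: nothing above threshold
  flat <- matrix(1, 40, 40) + matrix(runif(1600, 0, 1e-3), 40, 40)
  expect_equal(nrow(block_peaks(flat, 20)$peaks), 0L)
})

test_that("a dimmer planted image yields fewer peaks per block", {
  g <- small_geom()
  psf <- psf_model(100)
  set.seed(77)
  make_cell <- function(n_sources, seed) {
    obj <- pulse_chase_fixture(g, n_sources = n_sources, shared_frac = 0,
                               rate = 600, seed = seed)
    st <- simulate_stack(obj, psf, noise_model(seed = seed + 40), g, 20)
    apply(st$counts[, 1, , ], c(2, 3), sum)
  }
  untreated <- lapply(1:3, function(s) make_cell(30, s))
  treated <- lapply(1:3, function(s) make_cell(15, s + 10))
  r_un <- peak_rate(untreated, block = 16)
  r_tr <- peak_rate(treated, block = 16)
  expect_lt(r_tr$mean_peaks_per_block, r_un$mean_peaks_per_block)
})

test_that("pairwise peak distances match a brute-force double loop", {
  g <- small_geom()
  set.seed(6)
  peaks <- data.frame(row = sample(60, 5), col = sample(60, 5),
                      slice = sample(10, 5, replace = TRUE))
  got <- peak_pairwise_distances(peaks, g)
  expect_equal(got$n_pairs, 10L)
  manual <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    manual <- c(manual, sqrt(
      (50 * (peaks$col[i] - peaks$col[j]))^2 +
      (50 * (peaks$row[i] - peaks$row[j]))^2 +
      (5 * (peaks$slice[i] - peaks$slice[j]))^2))
  }
  expect_equal(sort(got$distances_nm), sort(manual))
  expect_equal(got$mean_nm, mean(manual))

  # two peaks 4 px apart in one slice: a single 200 nm distance
  two <- data.frame(row = c(10, 10), col = c(10, 14), slice = c(1, 1))
  expect_equal(peak_pairwise_distances(two, g)$distances_nm, 200)

  # duplicated peak flagged as a zero distance
  dup <- peak_pairwise_distances(rbind(two, two[1, ]), g)
  expect_equal(dup$n_zero_distances, 1L)

  # fewer than 2 peaks: empty result with a note
  single <- peak_pairwise_distances(two[1, ], g)
  expect_equal(single$n_pairs, 0L)
  expect_match(single$note, "fewer")
})

test_that("hierarchical clustering of planted voxel groups recovers the split", {
  set.seed(12)
  A <- cbind(rnorm(40, 0, 5), rnorm(40, 0, 5), rnorm(40, 0, 5))
  B <- cbind(rnorm(40, 400, 5), rnorm(40, 400, 5), rnorm(40, 400, 5))
  eh <- euclid_hierarchical(A, B, k = 2)
  expect_equal(length(unique(eh$cluster[eh$source == 1])), 1L)
  expect_equal(length(unique(eh$cluster[eh$source == 2])), 1L)
  expect_false(eh$cluster[1] == eh$cluster[41])
  # symmetric zero-diagonal distance matrix
  M <- as.matrix(eh$dist)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  # subsampling cap honored and seeded
  eh2 <- euclid_hierarchical(A, B, cap = 30, seed = 2)
  expect_equal(length(eh2$cluster), 30L)
})

test_that("channel correlation matrix has unit diagonal and flags constant channels", {
  st <- tiny_stack(n_slices = 3, n_channels = 2, n_px = 10, seed = 13)
  d <- dim(st$counts)
  counts <- array(0, dim = c(d[1], 4, d[3], d[4]))
  counts[, 1:2, , ] <- st$counts
  counts[, 3, , ] <- st$counts[, 1, , ]        # duplicate of channel 1
  counts[, 4, , ] <- 7                         # constant channel
  st4 <- ion_stack(counts, st$geometry,
                   channel_labels = c("a", "b", "a2", "const"))
  cm <- channel_correlation_matrix(st4)
  expect_equal(diag(cm$correlation)[1:3], c(a = 1, b = 1, a2 = 1))
  expect_equal(cm$correlation["a", "a2"], 1)
  expect_true(all(is.na(cm$correlation["const", ])))
  expect_equal(cm$constant_channels, "const")
  expect_true(all(cm$association >= 0, na.rm = TRUE))
  # independent channels decorrelated at scale
  set.seed(3)
  big <- ion_stack(array(rpois(2 * 2 * 64 * 64, 5), dim = c(2, 2, 64, 64)),
                   acq_geometry(3.2, 3.2, n_pixels_x = 64L))
  expect_lt(abs(channel_correlation_matrix(big)$correlation[1, 2]), 0.05)
})
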
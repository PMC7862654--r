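# Spatial-statistics layer: fuzzy C-means chromatin-state segmentation,
# multichannel voxel K-means with z-score heatmap export, block-based peak
# counting, pairwise peak distances, hierarchical clustering of voxel
# positions and channel correlation matrices.

#' Fuzzy C-means chromatin-state segmentation
#'
#' Full FCM iteration on voxel intensities: centroid update with fuzzifier
#' `m`, membership update, until the maximum membership change drops below
#' `tol`. Hard labels are the argmax memberships; states are ordered by
#' ascending centroid intensity and named `very-low < decondensed < compacted`
#' when `C = 3`. The hard labeling is invariant to positive affine rescaling
#' of the input, which is what makes the segmentation robust to dynamic-range
#' differences between ion images.
#'
#' @param volume Numeric array or vector of voxel intensities.
#' @param C Number of states (default 3).
#' @param m Fuzzifier (> 1, default 2).
#' @param tol Convergence tolerance on memberships (default 1e-5).
#' @param max_iter Iteration cap (default 300).
#' @param seed Seed for centroid initialization (default 1).
#' @return A list of class `state_map`: `labels` (integer array like
#'   `volume`), `state_names`, `membership` (voxels x C), `centroids`
#'   (ascending), `converged`, `iterations`.
#' @export
fcm_states <- function(volume, C = 3, m = 2, tol = 1e-5, max_iter = 300,
                       seed = 1) {
  x <- as.vector(volume)
  stopifnot(C >= 2, m > 1)
  if (length(unique(x)) < C)
    stop("degenerate input: fewer than C distinct voxel values")
  set.seed(seed)
  centers <- sort(stats::quantile(x, probs = (seq_len(C) - 0.5) / C,
                                  names = FALSE))
  centers <- centers + stats::rnorm(C, 0, 1e-9 * (diff(range(x)) + 1))
  n <- length(x)
  U <- matrix(1 / C, n, C)
  exp_u <- 2 / (m - 1)
  converged <- FALSE; it <- 0
  repeat {
    it <- it + 1
    D <- abs(outer(x, centers, "-"))
    D <- pmax(D, 1e-12)
    Unew <- 1 / (D^exp_u * rowSums(D^(-exp_u)))
    # voxels coinciding with a centroid get crisp membership
    hit <- which(abs(outer(x, centers, "-")) < 1e-12, arr.ind = TRUE)
    if (nrow(hit)) {
      Unew[hit[, 1], ] <- 0
      Unew[hit] <- 1
    }
    delta <- max(abs(Unew - U))
    U <- Unew
    Um <- U^m
    centers <- colSums(Um * x) / colSums(Um)
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning("fuzzy C-means did not converge within ", max_iter, " iterations")
  ord <- order(centers)
  centers <- centers[ord]
  U <- U[, ord, drop = FALSE]
  labels <- max.col(U, ties.method = "first")
  state_names <- if (C == 3) c("very-low", "decondensed", "compacted")
                 else paste0("state", seq_len(C))
  lab_arr <- array(labels, dim = dim(volume) %||% length(volume))
  structure(list(labels = lab_arr, state_names = state_names, membership = U,
                 centroids = centers, converged = converged, iterations = it),
            class = "state_map")
}

# k-means++ initialization (seeded) on a feature matrix.
kmeanspp_init <- function(X, C) {
  n <- nrow(X)
  centers <- matrix(0, C, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (k in seq(2, length.out = C - 1)) {
    p <- if (sum(d2) == 0) rep(1 / n, n) else d2 / sum(d2)
    idx <- sample.int(n, 1, prob = p)
    centers[k, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[k, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Spatially resolved 3D K-means clustering of voxel channel vectors
#'
#' Voxel features are the per-voxel channel vectors, standardized per channel
#' (zero mean, unit variance) and then min-max normalized to `[0, 1]` (both
#' steps individually switchable). Clustering is k-means++ initialization with
#' a fixed seed followed by Lloyd iterations to an assignment fixed point;
#' empty clusters are re-seeded from the point farthest from its centroid
#' (logged). The per-cluster, per-channel mean z-scores are returned for
#' heatmap export.
#'
#' @param stack An [ion_stack()] (all channels used) or a numeric matrix of
#'   voxel features (voxels x channels).
#' @param C Number of clusters (default 6).
#' @param seed Integer seed.
#' @param scale_features Standardize channels before clustering (default TRUE).
#' @param normalize_features Min-max normalize after standardization (default
#'   TRUE).
#' @param max_iter Lloyd iteration cap.
#' @return A list of class `cluster_result`: `cluster` (per-voxel id),
#'   `zscore_heatmap` (C x channels), `centers`, `inertia`, `iterations`,
#'   `reseeded`, `seed`.
#' @export
kmeans3d <- function(stack, C = 6, seed = 1, scale_features = TRUE,
                     normalize_features = TRUE, max_iter = 100) {
  if (inherits(stack, "ion_stack")) {
    d <- dim(stack$counts)
    X <- sapply(seq_len(d[2]), function(ch) as.vector(stack$counts[, ch, , ]))
    X <- matrix(X, ncol = d[2])
    colnames(X) <- stack$channel_labels
  } else {
    X <- as.matrix(stack)
  }
  if (nrow(X) < C) stop("need at least C voxels")
  Z <- scale(X)                       # per-channel z-scores (always computed)
  Z[is.nan(Z)] <- 0
  feat <- if (scale_features) Z else X
  if (normalize_features) feat <- apply(feat, 2, minmax01)
  feat <- matrix(feat, nrow = nrow(X))
  set.seed(seed)
  centers <- kmeanspp_init(feat, C)
  assign_pts <- function(centers) {
    d2 <- sapply(seq_len(C), function(k)
      rowSums((feat - matrix(centers[k, ], nrow(feat), ncol(feat), byrow = TRUE))^2))
    list(cl = max.col(-d2, ties.method = "first"), d2 = d2)
  }
  cl_old <- rep(0L, nrow(feat)); reseeded <- 0L; it <- 0
  repeat {
    it <- it + 1
    a <- assign_pts(centers)
    cl <- a$cl
    for (k in seq_len(C)) {
      if (!any(cl == k)) {            # empty cluster: reseed farthest point
        own <- a$d2[cbind(seq_len(nrow(feat)), cl)]
        far <- which.max(own)
        cl[far] <- k
        reseeded <- reseeded + 1L
      }
      centers[k, ] <- colMeans(feat[cl == k, , drop = FALSE])
    }
    if (identical(cl, cl_old) || it >= max_iter) break
    cl_old <- cl
  }
  a <- assign_pts(centers)
  inertia <- sum(a$d2[cbind(seq_len(nrow(feat)), a$cl)])
  heat <- t(sapply(seq_len(C), function(k)
    colMeans(Z[a$cl == k, , drop = FALSE])))
  colnames(heat) <- colnames(X)
  structure(list(cluster = a$cl, zscore_heatmap = heat, centers = centers,
                 inertia = inertia, iterations = it, reseeded = reseeded,
                 seed = seed),
            class = "cluster_result")
}

#' Block-based local peak detection
#'
#' Divides an image into `block x block` pixel blocks (incomplete edge blocks
#' are dropped and counted), thresholds each block at its median plus
#' `k_mad` block MADs, and collects local maxima above the block threshold.
#'
#' @param image 2D matrix.
#' @param block Block edge length in pixels (default 20).
#' @param k_mad Threshold multiplier (default 4).
#' @return A list of class `peak_set`: `peaks` (data frame `row, col, value,
#'   block_row, block_col`), `n_blocks`, `n_dropped`, `peaks_per_block`.
#' @export
block_peaks <- function(image, block = 20, k_mad = 4) {
  stopifnot(is.matrix(image), block >= 1)
  nby <- nrow(image) %/% block
  nbx <- ncol(image) %/% block
  if (nby < 1 || nbx < 1) stop("image smaller than one block")
  full_rows <- nby * block; full_cols <- nbx * block
  n_dropped <- (nrow(image) > full_rows) * nbx + (ncol(image) > full_cols) * nby +
    (nrow(image) > full_rows && ncol(image) > full_cols)
  out <- list()
  for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
    rows <- ((by - 1) * block + 1):(by * block)
    cols <- ((bx - 1) * block + 1):(bx * block)
    blk <- image[rows, cols]
    thr <- stats::median(blk) + k_mad * max(raw_mad(blk), 1e-12)
    pk <- local_maxima(blk, threshold = thr)
    if (nrow(pk)) {
      out[[length(out) + 1]] <- data.frame(
        row = rows[1] - 1 + pk[, 1], col = cols[1] - 1 + pk[, 2],
        value = blk[pk], block_row = by, block_col = bx)
    }
  }
  peaks <- if (length(out)) do.call(rbind, out)
           else data.frame(row = integer(0), col = integer(0),
                           value = numeric(0), block_row = integer(0),
                           block_col = integer(0))
  structure(list(peaks = peaks, n_blocks = nby * nbx, n_dropped = n_dropped,
                 peaks_per_block = nrow(peaks) / (nby * nbx)),
            class = "peak_set")
}

#' Mean peaks per block across images
#'
#' Averages [block_peaks()] rates over one or more images (e.g. replicate
#' cells of one condition) and returns the per-image rates for a step plot.
#'
#' @param images A list of 2D matrices.
#' @param block,k_mad Passed to [block_peaks()].
#' @return A list with `mean_peaks_per_block` and `per_image` rates.
#' @export
peak_rate <- function(images, block = 20, k_mad = 4) {
  rates <- vapply(images, function(im)
    block_peaks(im, block = block, k_mad = k_mad)$peaks_per_block, 0)
  list(mean_peaks_per_block = mean(rates), per_image = rates)
}

#' Pairwise Euclidean distances between detected peaks
#'
#' All unordered pair distances in nanometres, with anisotropic voxel scaling
#' (`dx`, `dy`, `z_step`). Zero distances (duplicated peaks) are flagged.
#'
#' @param peaks Data frame with `row, col` (pixels) and optionally `slice`
#'   (depth index), or a `peak_set`.
#' @param geom An [acq_geometry()].
#' @return A list with `distances_nm`, `mean_nm`, `n_pairs`,
#'   `n_zero_distances`, and `histogram` (an [graphics::hist()] object,
#'   computed without plotting); empty with a note when fewer than 2 peaks.
#' @export
peak_pairwise_distances <- function(peaks, geom) {
  if (inherits(peaks, "peak_set")) peaks <- peaks$peaks
  stopifnot(inherits(geom, "acq_geometry"))
  if (is.null(peaks) || nrow(peaks) < 2)
    return(list(distances_nm = numeric(0), mean_nm = NA_real_, n_pairs = 0L,
                n_zero_distances = 0L, histogram = NULL,
                note = "fewer than 2 peaks"))
  px <- pixel_size_nm(geom)
  x <- peaks$col * px$dx_nm
  y <- peaks$row * px$dy_nm
  z <- if ("slice" %in% names(peaks)) peaks$slice * geom$z_step_nm else
    rep(0, nrow(peaks))
  d <- as.vector(stats::dist(cbind(x, y, z)))
  h <- if (length(unique(d)) >= 2)
    graphics::hist(d, breaks = "FD", plot = FALSE) else NULL
  list(distances_nm = d, mean_nm = mean(d), n_pairs = length(d),
       n_zero_distances = sum(d == 0), histogram = h)
}

#' Euclidean-distance hierarchical clustering of voxel positions
#'
#' Pools two voxel coordinate sets, computes the symmetric pairwise Euclidean
#' distance matrix (with a seeded subsampling cap for tractability) and
#' clusters it hierarchically with average linkage.
#'
#' @param voxelsA,voxelsB Matrices/data frames of coordinates (columns =
#'   dimensions, already in physical units).
#' @param cap Maximum pooled voxels (default 2000), subsampled with `seed`.
#' @param seed Subsampling seed.
#' @param linkage Linkage method for [stats::hclust()] (default "average").
#' @param k Number of clusters to cut at (default 2).
#' @return A list with `dist` (the `dist` object), `hclust`, `order`,
#'   `cluster` (cut at `k`), and `source` (1 = A, 2 = B per retained voxel).
#' @export
euclid_hierarchical <- function(voxelsA, voxelsB = NULL, cap = 2000, seed = 1,
                                linkage = "average", k = 2) {
  A <- as.matrix(voxelsA)
  if (!nrow(A)) stop("voxelsA is empty")
  src <- rep(1L, nrow(A))
  X <- A
  if (!is.null(voxelsB)) {
    B <- as.matrix(voxelsB)
    X <- rbind(A, B)
    src <- c(src, rep(2L, nrow(B)))
  }
  if (nrow(X) > cap) {
    set.seed(seed)
    keep <- sort(sample.int(nrow(X), cap))
    X <- X[keep, , drop = FALSE]
    src <- src[keep]
  }
  D <- stats::dist(X)
  hc <- stats::hclust(D, method = linkage)
  list(dist = D, hclust = hc, order = hc$order,
       cluster = stats::cutree(hc, k = k), source = src)
}

#' Channel correlation and association matrices of a stack
#'
#' Pairwise Pearson correlations of the per-voxel channel values over the
#' whole data cube; the association matrix clips correlations at zero (export
#' for chord-diagram drawing, which is out of scope here). Constant channels
#' yield `NA` rows/columns and are flagged.
#'
#' @param stack An [ion_stack()] with at least 2 channels.
#' @return A list with `correlation` (M x M), `association` (non-negative
#'   clipped), `constant_channels`.
#' @export
channel_correlation_matrix <- function(stack) {
  stopifnot(inherits(stack, "ion_stack"))
  d <- dim(stack$counts)
  if (d[2] < 2) stop("need at least 2 channels")
  X <- sapply(seq_len(d[2]), function(ch) as.vector(stack$counts[, ch, , ]))
  colnames(X) <- stack$channel_labels
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  R <- suppressWarnings(stats::cor(X))
  R[const, ] <- NA_real_; R[, const] <- NA_real_
  diag(R)[!const] <- 1
  A <- pmax(R, 0)
  list(correlation = R, association = A,
       constant_channels = stack$channel_labels[const])
}
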
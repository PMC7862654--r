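# Delaunay triangulation (2D) and tetrahedralization (3D) by the
# Bowyer-Watson incremental algorithm, plus the block-neighborhood analysis
# built on it: images/volumes are divided into small pixel blocks, each block
# is reduced to its intensity-weighted center of mass and per-channel signal
# sum, and the Delaunay simplices over the centroids define the molecular
# neighborhood graph.

# Circumcenter and squared circumradius of a (d+1)-point simplex (rows).
circumsphere <- function(P) {
  d <- ncol(P)
  A <- 2 * (P[-1, , drop = FALSE] -
            matrix(P[1, ], nrow(P) - 1, d, byrow = TRUE))
  b <- rowSums(P[-1, , drop = FALSE]^2) - sum(P[1, ]^2)
  c0 <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(c0)) return(NULL)  # degenerate simplex
  list(center = c0, r2 = sum((P[1, ] - c0)^2))
}

#' Delaunay triangulation / tetrahedralization of a point set
#'
#' Incremental Bowyer-Watson construction. Exactly degenerate configurations
#' (collinear / cospherical points) are perturbed by a deterministic, seeded
#' jitter of `1e-6` units and retried; a `jittered` flag reports this.
#'
#' @param points Numeric matrix with 2 (triangles) or 3 (tetrahedra) columns.
#' @param jitter_seed Seed for the degeneracy jitter (default 1).
#' @return A list with `simplices` (integer matrix, one simplex per row,
#'   vertex indices into `points`), `jittered`, and `points` (the input
#'   coordinates, jittered if degeneracy required it).
#' @export
delaunay <- function(points, jitter_seed = 1) {
  P <- as.matrix(points)
  d <- ncol(P)
  stopifnot(d %in% c(2, 3), nrow(P) >= d + 1)
  res <- bowyer_watson(P)
  jittered <- FALSE
  Pj <- P
  if (is.null(res)) {
    set.seed(jitter_seed)
    for (try in 1:5) {
      Pj <- P + matrix(stats::rnorm(length(P), 0, 1e-6), nrow(P), d)
      res <- bowyer_watson(Pj)
      jittered <- TRUE
      if (!is.null(res)) break
    }
    if (is.null(res)) stop("triangulation failed even after jitter")
  }
  list(simplices = res, jittered = jittered, points = Pj)
}

bowyer_watson <- function(P) {
  d <- ncol(P); n <- nrow(P)
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  ctr <- (lo + hi) / 2
  span <- max(hi - lo, 1)
  # super-simplex far outside the data so its vertices never sit inside the
  # circumspheres of boundary simplices
  S <- matrix(ctr, d + 1, d, byrow = TRUE)
  for (k in seq_len(d)) S[k, k] <- S[k, k] + 4e3 * span
  S[d + 1, ] <- S[d + 1, ] - 4e3 * span / d
  V <- rbind(S, P)                 # super vertices are 1..(d+1)
  simp <- matrix(seq_len(d + 1), 1)
  cache <- list(circumsphere(V[simp[1, ], , drop = FALSE]))
  tol <- 1e-9
  for (ip in seq_len(n)) {
    p <- V[d + 1 + ip, ]
    bad <- logical(nrow(simp))
    for (s in seq_len(nrow(simp))) {
      cs <- cache[[s]]
      rel <- (sum((p - cs$center)^2) - cs$r2) / cs$r2
      bad[s] <- rel < -tol
      if (!bad[s] && rel < tol &&
          all(simp[s, ] > d + 1))  # cospherical with a real simplex: jitter
        return(NULL)
    }
    if (!any(bad)) return(NULL)    # numerical trouble; jitter and retry
    # boundary facets = facets of bad simplices appearing exactly once
    facets <- list()
    for (s in which(bad)) {
      vs <- simp[s, ]
      for (drop in seq_len(d + 1)) {
        facets[[length(facets) + 1]] <- sort(vs[-drop])
      }
    }
    keys <- vapply(facets, paste, "", collapse = ",")
    once <- names(which(table(keys) == 1))
    boundary <- facets[match(once, keys)]
    simp <- simp[!bad, , drop = FALSE]
    cache <- cache[!bad]
    for (f in boundary) {
      new_s <- c(f, d + 1 + ip)
      cs <- circumsphere(V[new_s, , drop = FALSE])
      if (is.null(cs)) return(NULL)
      simp <- rbind(simp, new_s)
      cache[[length(cache) + 1]] <- cs
    }
  }
  keep <- apply(simp, 1, function(vs) all(vs > d + 1))
  out <- simp[keep, , drop = FALSE] - (d + 1)
  rownames(out) <- NULL
  if (!nrow(out)) return(NULL)
  out
}

# Block reduction of a 2D image: per-block center of mass and channel sums.
block_centroids_2d <- function(images, block) {
  ny <- nrow(images[[1]]); nx <- ncol(images[[1]])
  nby <- ny %/% block; nbx <- nx %/% block
  rows <- list()
  dropped <- 0L
  for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
    ri <- ((by - 1) * block + 1):(by * block)
    ci <- ((bx - 1) * block + 1):(bx * block)
    tot <- Reduce(`+`, lapply(images, function(im) im[ri, ci]))
    s <- sum(tot)
    if (s == 0) { dropped <- dropped + 1L; next }
    wy <- sum(rowSums(tot) * ri) / s
    wx <- sum(colSums(tot) * ci) / s
    rows[[length(rows) + 1]] <- c(
      x = wx, y = wy, total = s,
      stats::setNames(vapply(images, function(im) sum(im[ri, ci]), 0),
                      paste0("ch", seq_along(images))))
  }
  list(table = do.call(rbind, rows), dropped = dropped,
       n_blocks = nby * nbx)
}

#' Delaunay neighborhood analysis of blocked image signal
#'
#' Divides a 2D image (or each channel of one slice) into `block x block`
#' pixel blocks — or an [ion_stack()] volume into `block^3` voxel blocks —
#' keeps each non-empty block's intensity-weighted center of mass and
#' per-channel signal sums, and triangulates the centroids. Per-simplex mean
#' signals are returned as the neighborhood heatmap table. Over complete
#' blocks the per-block channel sums conserve the image total exactly.
#'
#' @param x A 2D matrix, a list of same-shape matrices (channels), or an
#'   [ion_stack()].
#' @param block Block edge length in pixels (2, 4 or 8 typically).
#' @param z Slice selection: for an `ion_stack`, `z = NULL` (default) blocks
#'   the full volume in 3D; an integer analyzes that single slice in 2D.
#' @return A list of class `neighborhood_graph`: `centroids` (data frame with
#'   positions, total and per-channel signal), `simplices`, `simplex_signal`
#'   (per-simplex mean total signal), `n_dropped`, `jittered`.
#' @export
delaunay_neighborhoods <- function(x, block = 2, z = NULL) {
  stopifnot(block >= 1)
  if (inherits(x, "ion_stack") && is.null(z)) {
    # 3D: block the (z, y, x) volume; channels summed for mass
    d <- dim(x$counts)
    nbz <- d[1] %/% block; nby <- d[3] %/% block; nbx <- d[4] %/% block
    rows <- list(); dropped <- 0L
    for (bz in seq_len(nbz)) for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
      zi <- ((bz - 1) * block + 1):(bz * block)
      ri <- ((by - 1) * block + 1):(by * block)
      ci <- ((bx - 1) * block + 1):(bx * block)
      sub <- x$counts[zi, , ri, ci, drop = FALSE]
      tot <- apply(sub, c(1, 3, 4), sum)      # (z, y, x) within block
      s <- sum(tot)
      if (s == 0) { dropped <- dropped + 1L; next }
      wz <- sum(apply(tot, 1, sum) * zi) / s
      wy <- sum(apply(tot, 2, sum) * ri) / s
      wx <- sum(apply(tot, 3, sum) * ci) / s
      ch_sums <- vapply(seq_len(d[2]), function(ch) sum(sub[, ch, , ]), 0)
      rows[[length(rows) + 1]] <- c(x = wx, y = wy, z = wz, total = s,
                                    stats::setNames(ch_sums,
                                                    x$channel_labels))
    }
    tab <- do.call(rbind, rows)
    if (is.null(tab) || nrow(tab) < 4)
      stop("need at least 4 non-empty blocks for 3D neighborhoods")
    tri <- delaunay(tab[, c("x", "y", "z"), drop = FALSE])
    n_blocks <- nbz * nby * nbx
  } else {
    images <- if (inherits(x, "ion_stack")) {
      lapply(seq_len(n_channels(x)), function(ch) get_slice(x, z %||% 1, ch))
    } else if (is.list(x)) x else list(x)
    bc <- block_centroids_2d(images, block)
    tab <- bc$table
    if (is.null(tab) || nrow(tab) < 3)
      stop("need at least 3 non-empty blocks for 2D neighborhoods")
    dropped <- bc$dropped
    n_blocks <- bc$n_blocks
    tri <- delaunay(tab[, c("x", "y"), drop = FALSE])
  }
  simplex_signal <- apply(tri$simplices, 1,
                          function(vs) mean(tab[vs, "total"]))
  structure(list(centroids = as.data.frame(tab), simplices = tri$simplices,
                 simplex_signal = simplex_signal, n_dropped = dropped,
                 n_blocks = n_blocks, jittered = tri$jittered),
            class = "neighborhood_graph")
}
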
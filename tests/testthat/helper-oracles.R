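# Independent brute-force oracles. These deliberately avoid the package's
# algorithms (sorting prefix / BFS labeling / boundary-pixel scan) so that
# equivalence tests are a genuine dual route.

# Exhaustive threshold scan: try every distinct intensity as a threshold,
# keep those capturing >= fraction of the ROI total, pick the one with
# minimal coverage (i.e. the largest such threshold).
oracle_fraction_mask <- function(pixels, analyzed, fraction) {
  vals <- pixels[analyzed]
  total <- sum(vals)
  best_t <- NA_real_
  best_cov <- Inf
  for (t in unique(vals)) {
    s <- sum(vals[vals >= t])
    if (s >= fraction * total) {
      cov <- sum(vals >= t)
      if (cov < best_cov) { best_cov <- cov; best_t <- t }
    }
  }
  analyzed & (pixels >= best_t)
}

# Flood-fill component labeling with an explicit queue.
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (jj in seq_len(nc)) for (ii in seq_len(nr)) {
    if (!mask[ii, jj] || lab[ii, jj] > 0) next
    cur <- cur + 1L
    queue <- matrix(c(ii, jj), 1, 2)
    lab[ii, jj] <- cur
    while (nrow(queue) > 0) {
      px <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (d in seq_len(nrow(nb))) {
        ni <- px[1] + nb[d, 1]; nj <- px[2] + nb[d, 2]
        if (ni < 1 || nj < 1 || ni > nr || nj > nc) next
        if (mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  lab
}

# All-pairs minimum distance by exhaustive pixel-pair scan (no boundary
# shortcut), in pixel units.
oracle_pair_dists <- function(lab) {
  k <- max(lab)
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  D <- matrix(Inf, k, k)
  diag(D) <- 0
  for (a in seq_len(k - 1)) {
    pa <- idx[l == a, , drop = FALSE]
    for (b in (a + 1):k) {
      pb <- idx[l == b, , drop = FALSE]
      dd <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
      D[a, b] <- D[b, a] <- sqrt(min(dd))
    }
  }
  D
}

# CRU partition by union-find over the full pairwise matrix.
oracle_cru_partition <- function(D, ids, threshold) {
  k <- length(ids)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (k > 1) for (a in seq_len(k - 1)) for (b in (a + 1):k)
    if (D[ids[a], ids[b]] < threshold) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  roots <- vapply(seq_len(k), find, 0L)
  split(ids, roots)
}

# Canonical form of a labeling: list of sorted pixel-index sets, sorted.
canonical_partition <- function(lab) {
  sets <- split(which(lab > 0), lab[lab > 0])
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, min, 0))])
}

# Random blob-like test image on an nr x nc grid: a few dozen seeded
# points dilated by distance, plus noise; intensities are integers.
random_blob_image <- function(seed, nr = 64, nc = 64, n_seeds = 25,
                              radius = 3, pixel_size_nm = 5) {
  set.seed(seed)
  img <- matrix(0, nr, nc)
  si <- sample.int(nr, n_seeds, replace = TRUE)
  sj <- sample.int(nc, n_seeds, replace = TRUE)
  amp <- sample(50:500, n_seeds, replace = TRUE)
  for (s in seq_len(n_seeds)) {
    i0 <- max(1, si[s] - radius):min(nr, si[s] + radius)
    j0 <- max(1, sj[s] - radius):min(nc, sj[s] + radius)
    d2 <- outer((i0 - si[s])^2, (j0 - sj[s])^2, "+")
    img[i0, j0] <- img[i0, j0] + amp[s] * exp(-d2 / (radius^2))
  }
  round(img + matrix(runif(nr * nc, 0, 5), nr, nc))
}

# Build a rendered_image + full-frame roi pair around a pixel matrix.
toy_image <- function(pixels, pixel_size_nm = 5) {
  rendered_image(pixels, pixel_size_nm = pixel_size_nm)
}

toy_roi <- function(shape, exclude = NULL) {
  roi_mask(matrix(TRUE, shape[1], shape[2]), exclude)
}

# Cluster set straight from a binary mask (full-frame ROI, no filtering).
toy_cluster_set <- function(mask, pixel_size_nm = 5, connectivity = 8,
                            analyzed_area_nm2 = length(mask) * pixel_size_nm^2) {
  cfg <- analysis_config(pixel_size_nm = pixel_size_nm,
                         connectivity = connectivity)
  label_clusters(mask, cfg, analyzed_area_nm2 = analyzed_area_nm2)
}

# Rectangular block helper for crafting masks.
add_block <- function(mask, rows, cols) {
  mask[rows, cols] <- TRUE
  mask
}
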
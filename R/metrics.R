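#' Convert cluster area to an estimated channel count
#'
#' Under the isotropic-packing assumption each channel occupies a fixed
#' membrane footprint, so the estimated channel count is simply
#' `area_nm2 / channel_footprint_nm2`, reported unrounded (13 420 nm^2
#' gives 14.9 channels at the default 900 nm^2 footprint).
#'
#' @param area_nm2 positive cluster area(s) in nm^2.
#' @param channel_footprint_nm2 single-channel footprint in nm^2.
#' @return Numeric channel estimate(s).
#' @export
channels_per_cluster <- function(area_nm2, channel_footprint_nm2 = 900) {
  nc_check(is.numeric(area_nm2) && all(is.finite(area_nm2)) && all(area_nm2 > 0),
           "area_nm2 must be positive and finite")
  nc_check(channel_footprint_nm2 > 0, "channel_footprint_nm2 must be positive")
  area_nm2 / channel_footprint_nm2
}

#' Pairwise minimum edge-to-edge distances between clusters
#'
#' Minimum Euclidean distance between any pixel of one cluster and any
#' pixel of another, computed on pixel centres and scaled to nm. Distances
#' between touching-but-distinct clusters (possible under 4-connectivity)
#' equal one pixel edge.
#'
#' @param cs a `cluster_set`.
#' @return Symmetric k x k matrix in nm, zero diagonal.
#' @export
cluster_pair_distances <- function(cs) {
  nc_check(inherits(cs, "cluster_set"), "cs must be a cluster_set")
  k <- nrow(cs$clusters)
  min_pair_dist_cpp(cs$labels, k) * cs$pixel_size_nm
}

#' Edge-to-edge nearest-neighbour distance per cluster
#'
#' For each cluster the minimum edge-to-edge distance to any other
#' cluster. With fewer than two clusters the NND is undefined and
#' reported as `NA` (missing, not zero).
#'
#' @param cs a `cluster_set`.
#' @param D optional precomputed [cluster_pair_distances()] matrix.
#' @return Numeric vector (nm), one value per cluster.
#' @export
edge_to_edge_nnd <- function(cs, D = NULL) {
  nc_check(inherits(cs, "cluster_set"), "cs must be a cluster_set")
  k <- nrow(cs$clusters)
  if (k < 2) return(rep(NA_real_, k))
  if (is.null(D)) D <- cluster_pair_distances(cs)
  diag(D) <- Inf
  apply(D, 1, min)
}

#' Per-cell summary of cluster metrics
#'
#' Aggregates over retained clusters: count, mean area, mean channels,
#' cluster density over the analyzed (nucleus-excluded) area, mean NND,
#' and the fraction of clusters with at most `k_channels` channels
#' (cumulative-histogram support). An empty cluster set yields a marker
#' row with `n_clusters = 0` and missing aggregates.
#'
#' @param cs a `cluster_set`.
#' @param k_channels cut point for the small-cluster fraction.
#' @param D optional precomputed pair-distance matrix.
#' @return One-row `data.table`.
#' @export
cell_summary <- function(cs, k_channels = 6, D = NULL) {
  nc_check(inherits(cs, "cluster_set"), "cs must be a cluster_set")
  tab <- cs$clusters
  n <- nrow(tab)
  area_um2 <- cs$analyzed_area_nm2 / 1e6
  if (n == 0) {
    return(data.table::data.table(
      n_clusters = 0L, mean_area_nm2 = NA_real_, mean_channels = NA_real_,
      density_per_um2 = if (is.na(area_um2)) NA_real_ else 0,
      mean_nnd_nm = NA_real_, frac_channels_le_k = NA_real_))
  }
  nnd <- edge_to_edge_nnd(cs, D)
  data.table::data.table(
    n_clusters = n,
    mean_area_nm2 = mean(tab$area_nm2),
    mean_channels = mean(tab$channels),
    density_per_um2 = n / area_um2,
    mean_nnd_nm = if (n >= 2) mean(nnd) else NA_real_,
    frac_channels_le_k = mean(tab$channels <= k_channels))
}
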
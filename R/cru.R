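#' Group clusters into Ca2+ release units (CRUs)
#'
#' Single-linkage grouping: eligible clusters are nodes, and an edge
#' joins two clusters whose edge-to-edge distance is strictly below
#' `threshold_nm` (exactly the threshold is NOT grouped). CRUs are the
#' connected components, so linkage is transitive: A-B < t and B-C < t
#' put A and C in one CRU regardless of their direct distance. By default
#' only clusters with an estimated two or more channels are eligible;
#' single-channel clusters can optionally join as linkers.
#'
#' @param cs a `cluster_set`.
#' @param threshold_nm grouping distance in nm (strict `<`).
#' @param min_channels eligibility floor on the estimated channel count.
#' @param include_small_joiners if `TRUE`, clusters below the floor still
#'   participate in linkage (they can bridge CRUs) but are not counted as
#'   members.
#' @param D optional precomputed [cluster_pair_distances()] matrix.
#' @return A `cru_set`: per-CRU table (`cru_id`, `n_clusters`,
#'   `total_channels`, `is_isolated`), a membership table, and the count
#'   of eligible clusters.
#' @export
group_crus <- function(cs, threshold_nm = cs$config$cru_threshold_nm,
                       min_channels = cs$config$cru_min_channels,
                       include_small_joiners = FALSE, D = NULL) {
  nc_check(inherits(cs, "cluster_set"), "cs must be a cluster_set")
  nc_check(threshold_nm > 0, "threshold_nm must be positive")
  tab <- cs$clusters
  eligible <- tab$channels >= min_channels
  node <- if (include_small_joiners) rep(TRUE, nrow(tab)) else eligible
  ids <- tab$cluster_id[node]
  k <- length(ids)
  empty <- data.table::data.table(cru_id = integer(), n_clusters = integer(),
                                  total_channels = numeric(), is_isolated = logical())
  if (sum(eligible) == 0) {
    return(structure(list(crus = empty,
                          membership = data.table::data.table(
                            cluster_id = integer(), cru_id = integer()),
                          threshold_nm = threshold_nm,
                          n_eligible = 0L),
                     class = "cru_set"))
  }
  if (is.null(D)) D <- cluster_pair_distances(cs)
  # union-find over linkage graph
  parent <- seq_len(k)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  if (k > 1) {
    Dn <- D[ids, ids, drop = FALSE]
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (Dn[a, b] < threshold_nm) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  root <- vapply(seq_len(k), find, 0L)
  comp <- match(root, unique(root))
  memb <- data.table::data.table(cluster_id = ids, cru_id = comp,
                                 channels = tab$channels[node],
                                 eligible = eligible[node])
  # CRUs are defined by their eligible members; components containing
  # only small joiners are dropped
  crus <- memb[memb$eligible,
               list(n_clusters = .N, total_channels = sum(channels)),
               by = "cru_id"]
  crus <- crus[order(cru_id)]
  crus$cru_id <- seq_len(nrow(crus))
  crus$is_isolated <- crus$n_clusters == 1L
  structure(list(crus = crus,
                 membership = memb[memb$eligible, c("cluster_id", "cru_id"), with = FALSE],
                 threshold_nm = threshold_nm,
                 n_eligible = sum(eligible)),
            class = "cru_set")
}

#' @export
print.cru_set <- function(x, ...) {
  cat(sprintf("cru_set: %d CRUs over %d eligible clusters (threshold %.4g nm)\n",
              nrow(x$crus), x$n_eligible, x$threshold_nm))
  invisible(x)
}

#' Per-cell CRU composition summary
#'
#' Reports the CRU count, mean clusters per CRU in two variants (over all
#' CRUs, and over multi-cluster CRUs only - both are always emitted
#' because published means are ambiguous between the two accountings),
#' mean channels per CRU, and the fraction of eligible clusters that are
#' isolated (singleton CRUs over eligible clusters).
#'
#' @param crus a `cru_set` from [group_crus()].
#' @return One-row `data.table`.
#' @export
cru_summary <- function(crus) {
  nc_check(inherits(crus, "cru_set"), "crus must be a cru_set")
  tab <- crus$crus
  if (nrow(tab) == 0) {
    return(data.table::data.table(
      n_crus = 0L, mean_clusters_per_cru_all = NA_real_,
      mean_clusters_per_cru_multi = NA_real_,
      mean_channels_per_cru = NA_real_, frac_isolated = NA_real_))
  }
  multi <- tab$n_clusters[tab$n_clusters > 1]
  data.table::data.table(
    n_crus = nrow(tab),
    mean_clusters_per_cru_all = mean(tab$n_clusters),
    mean_clusters_per_cru_multi = if (length(multi)) mean(multi) else NA_real_,
    mean_channels_per_cru = mean(tab$total_channels),
    frac_isolated = sum(tab$is_isolated) / crus$n_eligible)
}
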
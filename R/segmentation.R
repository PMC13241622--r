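#' Analysis configuration
#'
#' The handful of constants that drive segmentation and grouping. The
#' defaults are the standard values for this analysis: a binary mask
#' capturing 75% of the total labelling intensity, a single-channel area
#' floor of 900 nm^2, 8-connected components, and a 150 nm edge-to-edge
#' threshold for grouping clusters into Ca2+ release units.
#'
#' @param mask_fraction fraction of total ROI intensity the binary mask
#'   must contain, in (0, 1].
#' @param min_cluster_area_nm2 clusters strictly smaller than this are
#'   discarded (exactly this area is retained).
#' @param connectivity pixel adjacency for component labeling, 4 or 8.
#' @param cru_threshold_nm edge-to-edge distance below which clusters are
#'   grouped (strictly less than).
#' @param pixel_size_nm rendered pixel edge in nm.
#' @param cru_min_channels minimum (estimated) channels for a cluster to
#'   enter CRU analysis.
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(mask_fraction = 0.75,
                            min_cluster_area_nm2 = 900,
                            connectivity = 8,
                            cru_threshold_nm = 150,
                            pixel_size_nm = 5,
                            cru_min_channels = 2) {
  cfg <- list(mask_fraction = mask_fraction,
              min_cluster_area_nm2 = min_cluster_area_nm2,
              connectivity = as.integer(connectivity),
              cru_threshold_nm = cru_threshold_nm,
              pixel_size_nm = pixel_size_nm,
              cru_min_channels = cru_min_channels)
  nc_check(is.numeric(mask_fraction) && length(mask_fraction) == 1 &&
             mask_fraction > 0 && mask_fraction <= 1,
           "mask_fraction must lie in (0, 1]")
  nc_check(min_cluster_area_nm2 > 0, "min_cluster_area_nm2 must be positive")
  nc_check(cfg$connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  nc_check(cru_threshold_nm > 0, "cru_threshold_nm must be positive")
  nc_check(pixel_size_nm > 0, "pixel_size_nm must be positive")
  nc_check(cru_min_channels >= 0, "cru_min_channels must be >= 0")
  structure(cfg, class = "analysis_config")
}

#' Intensity-fraction binary mask
#'
#' Produces the smallest intensity-threshold mask containing at least
#' `fraction` of the total labelling intensity inside the analyzed ROI.
#' Algorithm: sort analyzed-pixel intensities descending, take the
#' shortest prefix whose cumulative sum reaches `fraction * total`, set
#' the threshold `t*` to the last included intensity, and include every
#' analyzed pixel with intensity >= `t*` (so ties at the threshold are
#' all kept, making the rule order-independent).
#'
#' @param image a [rendered_image()].
#' @param roi a [roi_mask()]; the mask is a subset of `include & !exclude`.
#' @param fraction target intensity fraction in (0, 1].
#' @return Logical matrix of the image shape.
#' @export
intensity_fraction_mask <- function(image, roi, fraction = 0.75) {
  nc_check(inherits(image, "rendered_image"), "image must be a rendered_image")
  nc_check(inherits(roi, "roi_mask"), "roi must be a roi_mask")
  nc_check(all(dim(roi$include) == dim(image$pixels)),
           "ROI shape does not match image shape")
  nc_check(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  vals <- image$pixels[roi$analyzed]
  total <- sum(vals)
  if (total <= 0)
    nc_stop("analyzed ROI contains no intensity", "nc_empty_signal_error")
  srt <- sort(vals, decreasing = TRUE)
  cs <- cumsum(srt)
  # tolerance guards exact-fraction cases against float summation error
  m <- which(cs >= fraction * total * (1 - 1e-12))[1]
  tstar <- srt[m]
  roi$analyzed & (image$pixels >= tstar)
}

#' Label connected clusters in a binary mask
#'
#' Connected-component labeling under the configured connectivity; every
#' mask pixel belongs to exactly one cluster. Areas, centroids (world nm)
#' and channel estimates are tabulated per cluster.
#'
#' @param mask logical matrix (typically from
#'   [intensity_fraction_mask()]).
#' @param config an [analysis_config()].
#' @param analyzed_area_nm2 area of the analyzed ROI in nm^2 (used for
#'   density downstream); pass `roi_analyzed_area_nm2(roi, p)`.
#' @param origin_nm world coordinate of the frame corner.
#' @param channel_footprint_nm2 footprint for the channel estimate.
#' @return A `cluster_set`: per-cluster table, label matrix, scale and
#'   provenance.
#' @export
label_clusters <- function(mask, config = analysis_config(),
                           analyzed_area_nm2 = NA_real_,
                           origin_nm = c(0, 0),
                           channel_footprint_nm2 = 900) {
  nc_check(is.matrix(mask), "mask must be a matrix")
  labels <- cc_label_cpp(mask > 0, config$connectivity)
  k <- attr(labels, "n_labels")
  p <- config$pixel_size_nm
  if (k == 0) {
    tab <- data.table::data.table(cluster_id = integer(), n_pixels = integer(),
                                  area_nm2 = numeric(), channels = numeric(),
                                  centroid_x_nm = numeric(), centroid_y_nm = numeric())
  } else {
    idx <- which(labels > 0)
    nr <- nrow(labels)
    i <- ((idx - 1L) %% nr) + 1L
    j <- ((idx - 1L) %/% nr) + 1L
    dt <- data.table::data.table(l = labels[idx], i = i, j = j)
    tab <- dt[, list(n_pixels = .N,
                     centroid_x_nm = origin_nm[1] + (mean(j) - 0.5) * p,
                     centroid_y_nm = origin_nm[2] + (mean(i) - 0.5) * p),
              by = "l"][order(l)]
    data.table::setnames(tab, "l", "cluster_id")
    tab$area_nm2 <- tab$n_pixels * p^2
    tab$channels <- tab$area_nm2 / channel_footprint_nm2
    data.table::setcolorder(tab, c("cluster_id", "n_pixels", "area_nm2",
                                   "channels", "centroid_x_nm", "centroid_y_nm"))
  }
  structure(list(clusters = tab, labels = labels,
                 pixel_size_nm = p,
                 analyzed_area_nm2 = analyzed_area_nm2,
                 channel_footprint_nm2 = channel_footprint_nm2,
                 config = config),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, analyzed area %.3g um^2, %.3g nm/px\n",
              nrow(x$clusters), x$analyzed_area_nm2 / 1e6, x$pixel_size_nm))
  invisible(x)
}

#' Drop clusters below the single-channel area floor
#'
#' Retains clusters with `area_nm2 >= min_cluster_area_nm2` (the floor
#' itself is retained; only strictly smaller particles are excluded).
#' Surviving clusters are relabeled contiguously; the number removed is
#' recorded in the `n_removed` attribute and reported via a message.
#'
#' @param cs a `cluster_set`.
#' @param min_cluster_area_nm2 area floor in nm^2.
#' @param quiet suppress the removal message.
#' @return The filtered `cluster_set`.
#' @export
filter_min_area <- function(cs, min_cluster_area_nm2 = cs$config$min_cluster_area_nm2,
                            quiet = TRUE) {
  nc_check(inherits(cs, "cluster_set"), "cs must be a cluster_set")
  keep <- cs$clusters$area_nm2 >= min_cluster_area_nm2
  n_removed <- sum(!keep)
  if (!quiet && n_removed > 0)
    message(sprintf("filter_min_area: removed %d cluster(s) below %.4g nm^2",
                    n_removed, min_cluster_area_nm2))
  remap <- integer(nrow(cs$clusters) + 1L) # index 1 holds label 0 -> 0
  remap[which(keep) + 1L] <- seq_len(sum(keep))
  labels <- matrix(remap[cs$labels + 1L], nrow(cs$labels), ncol(cs$labels))
  tab <- cs$clusters[keep]
  tab$cluster_id <- seq_len(nrow(tab))
  out <- cs
  out$clusters <- tab
  out$labels <- labels
  attr(out, "n_removed") <- n_removed
  out
}

#' Segment a rendered image into clusters
#'
#' Composition of [intensity_fraction_mask()], [label_clusters()] and
#' [filter_min_area()], the full segmentation stage for one cell.
#'
#' @param image a [rendered_image()].
#' @param roi a [roi_mask()].
#' @param config an [analysis_config()].
#' @return A filtered `cluster_set`.
#' @export
segment_image <- function(image, roi, config = analysis_config()) {
  nc_check(isTRUE(all.equal(config$pixel_size_nm, image$pixel_size_nm)),
           "config pixel_size_nm does not match the image")
  mask <- intensity_fraction_mask(image, roi, config$mask_fraction)
  cs <- label_clusters(mask, config,
                       analyzed_area_nm2 = roi_analyzed_area_nm2(roi, image$pixel_size_nm),
                       origin_nm = image$origin_nm)
  filter_min_area(cs)
}
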
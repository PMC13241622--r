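#' Scene configuration for the synthetic SMLM generator
#'
#' Describes a ground-truth scene of clustered membrane channels inside a
#' soma-like disc ROI with a nuclear disc excluded. Channel counts per
#' cluster follow a geometric law truncated at 1 (discrete,
#' near-exponential); channels are packed isotropically so that the true
#' cluster area is `channels * channel_footprint_nm2`.
#'
#' Defaults describe the control condition of the system this package
#' models: mean cluster size 14.91 channels (13 420 nm^2 at the 900
#' nm^2/channel footprint) and a cluster density calibrated once so that
#' the measured inter-cluster edge-to-edge nearest-neighbour distance
#' averages ~119 nm after rendering and segmentation (see the methods
#' vignette for the calibration).
#'
#' @param frame_size_nm width and height of the field in nm.
#' @param cluster_density_um2 expected clusters per square micron of
#'   analyzed area; realized counts are Poisson.
#' @param n_clusters optional fixed cluster count overriding the density.
#' @param mean_channels mean of the geometric channels-per-cluster law
#'   (must be >= 1).
#' @param channel_footprint_nm2 membrane footprint of one channel.
#' @param min_edge_gap_nm hard minimum edge-to-edge gap between placed
#'   clusters (rejection sampling on bounding circles, so the realized
#'   gap is at least this).
#' @param soma_radius_nm,nucleus_radius_nm radii of the concentric
#'   include/exclude discs, centred in the frame.
#' @param group_effect multiplicative factor applied to `mean_channels`
#'   for the disease group in two-group designs.
#' @param seed default RNG seed used when none is passed to the
#'   simulation functions.
#' @return A validated `scene_config` list.
#' @export
scene_config <- function(frame_size_nm = c(3200, 3200),
                         cluster_density_um2 = 10,
                         n_clusters = NULL,
                         mean_channels = 14.91,
                         channel_footprint_nm2 = 900,
                         min_edge_gap_nm = 20,
                         soma_radius_nm = 1450,
                         nucleus_radius_nm = 550,
                         group_effect = 0.79,
                         seed = 1L) {
  cfg <- list(frame_size_nm = as.numeric(frame_size_nm),
              cluster_density_um2 = cluster_density_um2,
              n_clusters = n_clusters,
              mean_channels = mean_channels,
              channel_footprint_nm2 = channel_footprint_nm2,
              min_edge_gap_nm = min_edge_gap_nm,
              soma_radius_nm = soma_radius_nm,
              nucleus_radius_nm = nucleus_radius_nm,
              group_effect = group_effect,
              seed = seed)
  nc_check(length(cfg$frame_size_nm) == 2 && all(cfg$frame_size_nm > 0),
           "frame_size_nm must be two positive numbers")
  nc_check(cfg$cluster_density_um2 >= 0, "cluster_density_um2 must be >= 0")
  nc_check(is.null(n_clusters) || (n_clusters >= 0 && n_clusters == round(n_clusters)),
           "n_clusters must be a non-negative integer")
  nc_check(cfg$mean_channels >= 1, "mean_channels must be >= 1")
  nc_check(cfg$channel_footprint_nm2 > 0, "channel_footprint_nm2 must be positive")
  nc_check(cfg$min_edge_gap_nm >= 0, "min_edge_gap_nm must be >= 0")
  nc_check(cfg$soma_radius_nm > 0 &&
             cfg$soma_radius_nm <= min(cfg$frame_size_nm) / 2,
           "soma_radius_nm must be positive and fit inside the frame")
  nc_check(cfg$nucleus_radius_nm >= 0 &&
             cfg$nucleus_radius_nm < cfg$soma_radius_nm,
           "nucleus_radius_nm must be non-negative and smaller than the soma radius")
  nc_check(cfg$group_effect > 0 && cfg$group_effect <= 2,
           "group_effect must lie in (0, 2]")
  structure(cfg, class = "scene_config")
}

#' Emission configuration for the blinking-fluorophore model
#'
#' Standard SMLM generative hierarchy: each channel is labeled with some
#' probability, each labeled channel produces >= 1 blink events
#' (1 + Poisson), and every blink is localized with isotropic Gaussian
#' precision error. Spurious background localizations are uniform over
#' the frame.
#'
#' @param labeling_efficiency probability a channel carries a working
#'   label.
#' @param mean_blinks mean blinks per labeled channel (>= 1).
#' @param localization_precision_nm Gaussian sigma of the per-axis
#'   localization error; 15 nm is a typical dSTORM figure.
#' @param background_rate_um2 spurious localizations per square micron.
#' @return A validated `emission_config` list.
#' @export
emission_config <- function(labeling_efficiency = 0.9,
                            mean_blinks = 20,
                            localization_precision_nm = 15,
                            background_rate_um2 = 5) {
  cfg <- list(labeling_efficiency = labeling_efficiency,
              mean_blinks = mean_blinks,
              localization_precision_nm = localization_precision_nm,
              background_rate_um2 = background_rate_um2)
  nc_check(labeling_efficiency >= 0 && labeling_efficiency <= 1,
           "labeling_efficiency must lie in [0, 1]")
  nc_check(mean_blinks >= 1, "mean_blinks must be >= 1")
  nc_check(localization_precision_nm >= 0,
           "localization_precision_nm must be >= 0")
  nc_check(background_rate_um2 >= 0, "background_rate_um2 must be >= 0")
  structure(cfg, class = "emission_config")
}

# First k sites of a jittered hexagonal lattice, densest-first, centred
# at the origin and randomly rotated. The lattice cell area equals the
# channel footprint, so k channels tile ~k * footprint of membrane.
.hex_sites <- function(k, footprint_nm2) {
  if (k == 1) return(matrix(0, 1, 2))
  a <- sqrt(footprint_nm2 * 2 / sqrt(3))
  rings <- 1L
  while (1 + 3 * rings * (rings + 1) < k) rings <- rings + 1L
  idx <- expand.grid(i = -rings:rings, j = -rings:rings)
  idx <- idx[abs(idx$i + idx$j) <= rings, ]
  x <- a * (idx$i + idx$j / 2)
  y <- a * idx$j * sqrt(3) / 2
  ord <- order(x^2 + y^2)
  pts <- cbind(x[ord], y[ord])[seq_len(k), , drop = FALSE]
  theta <- runif(1, 0, 2 * pi)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  jit <- matrix(runif(2 * k, -2, 2), k, 2)
  pts %*% rot + jit
}

#' Simulate a ground-truth scene of clustered channels
#'
#' Clusters are placed sequentially at uniform positions inside the soma
#' disc (and outside the nucleus disc), rejecting candidates whose
#' bounding circles come closer than `min_edge_gap_nm` to an already
#' placed cluster. Channel counts are drawn from the geometric law.
#'
#' @param config a [scene_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param max_tries placement attempts per cluster before giving up.
#' @return A `ground_truth_scene`: per-cluster channel positions (nm),
#'   true channel counts and areas, plus the ROI disc geometry.
#' @export
simulate_scene <- function(config, seed = config$seed, max_tries = 5000L) {
  nc_check(inherits(config, "scene_config"), "config must be a scene_config")
  set.seed(seed)
  centre <- config$frame_size_nm / 2
  rs <- config$soma_radius_nm
  rn <- config$nucleus_radius_nm
  analyzed_um2 <- pi * (rs^2 - rn^2) / 1e6
  n <- if (!is.null(config$n_clusters)) as.integer(config$n_clusters) else
    rpois(1, config$cluster_density_um2 * analyzed_um2)
  clusters <- vector("list", n)
  if (n > 0) {
    p <- 1 / config$mean_channels
    k <- rgeom(n, p) + 1L # geometric truncated at 1
    # place large clusters first: greatly raises the packing density at
    # which sequential rejection sampling still succeeds
    k <- sort(k, decreasing = TRUE)
    placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
    for (c_i in seq_len(n)) {
      sites <- .hex_sites(k[c_i], config$channel_footprint_nm2)
      # bounding radius: farthest channel centre plus half a channel diagonal
      r <- sqrt(max(rowSums(sites^2))) +
        sqrt(config$channel_footprint_nm2 / 2)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        # uniform in the annulus where the whole cluster fits
        lo2 <- if (rn > 0) (rn + r)^2 else 0
        rad <- sqrt(runif(1, lo2, max((rs - r)^2, lo2 + 1)))
        ang <- runif(1, 0, 2 * pi)
        cx <- centre[1] + rad * cos(ang)
        cy <- centre[2] + rad * sin(ang)
        if (rad + r > rs) next
        if (length(placed_x) &&
            any(sqrt((placed_x - cx)^2 + (placed_y - cy)^2) <
                placed_r + r + config$min_edge_gap_nm)) next
        ok <- TRUE
        break
      }
      if (!ok)
        nc_stop(sprintf("could not place cluster %d of %d after %d tries; ROI too small for the requested density/gap",
                        c_i, n, max_tries), "nc_placement_error")
      placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
      placed_r <- c(placed_r, r)
      clusters[[c_i]] <- list(
        cluster_id = c_i,
        channels_xy = sweep(sites, 2, c(cx, cy), "+"),
        n_channels = k[c_i],
        true_area_nm2 = k[c_i] * config$channel_footprint_nm2,
        centre = c(cx, cy),
        radius = r)
    }
  }
  structure(list(clusters = clusters,
                 frame_size_nm = config$frame_size_nm,
                 soma_centre_nm = centre, soma_radius_nm = rs,
                 nucleus_centre_nm = centre, nucleus_radius_nm = rn,
                 analyzed_um2 = analyzed_um2,
                 config = config, seed = seed),
            class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  k <- vapply(x$clusters, `[[`, 0, "n_channels")
  cat(sprintf("ground_truth_scene: %d clusters, %s channels, mean %.2f channels/cluster, analyzed %.2f um^2\n",
              length(k), format(sum(k)), if (length(k)) mean(k) else NA,
              x$analyzed_um2))
  invisible(x)
}

#' Ground-truth per-cluster table of a scene
#'
#' @param scene a `ground_truth_scene`.
#' @return `data.table` with `cluster_id`, `n_channels`, `true_area_nm2`,
#'   centre coordinates.
#' @export
scene_truth <- function(scene) {
  if (!length(scene$clusters))
    return(data.table::data.table(cluster_id = integer(), n_channels = integer(),
                                  true_area_nm2 = numeric(),
                                  centre_x_nm = numeric(), centre_y_nm = numeric()))
  data.table::rbindlist(lapply(scene$clusters, function(cl)
    list(cluster_id = cl$cluster_id, n_channels = cl$n_channels,
         true_area_nm2 = cl$true_area_nm2,
         centre_x_nm = cl$centre[1], centre_y_nm = cl$centre[2])))
}

#' Rasterize the ROI discs of a scene to an include/exclude mask pair
#'
#' @param scene a `ground_truth_scene`.
#' @param pixel_size_nm pixel edge in nm.
#' @return A [roi_mask()] congruent with the rendered frame.
#' @export
scene_roi <- function(scene, pixel_size_nm = 5) {
  shape <- ceiling(rev(scene$frame_size_nm) / pixel_size_nm) # rows, cols
  cx <- (seq_len(shape[2]) - 0.5) * pixel_size_nm
  cy <- (seq_len(shape[1]) - 0.5) * pixel_size_nm
  dx2 <- outer(rep(1, shape[1]), (cx - scene$soma_centre_nm[1])^2)
  dy2 <- outer((cy - scene$soma_centre_nm[2])^2, rep(1, shape[2]))
  d2 <- dx2 + dy2
  include <- d2 <= scene$soma_radius_nm^2
  exclude <- if (scene$nucleus_radius_nm > 0)
    d2 <= scene$nucleus_radius_nm^2 else NULL
  roi_mask(include, exclude)
}

#' Simulate blinking localizations from a ground-truth scene
#'
#' @param scene a `ground_truth_scene`.
#' @param emission an [emission_config()].
#' @param seed RNG seed.
#' @return Localization `data.table` (`x_nm`, `y_nm`, `frame`, `weight`).
#' @export
simulate_localizations <- function(scene, emission = emission_config(),
                                   seed = 1L) {
  nc_check(inherits(emission, "emission_config"),
           "emission must be an emission_config")
  set.seed(seed)
  sigma <- emission$localization_precision_nm
  xs <- list(); n_out <- 0L
  for (cl in scene$clusters) {
    labeled <- runif(cl$n_channels) < emission$labeling_efficiency
    if (!any(labeled)) next
    pos <- cl$channels_xy[labeled, , drop = FALSE]
    blinks <- 1L + rpois(nrow(pos), emission$mean_blinks - 1)
    rep_idx <- rep(seq_len(nrow(pos)), blinks)
    nb <- length(rep_idx)
    n_out <- n_out + 1L
    xs[[n_out]] <- data.table::data.table(
      x_nm = pos[rep_idx, 1] + rnorm(nb, 0, sigma),
      y_nm = pos[rep_idx, 2] + rnorm(nb, 0, sigma))
  }
  frame_um2 <- prod(scene$frame_size_nm) / 1e6
  n_bg <- rpois(1, emission$background_rate_um2 * frame_um2)
  if (n_bg > 0) {
    n_out <- n_out + 1L
    xs[[n_out]] <- data.table::data.table(
      x_nm = runif(n_bg, 0, scene$frame_size_nm[1]),
      y_nm = runif(n_bg, 0, scene$frame_size_nm[2]))
  }
  locs <- if (n_out) data.table::rbindlist(xs[seq_len(n_out)]) else
    data.table::data.table(x_nm = numeric(), y_nm = numeric())
  locs$frame <- if (nrow(locs)) sample.int(10000L, nrow(locs), replace = TRUE) else integer()
  locs$weight <- rep(1, nrow(locs))
  locs[]
}

#' Render localizations to an intensity image
#'
#' Each event deposits its weight through a per-pixel-integrated Gaussian
#' kernel of standard deviation `sigma_render_nm` (0 degenerates to
#' nearest-pixel binning). Total deposited intensity is conserved up to
#' frame clipping and kernel truncation at 4 sigma.
#'
#' @param locs localization table with `x_nm`, `y_nm`, `weight`.
#' @param pixel_size_nm pixel edge in nm.
#' @param frame_size_nm frame extent `c(width, height)` in nm.
#' @param sigma_render_nm rendering kernel sigma in nm.
#' @param origin_nm world coordinate of the frame corner.
#' @return A [rendered_image()] (continuous intensities; quantization to
#'   16 bits happens on write).
#' @export
render <- function(locs, pixel_size_nm = 5, frame_size_nm,
                   sigma_render_nm = 12, origin_nm = c(0, 0)) {
  nc_check(pixel_size_nm > 0, "pixel_size_nm must be positive")
  shape <- ceiling(rev(frame_size_nm) / pixel_size_nm)
  w <- if ("weight" %in% names(locs)) locs$weight else rep(1, nrow(locs))
  img <- render_cpp(as.numeric(locs$x_nm), as.numeric(locs$y_nm),
                    as.numeric(w), shape[1], shape[2], pixel_size_nm,
                    origin_nm[1], origin_nm[2], sigma_render_nm)
  rendered_image(img, pixel_size_nm, origin_nm)
}

#' Simulate one complete synthetic cell
#'
#' Scene, localizations, rendered image and ROI mask in one call; the
#' three stage seeds are derived deterministically from `seed`.
#'
#' @param config a [scene_config()].
#' @param emission an [emission_config()].
#' @param pixel_size_nm rendering scale.
#' @param sigma_render_nm rendering kernel sigma.
#' @param seed integer seed.
#' @return List with `image`, `roi`, `locs`, `scene`.
#' @export
simulate_cell <- function(config, emission = emission_config(),
                          pixel_size_nm = 5, sigma_render_nm = 12, seed = 1L) {
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max, 2)
  scene <- simulate_scene(config, seed = stage_seeds[1])
  locs <- simulate_localizations(scene, emission, seed = stage_seeds[2])
  img <- render(locs, pixel_size_nm, scene$frame_size_nm, sigma_render_nm)
  roi <- scene_roi(scene, pixel_size_nm)
  list(image = img, roi = roi, locs = locs, scene = scene)
}

#' Simulate a nested two-group dataset (cells within animals)
#'
#' Generates `control` and `disease` groups with `n_animals_per_group`
#' animals each and `cells_per_animal` cells per animal. The disease
#' group's mean cluster size is multiplied by `config$group_effect`; a
#' lognormal animal-level random effect (SD `animal_sd` on the log scale)
#' perturbs each animal's mean cluster size. Spacing parameters are
#' shared between groups, so the disease condition changes cluster size
#' but not inter-cluster distances.
#'
#' @param config control-group [scene_config()].
#' @param emission an [emission_config()].
#' @param n_animals_per_group animals per group.
#' @param cells_per_animal cells per animal.
#' @param animal_sd SD of the animal random effect on log mean cluster
#'   size (0.08 ~ 8% between-animal CV by default).
#' @param pixel_size_nm,sigma_render_nm rendering parameters.
#' @param seed master seed; all per-cell seeds derive from it.
#' @param cell_fun function applied to each simulated cell
#'   `(image, roi, scene)`; its value is stored in the `data` field of
#'   the per-cell record. Defaults to keeping the full cell; pass an
#'   analysis function to stream large designs without holding every
#'   image in memory.
#' @return List of per-cell records: `animal_id`, `group`, `cell_id`,
#'   `true_mean_channels` (the animal-level law mean), ground-truth
#'   table, and `data` (the `cell_fun` result).
#' @export
make_two_group_dataset <- function(config = scene_config(),
                                   emission = emission_config(),
                                   n_animals_per_group = 5,
                                   cells_per_animal = 6,
                                   animal_sd = 0.08,
                                   pixel_size_nm = 5, sigma_render_nm = 12,
                                   seed = 1L,
                                   cell_fun = function(image, roi, scene)
                                     list(image = image, roi = roi, scene = scene)) {
  nc_check(n_animals_per_group >= 1 && cells_per_animal >= 1,
           "need at least one animal per group and one cell per animal")
  set.seed(seed)
  groups <- c("control", "disease")
  n_cells <- 2 * n_animals_per_group * cells_per_animal
  animal_fx <- exp(rnorm(2 * n_animals_per_group, 0, animal_sd))
  cell_seeds <- sample.int(.Machine$integer.max, n_cells)
  out <- vector("list", n_cells)
  idx <- 0L
  for (g in seq_along(groups)) {
    gfac <- if (groups[g] == "disease") config$group_effect else 1
    for (a in seq_len(n_animals_per_group)) {
      aid <- sprintf("%s_animal%02d", groups[g], a)
      afac <- animal_fx[(g - 1) * n_animals_per_group + a]
      mu <- max(1, config$mean_channels * gfac * afac)
      cfg_a <- config
      cfg_a$mean_channels <- mu
      for (ci in seq_len(cells_per_animal)) {
        idx <- idx + 1L
        cell <- simulate_cell(cfg_a, emission, pixel_size_nm,
                              sigma_render_nm, seed = cell_seeds[idx])
        out[[idx]] <- list(animal_id = aid, group = groups[g],
                           cell_id = sprintf("%s_cell%02d", aid, ci),
                           true_mean_channels = mu,
                           truth = scene_truth(cell$scene),
                           data = cell_fun(cell$image, cell$roi, cell$scene))
      }
    }
  }
  out
}
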
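#' Rendered SMLM image
#'
#' Container for a rendered localization-microscopy image: a 2-D
#' non-negative intensity grid plus the physical scale. World coordinates
#' are in nanometres, x growing rightwards (columns) and y downwards
#' (rows); pixel `(i, j)` (1-based) covers the half-open square
#' `[x0 + (j-1) p, x0 + j p) x [y0 + (i-1) p, y0 + i p)` where `p` is
#' `pixel_size_nm` and `(x0, y0)` is `origin_nm`.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixel_size_nm positive pixel edge length in nm (default 5, the
#'   usual rendering scale for dSTORM data).
#' @param origin_nm length-2 numeric, world offset of the corner of pixel
#'   (1, 1).
#' @return An object of class `rendered_image`.
#' @export
rendered_image <- function(pixels, pixel_size_nm = 5, origin_nm = c(0, 0)) {
  nc_check(is.matrix(pixels) && is.numeric(pixels), "pixels must be a numeric matrix")
  nc_check(all(is.finite(pixels)) && all(pixels >= 0),
           "pixel intensities must be finite and non-negative")
  nc_check(is.numeric(pixel_size_nm) && length(pixel_size_nm) == 1 &&
             pixel_size_nm > 0, "pixel_size_nm must be a positive scalar")
  nc_check(is.numeric(origin_nm) && length(origin_nm) == 2 &&
             all(is.finite(origin_nm)), "origin_nm must be two finite numbers")
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 origin_nm = as.numeric(origin_nm)),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("rendered_image: %d x %d px at %.3g nm/px (%.3g x %.3g um), total intensity %.4g\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              ncol(x$pixels) * x$pixel_size_nm / 1e3,
              nrow(x$pixels) * x$pixel_size_nm / 1e3, sum(x$pixels)))
  invisible(x)
}

#' @export
dim.rendered_image <- function(x) dim(x$pixels)

#' Read a rendered image from a greyscale TIFF
#'
#' Supports single-plane uncompressed 8/16-bit greyscale TIFFs. The pixel
#' size is a required parameter rather than being trusted from TIFF
#' resolution tags, which are unreliable across renderers.
#'
#' @param path TIFF file path.
#' @inheritParams rendered_image
#' @return A [rendered_image()].
#' @export
read_rendered_image <- function(path, pixel_size_nm = 5, origin_nm = c(0, 0)) {
  rendered_image(.read_tiff_gray(path), pixel_size_nm, origin_nm)
}

#' Write a rendered image to a 16-bit greyscale TIFF
#'
#' Intensities are rounded to integers; values outside the 16-bit range
#' raise a validation error.
#'
#' @param image a [rendered_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rendered_image <- function(image, path) {
  nc_check(inherits(image, "rendered_image"), "image must be a rendered_image")
  .write_tiff_gray(image$pixels, path, bits = 16L)
}

#' Read a localization table
#'
#' Expects delimited text with a header naming at least `x_nm` and `y_nm`
#' columns (optional `frame` and `weight`). Rows with non-finite
#' coordinates are dropped, with the number of drops reported via a
#' message and recorded in the `n_dropped` attribute.
#'
#' @param path CSV file path.
#' @return A `data.table` with columns `x_nm`, `y_nm`, `frame`, `weight`.
#' @export
read_localizations <- function(path) {
  tab <- data.table::fread(path)
  nc_check(all(c("x_nm", "y_nm") %in% names(tab)),
           "localization table must have x_nm and y_nm columns",
           "nc_schema_error")
  if (!"frame" %in% names(tab)) tab$frame <- 0L
  if (!"weight" %in% names(tab)) tab$weight <- 1
  tab <- tab[, c("x_nm", "y_nm", "frame", "weight"), with = FALSE]
  tab$x_nm <- as.numeric(tab$x_nm)
  tab$y_nm <- as.numeric(tab$y_nm)
  tab$frame <- as.integer(tab$frame)
  tab$weight <- as.numeric(tab$weight)
  ok <- is.finite(tab$x_nm) & is.finite(tab$y_nm) & is.finite(tab$weight)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("read_localizations: dropped %d row(s) with non-finite coordinates", n_dropped))
    tab <- tab[ok]
  }
  nc_check(all(tab$weight > 0), "localization weights must be positive")
  data.table::setattr(tab, "n_dropped", n_dropped)
  tab[]
}

#' Write a localization table to CSV
#'
#' @param locs a localization table (`x_nm`, `y_nm`, `frame`, `weight`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  nc_check(all(c("x_nm", "y_nm") %in% names(locs)),
           "localization table must have x_nm and y_nm columns",
           "nc_schema_error")
  data.table::fwrite(as.data.frame(locs), path)
  invisible(path)
}

#' Region-of-interest mask pair
#'
#' Binds the analysis region of a cell: an include mask (the soma) and an
#' exclude mask (the nucleus), both congruent with the paired image. The
#' exclude mask is clipped to the include mask; the analyzed region is
#' `include & !exclude` and must be non-empty.
#'
#' @param include logical matrix, TRUE inside the soma.
#' @param exclude logical matrix of the same shape, TRUE inside the
#'   nucleus; `NULL` means nothing excluded.
#' @return An object of class `roi_mask` with elements `include`,
#'   `exclude`, and `analyzed` (the effective region).
#' @export
roi_mask <- function(include, exclude = NULL) {
  nc_check(is.matrix(include), "include mask must be a matrix")
  include <- include > 0
  if (is.null(exclude)) {
    exclude <- array(FALSE, dim(include))
  } else {
    nc_check(is.matrix(exclude) && all(dim(exclude) == dim(include)),
             "include and exclude masks must have identical shape")
    exclude <- (exclude > 0) & include # clip to include
  }
  analyzed <- include & !exclude
  nc_check(any(analyzed), "analyzed region (include minus exclude) is empty")
  structure(list(include = include, exclude = exclude, analyzed = analyzed),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d x %d px; include %d px, exclude %d px, analyzed %d px\n",
              nrow(x$include), ncol(x$include), sum(x$include),
              sum(x$exclude), sum(x$analyzed)))
  invisible(x)
}

#' Analyzed-region area of an ROI
#'
#' @param roi a [roi_mask()].
#' @param pixel_size_nm pixel edge in nm.
#' @return Area of `include & !exclude` in nm^2.
#' @export
roi_analyzed_area_nm2 <- function(roi, pixel_size_nm) {
  nc_check(inherits(roi, "roi_mask"), "roi must be a roi_mask")
  sum(roi$analyzed) * pixel_size_nm^2
}

#' Read an ROI mask pair from 8-bit TIFF masks
#'
#' Non-zero pixels are inside. Both masks must match `image_shape`.
#'
#' @param path_include include-mask TIFF (soma).
#' @param path_exclude exclude-mask TIFF (nucleus) or `NULL`.
#' @param image_shape integer vector `c(rows, cols)` of the paired image.
#' @return A [roi_mask()].
#' @export
read_roi_mask <- function(path_include, path_exclude = NULL, image_shape) {
  inc <- .read_tiff_gray(path_include)
  nc_check(all(dim(inc) == image_shape),
           sprintf("include mask shape %dx%d does not match image shape %dx%d",
                   nrow(inc), ncol(inc), image_shape[1], image_shape[2]))
  exc <- NULL
  if (!is.null(path_exclude)) {
    exc <- .read_tiff_gray(path_exclude)
    nc_check(all(dim(exc) == image_shape),
             sprintf("exclude mask shape %dx%d does not match image shape %dx%d",
                     nrow(exc), ncol(exc), image_shape[1], image_shape[2]))
  }
  roi_mask(inc, exc)
}

#' Write a binary mask to an 8-bit TIFF
#'
#' @param mask logical (or 0/1) matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  .write_tiff_gray((mask > 0) * 255, path, bits = 8L)
}

#' Rasterize a polygon to a pixel mask
#'
#' A pixel is inside if its centre is inside the polygon under the
#' even-odd rule. Vertices are world coordinates in nm.
#'
#' @param poly two-column matrix of (x_nm, y_nm) vertices.
#' @param image_shape `c(rows, cols)`.
#' @inheritParams rendered_image
#' @return Logical matrix of `image_shape`.
#' @export
rasterize_polygon <- function(poly, image_shape, pixel_size_nm = 5,
                              origin_nm = c(0, 0)) {
  nc_check(is.matrix(poly) && ncol(poly) == 2 && nrow(poly) >= 3,
           "polygon must be a matrix of >= 3 (x, y) vertices")
  nr <- image_shape[1]; nc <- image_shape[2]
  cx <- origin_nm[1] + (seq_len(nc) - 0.5) * pixel_size_nm
  cy <- origin_nm[2] + (seq_len(nr) - 0.5) * pixel_size_nm
  px <- rep(cx, each = nr)
  py <- rep(cy, times = nc)
  matrix(point_in_polygon(px, py, poly), nrow = nr, ncol = nc)
}

#' Even-odd point-in-polygon test
#'
#' Vectorized ray-casting: a point is inside when a ray to +x crosses the
#' polygon boundary an odd number of times. Points exactly on an edge are
#' resolved by the half-open crossing rule (consistent, not symmetric).
#'
#' @param px,py point coordinates.
#' @param poly two-column vertex matrix (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  xv <- poly[, 1]; yv <- poly[, 2]
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((yv[i] > py) != (yv[j] > py)) &
      (px < (xv[j] - xv[i]) * (py - yv[i]) / (yv[j] - yv[i]) + xv[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Assemble a tidy results table
#'
#' One row per (animal, cell, entity, metric) with explicit units, the
#' exchange format written by the pipeline driver.
#'
#' @param animal_id,cell_id,entity_id identifier vectors (recycled).
#' @param metric metric name vector.
#' @param value numeric values.
#' @param units unit string per metric.
#' @return A `data.table` with one row per (entity, metric).
#' @export
results_table <- function(animal_id, cell_id, entity_id, metric, value, units) {
  tab <- data.table::data.table(animal_id = animal_id, cell_id = cell_id,
                                entity_id = entity_id, metric = metric,
                                value = value, units = units)
  nc_check(!anyNA(tab$units) && all(nzchar(tab$units)),
           "units must be populated for every row")
  nc_check(!anyDuplicated(tab[, c("animal_id", "cell_id", "entity_id", "metric")]),
           "results table must have one row per (entity, metric)")
  tab
}
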
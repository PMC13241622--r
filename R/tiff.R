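# Minimal baseline TIFF codec: single-plane greyscale, uncompressed,
# 8- or 16-bit unsigned, single or multiple strips, either byte order.
# This is all the pipeline needs for rendered images and ROI masks; no
# TIFF reader ships with the supported R stack, so the subset is
# implemented here rather than pulled in as a dependency.

.TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

.read_uint <- function(raw, off, size, n, endian) {
  # off is a 0-based byte offset
  v <- readBin(raw[(off + 1):(off + size * n)], "integer",
               n = n, size = size, endian = endian,
               signed = size == 4L)
  if (size == 4L && any(v < 0))
    nc_stop("TIFF offset exceeds 2 GiB; unsupported", "nc_format_error")
  v
}

.tiff_tag_values <- function(raw, entry_off, endian) {
  type <- .read_uint(raw, entry_off + 2, 2, 1, endian)
  count <- .read_uint(raw, entry_off + 4, 4, 1, endian)
  size <- .TIFF_TYPE_SIZE[as.character(type)]
  if (is.na(size)) return(NULL) # RATIONAL etc.: not needed, skip
  if (size * count <= 4) {
    .read_uint(raw, entry_off + 8, size, count, endian)
  } else {
    val_off <- .read_uint(raw, entry_off + 8, 4, 1, endian)
    .read_uint(raw, val_off, size, count, endian)
  }
}

.read_tiff_gray <- function(path) {
  nc_check(file.exists(path), sprintf("file not found: %s", path),
           "nc_format_error")
  raw <- readBin(path, "raw", file.size(path))
  nc_check(length(raw) >= 8, "not a TIFF file (too short)", "nc_format_error")
  bom <- rawToChar(raw[1:2])
  endian <- if (bom == "II") "little" else if (bom == "MM") "big" else
    nc_stop("not a TIFF file (bad byte-order mark)", "nc_format_error")
  nc_check(.read_uint(raw, 2, 2, 1, endian) == 42L,
           "not a TIFF file (bad magic number)", "nc_format_error")
  ifd <- .read_uint(raw, 4, 4, 1, endian)
  ntags <- .read_uint(raw, ifd, 2, 1, endian)
  tags <- list()
  for (t in seq_len(ntags) - 1L) {
    eoff <- ifd + 2 + 12 * t
    id <- .read_uint(raw, eoff, 2, 1, endian)
    tags[[as.character(id)]] <- .tiff_tag_values(raw, eoff, endian)
  }
  if (.read_uint(raw, ifd + 2 + 12 * ntags, 4, 1, endian) != 0L)
    nc_stop("multi-page TIFF not supported (single plane expected)",
            "nc_format_error")
  g <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  width <- g(256); height <- g(257)
  nc_check(!is.null(width) && !is.null(height),
           "TIFF lacks image dimensions", "nc_format_error")
  bits <- g(258, 1L)
  if (length(bits) > 1L || g(277, 1L) != 1L)
    nc_stop("multi-channel TIFF not supported (greyscale expected)",
            "nc_format_error")
  if (!bits %in% c(8L, 16L))
    nc_stop(sprintf("unsupported bit depth %d (8 or 16 expected)", bits),
            "nc_format_error")
  if (g(259, 1L) != 1L)
    nc_stop("compressed TIFF not supported", "nc_format_error")
  if (!g(262, 1L) %in% c(0L, 1L))
    nc_stop("non-greyscale photometric interpretation not supported",
            "nc_format_error")
  if (g(339, 1L) != 1L)
    nc_stop("non-integer (float/signed) TIFF not supported",
            "nc_format_error")
  offs <- g(273); counts <- g(279)
  nc_check(!is.null(offs) && !is.null(counts),
           "TIFF lacks strip layout tags", "nc_format_error")
  bytes <- unlist(lapply(seq_along(offs), function(s) {
    raw[(offs[s] + 1):(offs[s] + counts[s])]
  }))
  npix <- as.numeric(width) * height
  nc_check(length(bytes) >= npix * bits / 8,
           "TIFF pixel data truncated", "nc_format_error")
  v <- readBin(bytes, "integer", n = npix, size = bits / 8L,
               endian = endian, signed = FALSE)
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}

.write_tiff_gray <- function(pixels, path, bits = 16L) {
  pixels <- round(pixels)
  maxval <- 2^bits - 1
  nc_check(all(is.finite(pixels)) && all(pixels >= 0) &&
             all(pixels <= maxval),
           sprintf("pixel intensities must lie in [0, %d] for %d-bit output",
                   maxval, bits))
  con <- file(path, "wb")
  on.exit(close(con))
  h <- nrow(pixels); w <- ncol(pixels)
  wr <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  tags <- list( # id, type (3 = SHORT, 4 = LONG), value
    c(256L, 4L, w), c(257L, 4L, h), c(258L, 3L, bits), c(259L, 3L, 1L),
    c(262L, 3L, 1L), c(273L, 4L, NA), c(277L, 3L, 1L), c(278L, 4L, h),
    c(279L, 4L, h * w * bits / 8L), c(339L, 3L, 1L))
  data_off <- 8L + 2L + length(tags) * 12L + 4L
  tags[[6]][3] <- data_off
  writeBin(charToRaw("II"), con); wr(42L, 2); wr(8L, 4)
  wr(length(tags), 2)
  for (tg in tags) {
    wr(tg[1], 2); wr(tg[2], 2); wr(1L, 4)
    if (tg[2] == 3L) { wr(tg[3], 2); wr(0L, 2) } else wr(tg[3], 4)
  }
  wr(0L, 4) # no further IFD
  wr(t(pixels), bits / 8L)
  invisible(path)
}
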
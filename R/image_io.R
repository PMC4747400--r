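#' Construct an RGB brightfield image
#'
#' The container used throughout the pipeline. Pixel values are stored
#' normalized to \[0,1\] (intensities are divided by the white level
#' immediately on reading, so all downstream math is bit-depth independent);
#' `dtype_scale` records the original white level (255 for 8-bit, 65535 for
#' 16-bit, 1.0 for float data).
#'
#' @param pixels Numeric H x W x 3 array with values in \[0,1\].
#' @param dtype_scale White level of the source data.
#' @param pixel_size_um Optional micrometers per pixel; when absent, areas
#'   are reported in pixels only.
#' @return An object of class `"rgb_image"`.
#' @export
rgb_image <- function(pixels, dtype_scale = 1, pixel_size_um = NULL) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("format error: expected an H x W x 3 array, got ",
         if (length(d) == 3L) paste0(d[3], " channel(s)") else "a non-3D array")
  if (d[1] < 1L || d[2] < 1L) stop("image must be at least 1 x 1")
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1] after normalization")
  if (!is.null(pixel_size_um)) {
    pixel_size_um <- as.numeric(pixel_size_um)
    if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
      stop("pixel_size_um must be a positive number")
  }
  structure(list(pixels = pixels, dtype_scale = dtype_scale,
                 pixel_size_um = pixel_size_um),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("RGB brightfield image: %d x %d px, white level %g%s\n",
              d[1], d[2], x$dtype_scale,
              if (is.null(x$pixel_size_um)) ""
              else sprintf(", %g um/px", x$pixel_size_um)))
  invisible(x)
}

#' Read a TIFF or PNG raster as an RGB image
#'
#' The white level is inferred from the file's bit depth (255 for 8-bit,
#' 65535 for 16-bit, 1.0 for floating-point samples) and values are
#' normalized to \[0,1\]. Grayscale inputs are rejected; an alpha channel is
#' dropped with a warning. Whole-slide containers (VSI) are not supported:
#' convert to TIFF upstream.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um Optional micrometers per pixel, recorded as metadata.
#' @return An [rgb_image()].
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("cannot read image, file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(px, "bits.per.sample")
    scale <- if (is.null(bits) || !bits %in% c(8L, 16L)) 1.0 else 2^bits - 1
  } else if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    info <- attr(px, "info")
    bits <- if (is.null(info)) 8L else info$bit.depth
    scale <- 2^bits - 1
  } else {
    stop("unsupported image format '.", ext, "': expected TIFF or PNG")
  }
  d <- dim(px)
  if (length(d) < 3L || d[3] < 3L) {
    nch <- if (length(d) < 3L) 1L else d[3]
    stop("format error: image has ", nch,
         " channel(s); a 3-channel RGB raster is required")
  }
  if (d[3] > 3L) {
    warning("dropping alpha channel (", d[3], " channels in ", basename(path),
            ")")
    px <- px[, , 1:3, drop = FALSE]
  }
  px <- array(pmin(pmax(as.numeric(px), 0), 1), dim = c(d[1], d[2], 3L))
  rgb_image(px, dtype_scale = scale, pixel_size_um = pixel_size_um)
}

#' Write an RGB image or single raster as TIFF
#'
#' Uncompressed output so repeated writes of identical data are
#' byte-identical.
#'
#' @param x An [rgb_image()], or a numeric array/matrix with values in
#'   \[0,1\].
#' @param path Output path.
#' @param bits_per_sample 8, 16 or 32 (32 writes float samples).
#' @return Invisibly, `path`.
#' @export
write_image <- function(x, path, bits_per_sample = 16L) {
  px <- if (inherits(x, "rgb_image")) x$pixels else x
  if (!all(is.finite(px)) || min(px) < 0 || max(px) > 1)
    stop("pixel values must lie in [0, 1]")
  tiff::writeTIFF(px, path, bits.per.sample = as.integer(bits_per_sample),
                  compression = "none")
  invisible(path)
}

#' Write / read a label mask as a 16-bit single-channel TIFF
#'
#' Labels up to 65535 are stored losslessly.
#'
#' @param mask Integer label matrix (0 = background).
#' @param path File path.
#' @return `write_label_mask` invisibly returns `path`; `read_label_mask`
#'   returns an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask) > 65535L) stop("more than 65535 labels cannot be stored")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}

# %.17g formatting: doubles survive a write -> parse round trip exactly and
# output bytes are reproducible across runs.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

record_columns <- c("label", "area_px", "area_um2", "centroid_row",
                    "centroid_col", "ring_pixels", "perinuclear_mean",
                    "perinuclear_integrated", "border_flag")

#' Write per-cell records to CSV
#'
#' One row per nucleus, sorted by label. Undefined values (`area_um2`
#' without a pixel size, `perinuclear_mean` for ring-less cells) are written
#' as empty fields. Output is deterministic: fixed column order, label
#' ordering, and float formatting.
#'
#' @param records A per-cell data frame from [measure_cells()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_records <- function(records, path) {
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols))
    stop("records are missing column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[order(records$label), record_columns, drop = FALSE]
  out <- data.frame(
    label = as.integer(records$label),
    area_px = as.integer(records$area_px),
    area_um2 = fmt_num(records$area_um2),
    centroid_row = fmt_num(records$centroid_row),
    centroid_col = fmt_num(records$centroid_col),
    ring_pixels = as.integer(records$ring_pixels),
    perinuclear_mean = fmt_num(records$perinuclear_mean),
    perinuclear_integrated = fmt_num(records$perinuclear_integrated),
    border_flag = ifelse(records$border_flag, "TRUE", "FALSE"),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(record_columns, collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' Read per-cell records from CSV
#'
#' Validates that all expected columns are present, naming any that are
#' missing.
#'
#' @param path CSV path written by [write_records()].
#' @return A per-cell data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("cannot read records, file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(record_columns, names(df))
  if (length(missing_cols))
    stop("malformed records CSV ", basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df$label <- as.integer(df$label)
  df$area_px <- as.integer(df$area_px)
  df$ring_pixels <- as.integer(df$ring_pixels)
  for (cc in c("area_um2", "centroid_row", "centroid_col",
               "perinuclear_mean", "perinuclear_integrated"))
    df[[cc]] <- as.numeric(df[[cc]])
  df$border_flag <- as.logical(df$border_flag)
  df
}

# Boundary pixels of a label mask: labeled pixels with a 4-neighbor carrying
# a different value (another label or background).
label_contours <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(-1L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  ctr <- pad[2:(H + 1L), 2:(W + 1L)]
  diff_any <- (pad[1:H, 2:(W + 1L)] != ctr) |
    (pad[3:(H + 2L), 2:(W + 1L)] != ctr) |
    (pad[2:(H + 1L), 1:W] != ctr) |
    (pad[2:(H + 1L), 3:(W + 2L)] != ctr)
  (ctr > 0L) & diff_any
}

#' Write a QC overlay of nuclear and ring contours
#'
#' Draws nuclear contours (green) and perinuclear ring contours (magenta)
#' over the input image and writes a PNG. Because nuclear and ring masks are
#' disjoint, the two contour sets never share a pixel.
#'
#' @param image The analyzed [rgb_image()].
#' @param nuclei Nuclear label mask.
#' @param rings Ring label mask.
#' @param path Output PNG path.
#' @param nucleus_color,ring_color RGB triplets in \[0,1\].
#' @return Invisibly, `path`.
#' @export
write_overlay <- function(image, nuclei, rings, path,
                          nucleus_color = c(0, 0.85, 0),
                          ring_color = c(1, 0, 1)) {
  d <- dim(image$pixels)
  if (!identical(d[1:2], dim(nuclei)) || !identical(d[1:2], dim(rings)))
    stop("mask shape does not match image shape")
  out <- image$pixels
  nc <- label_contours(nuclei)
  rc <- label_contours(rings)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[nc] <- nucleus_color[ch]
    plane[rc] <- ring_color[ch]
    out[, , ch] <- plane
  }
  png::writePNG(out, path)
  invisible(path)
}
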
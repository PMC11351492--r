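#' Read and write stained micrographs
#'
#' 8-bit RGB PNG or TIFF, dispatched on the file extension. Grayscale input
#' is rejected; an alpha channel, if present, is dropped.
#'
#' @param path image file (\code{.png}, \code{.tif}, \code{.tiff}).
#' @param stain_type one of \code{stain_types()}.
#' @param microns_per_pixel optional physical pixel size.
#' @param label free-text label; defaults to the file name.
#' @return a \code{\link{stain_image}}.
#' @export
read_stain_image <- function(path, stain_type, microns_per_pixel = NULL,
                             label = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: '", ext, "'", call. = FALSE))
  if (length(dim(raw)) != 3)
    stop("grayscale images are not supported; 8-bit RGB required", call. = FALSE)
  if (dim(raw)[3] >= 4) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] != 3)
    stop("expected 3 color channels, found ", dim(raw)[3], call. = FALSE)
  px <- array(as.integer(round(raw * 255)), dim = dim(raw)[1:3])
  stain_image(px, stain_type = stain_type,
              microns_per_pixel = microns_per_pixel, label = label)
}

#' @rdname read_stain_image
#' @param image a \code{\link{stain_image}}.
#' @export
write_stain_image <- function(image, path) {
  stopifnot(inherits(image, "stain_image"))
  arr <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(arr, path),
         tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
         stop("unsupported image format: '", ext, "'", call. = FALSE))
  invisible(path)
}

#' Read and write binary masks as single-channel PNG
#'
#' Masks are stored as 0/255 grayscale; any non-zero value reads back as
#' foreground.
#' @param mask logical matrix.
#' @param path PNG file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  raw > 0
}

#' Read a manual-override mask
#'
#' Single-channel PNG whose raw 8-bit values are the override codes:
#' 0 = no change, 1 = background, 2 = fiber, 3 = nucleus, 4 = artifact.
#' @param path PNG file path.
#' @return integer matrix of codes.
#' @seealso \code{\link{apply_overrides}}
#' @export
read_override_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  codes <- matrix(as.integer(round(raw * 255)), nrow(raw), ncol(raw))
  if (any(codes > 4))
    stop("override PNG contains values above 4; expected raw codes 0..4",
         call. = FALSE)
  codes
}

#' Write a class map as a color-convention PNG
#'
#' Renders a segmentation's class map with the display convention used for
#' segmented dermis overlays: fibers red, nuclei blue, artifacts green,
#' background white.
#' @param seg a \code{\link{segment_stain}} result.
#' @param path PNG file path.
#' @export
write_class_map_png <- function(seg, path) {
  stopifnot(inherits(seg, "stain_segmentation"))
  cm <- seg$class_map
  cols <- rbind(background = c(1, 1, 1), fiber = c(1, 0, 0),
                nucleus = c(0, 0, 1), artifact = c(0, 0.8, 0))
  arr <- array(0, dim = c(nrow(cm), ncol(cm), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(cols[cm + 1L, ch], nrow(cm), ncol(cm))
  png::writePNG(arr, path)
  invisible(path)
}

#' Write a component table as CSV
#'
#' Columns \code{component_id,area_px,centroid_row,centroid_col} (plus
#' \code{max_thickness} when present).
#' @param components a \code{component_table}.
#' @param path CSV file path.
#' @export
write_component_csv <- function(components, path) {
  write.csv(as.data.frame(components), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_component_csv
#' @export
read_areas_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("component_id", "area_px") %in% names(df)) &&
      !all(c("bundle_id", "area_px") %in% names(df)))
    stop("areas CSV needs columns (component_id|bundle_id), area_px", call. = FALSE)
  df$area_px
}

#' Write drawn bundle areas as CSV
#'
#' Header \code{bundle_id,area_px}; the ground-truth export of the synthetic
#' generator.
#' @param truth the \code{truth} element of \code{\link{render_micrograph}}.
#' @param path CSV file path.
#' @export
write_bundle_areas_csv <- function(truth, path) {
  write.csv(data.frame(bundle_id = truth$bundle_ids, area_px = truth$bundle_areas),
            path, row.names = FALSE)
  invisible(path)
}
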
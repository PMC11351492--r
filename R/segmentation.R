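CLASS_BACKGROUND <- 0L
CLASS_FIBER <- 1L
CLASS_NUCLEUS <- 2L
CLASS_ARTIFACT <- 3L

#' An RGB micrograph with stain metadata
#'
#' Thin container for an 8-bit RGB brightfield micrograph of a stained skin
#' section, carrying the stain type and optional physical pixel size.
#'
#' @param pixels H x W x 3 array of 8-bit values (0--255).
#' @param stain_type one of \code{stain_types()}.
#' @param microns_per_pixel optional positive scalar.
#' @param label free-text label (e.g. \code{"2012 sample 1"}).
#' @return object of class \code{stain_image}.
#' @export
stain_image <- function(pixels, stain_type, microns_per_pixel = NULL, label = "") {
  stain_type <- match.arg(stain_type, stain_types())
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3)
    stop("'pixels' must be an H x W x 3 RGB array", call. = FALSE)
  if (d[1] < 32 || d[2] < 32)
    stop("image must be at least 32 x 32", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("'pixels' must be 8-bit values in [0, 255]", call. = FALSE)
  if (!is.null(microns_per_pixel) && microns_per_pixel <= 0)
    stop("'microns_per_pixel' must be positive", call. = FALSE)
  structure(list(pixels = pixels, stain_type = stain_type,
                 microns_per_pixel = microns_per_pixel, label = label),
            class = "stain_image")
}

#' @export
print.stain_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("stain_image: %d x %d, stain '%s'%s%s\n", d[1], d[2], x$stain_type,
              if (nzchar(x$label)) paste0(", label '", x$label, "'") else "",
              if (!is.null(x$microns_per_pixel))
                sprintf(", %.4g um/px", x$microns_per_pixel) else ""))
  invisible(x)
}

#' @export
dim.stain_image <- function(x) dim(x$pixels)

check_range01 <- function(x, what) {
  if (length(x) != 2 || any(x < 0) || any(x > 1))
    stop("'", what, "' range must be two values in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Color-threshold profile for one stain
#'
#' Hue/saturation/value box thresholds for the fiber and nucleus classes of a
#' stain. All bounds live in \eqn{[0, 1]}; a hue interval with low > high is
#' interpreted as wrapping through 0 (red hues). Ship-with defaults per stain
#' are calibrated on the synthetic renderer's palettes and can be overridden
#' freely for real material.
#'
#' @param stain_type one of \code{stain_types()}.
#' @param fiber,nucleus lists with components \code{h}, \code{s}, \code{v},
#'   each \code{c(low, high)}.
#' @return object of class \code{stain_profile}.
#' @export
#' @examples
#' default_stain_profile("he")
stain_profile <- function(stain_type, fiber, nucleus) {
  stain_type <- match.arg(stain_type, stain_types())
  for (cls in list(fiber, nucleus)) {
    check_range01(cls$h, "h"); check_range01(cls$s, "s"); check_range01(cls$v, "v")
    if (cls$s[1] > cls$s[2] || cls$v[1] > cls$v[2])
      stop("saturation/value ranges must have low <= high", call. = FALSE)
  }
  structure(list(stain_type = stain_type, fiber = fiber, nucleus = nucleus),
            class = "stain_profile")
}

#' @rdname stain_profile
#' @export
default_stain_profile <- function(stain_type) {
  stain_type <- match.arg(stain_type, stain_types())
  defs <- list(
    he = list(fiber = list(h = c(0.87, 0.05), s = c(0.20, 0.90), v = c(0.45, 0.99)),
              nucleus = list(h = c(0.58, 0.80), s = c(0.25, 1.00), v = c(0.15, 0.85))),
    mallory = list(fiber = list(h = c(0.54, 0.73), s = c(0.35, 1.00), v = c(0.25, 0.95)),
                   nucleus = list(h = c(0.74, 0.90), s = c(0.25, 1.00), v = c(0.15, 0.85))),
    silver = list(fiber = list(h = c(0.00, 1.00), s = c(0.00, 1.00), v = c(0.00, 0.35)),
                  nucleus = list(h = c(0.58, 0.80), s = c(0.25, 1.00), v = c(0.36, 0.85))),
    weigert_orcein = list(fiber = list(h = c(0.79, 0.94), s = c(0.25, 0.90), v = c(0.12, 0.62)),
                          nucleus = list(h = c(0.58, 0.78), s = c(0.25, 1.00), v = c(0.15, 0.85)))
  )[[stain_type]]
  stain_profile(stain_type, fiber = defs$fiber, nucleus = defs$nucleus)
}

# logical matrix of pixels inside an h/s/v box; hue may wrap through 0
hsv_in_range <- function(h, s, v, box) {
  hin <- if (box$h[1] <= box$h[2]) h >= box$h[1] & h <= box$h[2]
         else h >= box$h[1] | h <= box$h[2]
  hin & s >= box$s[1] & s <= box$s[2] & v >= box$v[1] & v <= box$v[2]
}

#' Segment fibrous ECM from a stained micrograph
#'
#' Classifies every pixel as background, fiber or nucleus by HSV color
#' thresholding: fiber pixels are those inside the fiber color box and
#' outside the nucleus box, mirroring the red/blue convention of manual
#' color-threshold segmentation of stained dermis. A morphological opening
#' (radius-1 diamond structuring element) removes speckle from the fiber
#' mask. Artifact pixels (class 3) only arise through
#' \code{\link{apply_overrides}}.
#'
#' @param image a \code{\link{stain_image}}.
#' @param profile a \code{\link{stain_profile}} whose \code{stain_type}
#'   matches the image's; defaults to the stain's shipped profile.
#' @param cleanup apply the morphological opening (default TRUE). Disabling
#'   it exposes the raw thresholded mask.
#' @return object of class \code{stain_segmentation}: list with
#'   \code{class_map} (integer H x W, 0 = background, 1 = fiber,
#'   2 = nucleus, 3 = artifact) and logical \code{fiber_mask}
#'   (identically \code{class_map == 1}).
#' @export
segment_stain <- function(image, profile = default_stain_profile(image$stain_type),
                          cleanup = TRUE) {
  stopifnot(inherits(image, "stain_image"), inherits(profile, "stain_profile"))
  if (!identical(profile$stain_type, image$stain_type))
    stop(sprintf("profile is for stain '%s' but image is '%s'",
                 profile$stain_type, image$stain_type), call. = FALSE)
  px <- image$pixels
  d <- dim(px)
  hsv <- rgb2hsv(rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                       as.vector(px[, , 3])), maxColorValue = 255)
  h <- matrix(hsv[1, ], d[1], d[2])
  s <- matrix(hsv[2, ], d[1], d[2])
  v <- matrix(hsv[3, ], d[1], d[2])

  nuc <- hsv_in_range(h, s, v, profile$nucleus)
  fib <- hsv_in_range(h, s, v, profile$fiber) & !nuc
  if (cleanup && any(fib)) {
    fib <- EBImage::opening(fib * 1, EBImage::makeBrush(3, "diamond")) > 0
  }
  class_map <- matrix(CLASS_BACKGROUND, d[1], d[2])
  class_map[nuc] <- CLASS_NUCLEUS
  class_map[fib] <- CLASS_FIBER
  structure(list(class_map = class_map, fiber_mask = fib,
                 stain_type = image$stain_type, label = image$label),
            class = "stain_segmentation")
}

#' @export
print.stain_segmentation <- function(x, ...) {
  tab <- tabulate(as.vector(x$class_map) + 1L, nbins = 4L)
  cat(sprintf("stain_segmentation %d x %d (%s): %d fiber, %d nucleus, %d artifact, %d background px\n",
              nrow(x$class_map), ncol(x$class_map), x$stain_type,
              tab[2], tab[3], tab[4], tab[1]))
  invisible(x)
}

#' Apply a manual-override mask to a segmentation
#'
#' File-based stand-in for interactive manual correction: non-zero override
#' pixels replace the class assignment. Override codes are
#' \code{0} = no change (sentinel), \code{1} = background, \code{2} = fiber,
#' \code{3} = nucleus, \code{4} = artifact. The fiber mask is recomputed.
#'
#' @param result a \code{\link{segment_stain}} result.
#' @param override integer matrix of the same shape with codes 0--4.
#' @return updated \code{stain_segmentation}.
#' @export
apply_overrides <- function(result, override) {
  stopifnot(inherits(result, "stain_segmentation"))
  if (!identical(dim(override), dim(result$class_map)))
    stop("override mask shape does not match the class map", call. = FALSE)
  if (any(override < 0 | override > 4))
    stop("override codes must be 0 (no change) .. 4 (artifact)", call. = FALSE)
  cm <- result$class_map
  sel <- override != 0L
  cm[sel] <- as.integer(override[sel]) - 1L
  result$class_map <- cm
  result$fiber_mask <- cm == CLASS_FIBER
  result
}

#' Label connected fiber bundles
#'
#' 8-connected component labeling of a binary mask (components touching only
#' at a corner are one bundle). Components smaller than \code{min_area} are
#' dropped; the remaining components are ordered by decreasing area, ties
#' broken by the top-left-most pixel in row-major order.
#'
#' @param mask logical matrix (or a \code{stain_segmentation}, whose fiber
#'   mask is used).
#' @param min_area minimum pixel area to keep; speckle suppression.
#' @return a \code{component_table}: data frame with columns
#'   \code{component_id}, \code{area_px}, \code{centroid_row},
#'   \code{centroid_col}, carrying the relabeled image as attribute
#'   \code{"labels"} (0 = background/dropped).
#' @export
label_components <- function(mask, min_area = 10) {
  if (inherits(mask, "stain_segmentation")) mask <- mask$fiber_mask
  stopifnot(is.matrix(mask))
  if (min_area < 0) stop("'min_area' must be non-negative", call. = FALSE)
  mask <- mask != 0
  lab <- label8_cpp(mask)
  L <- max(lab)
  if (L == 0) {
    tb <- data.frame(component_id = integer(0), area_px = numeric(0),
                     centroid_row = numeric(0), centroid_col = numeric(0))
    attr(tb, "labels") <- lab
    class(tb) <- c("component_table", "data.frame")
    return(tb)
  }
  H <- nrow(lab); W <- ncol(lab)
  wi <- which(lab > 0)
  lv <- lab[wi]
  rows <- (wi - 1L) %% H + 1L
  cols <- (wi - 1L) %/% H + 1L
  area <- tabulate(lv, nbins = L)
  crow <- rowsum(as.numeric(rows), lv)[, 1] / area
  ccol <- rowsum(as.numeric(cols), lv)[, 1] / area
  # top-left-most pixel in row-major order, for deterministic tie-breaking
  rm_idx <- (rows - 1L) * W + cols
  first_rm <- vapply(split(rm_idx, lv), min, numeric(1))

  keep <- which(area >= min_area)
  o <- keep[order(-area[keep], first_rm[keep])]
  tb <- data.frame(component_id = seq_along(o), area_px = as.numeric(area[o]),
                   centroid_row = unname(crow[o]), centroid_col = unname(ccol[o]))
  relab <- integer(L)
  relab[o] <- seq_along(o)
  newlab <- lab
  newlab[wi] <- relab[lv]
  attr(tb, "labels") <- newlab
  class(tb) <- c("component_table", "data.frame")
  tb
}
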
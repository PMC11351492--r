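#' Area fraction of a binary mask
#'
#' Percentage of image pixels that are foreground; the "area occupied by the
#' ECM" readout when applied to a fiber mask.
#' @param mask logical/binary matrix (or a \code{stain_segmentation}).
#' @return percent in \eqn{[0, 100]}.
#' @export
#' @examples
#' area_fraction(matrix(c(TRUE, FALSE), 32, 32))
area_fraction <- function(mask) {
  if (inherits(mask, "stain_segmentation")) mask <- mask$fiber_mask
  if (length(mask) == 0) stop("mask has zero size", call. = FALSE)
  100 * sum(mask != 0) / length(mask)
}

#' Local thickness transform
#'
#' For every foreground pixel \eqn{p}, the diameter of the largest disk that
#' fits entirely inside the foreground and covers \eqn{p} (the
#' Hildebrand-Ruegsegger definition; pixels outside the canvas count as
#' background). Computed from the exact Euclidean distance transform via
#' distance-ridge reduction and disk painting; the per-bundle maximum of the
#' map is the bundle width.
#'
#' @param mask logical/binary matrix.
#' @return numeric matrix of thickness in pixels (diameter convention), zero
#'   on background.
#' @export
#' @examples
#' tm <- local_thickness(make_geometric_fixture("disk", list(radius = 10),
#'                                              c(64, 64)))
#' max(tm)   # about 20
local_thickness <- function(mask) {
  stopifnot(is.matrix(mask))
  local_thickness_cpp(mask != 0)
}

#' Per-bundle maximum width and widest-point markers
#'
#' Fills the \code{max_thickness} column of a component table with each
#' bundle's maximum local thickness and returns a marker mask of the pixels
#' attaining it (all ties marked) -- the "widest point" overlay of each
#' bundle.
#'
#' @param tmap a \code{\link{local_thickness}} map.
#' @param components a \code{\link{label_components}} table (its
#'   \code{"labels"} attribute must align with \code{tmap}).
#' @return list with \code{components} (table plus \code{max_thickness},
#'   pixels) and logical \code{markers}.
#' @export
max_bundle_width <- function(tmap, components) {
  stopifnot(inherits(components, "component_table"))
  lab <- attr(components, "labels")
  if (is.null(lab) || !identical(dim(lab), dim(tmap)))
    stop("thickness map and component labels have different shapes", call. = FALSE)
  n <- nrow(components)
  markers <- matrix(FALSE, nrow(tmap), ncol(tmap))
  mx <- rep(NA_real_, n)
  if (n > 0) {
    wi <- which(lab > 0)
    lv <- lab[wi]
    tv <- tmap[wi]
    mx_by_label <- vapply(split(tv, lv), max, numeric(1))
    mx[as.integer(names(mx_by_label))] <- mx_by_label
    markers[wi[tv == mx[lv]]] <- TRUE
  }
  components$max_thickness <- mx
  list(components = components, markers = markers)
}

#' Mean with Student-t confidence interval
#'
#' Summary used for area fractions and normalized widths: mean and two-sided
#' confidence interval based on Student's t with \eqn{n - 1} degrees of
#' freedom.
#' @param values numeric vector, length at least 2.
#' @param level confidence level.
#' @return object of class \code{morph_summary}: list with \code{n},
#'   \code{mean}, \code{ci95 = c(low, high)}.
#' @export
#' @examples
#' summarize_mean_ci(c(40, 50, 60))
summarize_mean_ci <- function(values, level = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 values to form a confidence interval",
                  call. = FALSE)
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(values) / sqrt(n)
  structure(list(n = n, mean = m, ci95 = c(m - half, m + half), level = level),
            class = "morph_summary")
}

#' @export
print.morph_summary <- function(x, digits = 2, ...) {
  cat(sprintf("n = %d, mean = %.*f, %d%% CI (%.*f; %.*f)\n", x$n, digits, x$mean,
              round(100 * x$level), digits, x$ci95[1], digits, x$ci95[2]))
  invisible(x)
}

#' Histogram of per-bundle areas
#'
#' Linear bins \eqn{[0, w), [w, 2w), \ldots} covering the maximum area;
#' right-open intervals, with the last bin right-closed so the maximum is
#' counted.
#' @param components a \code{component_table}, or a numeric vector of areas.
#' @param bin_width bin width in pixel^2; positive.
#' @return object of class \code{area_histogram}: list with \code{bin_edges}
#'   (length one more than \code{counts}) and integer \code{counts}.
#' @export
#' @examples
#' component_area_histogram(c(1, 3, 5), bin_width = 2)
component_area_histogram <- function(components, bin_width) {
  if (bin_width <= 0) stop("'bin_width' must be positive", call. = FALSE)
  areas <- if (inherits(components, "component_table")) components$area_px
           else as.numeric(components)
  if (length(areas) == 0) {
    return(structure(list(bin_edges = 0, counts = integer(0)),
                     class = "area_histogram"))
  }
  nb <- max(1L, as.integer(ceiling(max(areas) / bin_width)))
  edges <- bin_width * (0:nb)
  idx <- findInterval(areas, edges, rightmost.closed = TRUE)
  structure(list(bin_edges = edges, counts = tabulate(idx, nbins = nb)),
            class = "area_histogram")
}

#' @export
print.area_histogram <- function(x, ...) {
  cat(sprintf("area histogram: %d bins of width %s, %d components\n",
              length(x$counts),
              format(if (length(x$bin_edges) > 1) diff(x$bin_edges[1:2]) else 0),
              sum(x$counts)))
  invisible(x)
}

#' @export
plot.area_histogram <- function(x, ...) {
  if (length(x$counts) == 0) {
    plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "bundle area (px^2)",
         ylab = "count", main = "Bundle areas", ...)
    return(invisible(x))
  }
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  plot(mids, x$counts, type = "h", lwd = 3, xlab = "bundle area (px^2)",
       ylab = "count", main = "Bundle areas", ...)
  invisible(x)
}

#' @rdname component_area_histogram
#' @param histogram an \code{area_histogram}.
#' @param path CSV file path (columns \code{bin_low,bin_high,count}).
#' @export
write_histogram_csv <- function(histogram, path) {
  ne <- length(histogram$bin_edges)
  df <- data.frame(bin_low = histogram$bin_edges[-ne],
                   bin_high = histogram$bin_edges[-1],
                   count = histogram$counts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
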
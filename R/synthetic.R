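#' Stain palette used by the synthetic renderer
#'
#' Flat RGB colors (0--255) for fiber, nucleus, artifact and background under
#' each supported stain: H&E (fibers pink-red), Mallory's trichrome (deep
#' blue), silver impregnation (black reticular fibers), Weigert's/orcein
#' (dark violet-brown elastic fibers). Nuclei are blue-purple, the background
#' near-white.
#'
#' @param stain_type one of \code{"he"}, \code{"mallory"}, \code{"silver"},
#'   \code{"weigert_orcein"}.
#' @return list of RGB triplets \code{fiber}, \code{nucleus}, \code{artifact},
#'   \code{background}.
#' @export
stain_palette <- function(stain_type) {
  stain_type <- match.arg(stain_type, stain_types())
  base <- list(
    he = list(fiber = c(229, 106, 141), nucleus = c(72, 61, 139),
              background = c(247, 244, 246)),
    mallory = list(fiber = c(47, 62, 167), nucleus = c(110, 50, 120),
                   background = c(245, 243, 247)),
    silver = list(fiber = c(38, 34, 32), nucleus = c(72, 61, 139),
                  background = c(235, 230, 226)),
    weigert_orcein = list(fiber = c(96, 48, 86), nucleus = c(72, 61, 139),
                          background = c(244, 240, 238))
  )[[stain_type]]
  base$artifact <- c(122, 139, 104)
  base
}

#' @rdname stain_palette
#' @export
stain_types <- function() c("he", "mallory", "silver", "weigert_orcein")

#' Recipe for one synthetic micrograph
#'
#' Bundles a full, reproducible description of a synthetic stained-dermis
#' micrograph: per-bundle pixel areas follow a two-parameter GPD with shape
#' \code{shape_k} and scale \code{scale_sigma}; bundles are rendered as
#' elongated ribbon strokes, plus nuclei, artifact debris, and Gaussian pixel
#' noise. Defaults mirror the package's reference study conditions: a shape
#' and scale from the young-dermis (Mallory 2012) reference fit, a few tens
#' of bundles per field, and mild sensor noise.
#'
#' @param shape_k GPD tail index of the bundle-area distribution.
#' @param scale_sigma GPD scale (area units, pixel^2); positive.
#' @param n_bundles number of fiber bundles to draw.
#' @param image_size \code{c(height, width)} in pixels; each at least 32.
#' @param stain_type one of \code{stain_types()}.
#' @param fiber_aspect elongation (length/width) of the ribbon strokes; >= 1.
#' @param n_nuclei number of nuclei.
#' @param n_artifacts number of artifact/debris structures.
#' @param noise_sd Gaussian pixel noise, 8-bit intensity units.
#' @param seed integer; the whole rendering is a deterministic function of
#'   the spec including this seed.
#' @return object of class \code{synthetic_spec}.
#' @seealso \code{\link{render_micrograph}}, \code{\link{sample_gpd}}
#' @export
synthetic_spec <- function(shape_k = 0.72, scale_sigma = 2.4, n_bundles = 30,
                           image_size = c(512, 512), stain_type = "he",
                           fiber_aspect = 4, n_nuclei = 30, n_artifacts = 2,
                           noise_sd = 3, seed = 1) {
  stain_type <- match.arg(stain_type, stain_types())
  check_scale(scale_sigma)
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 32))
    stop("'image_size' must be c(height, width) with both >= 32", call. = FALSE)
  if (n_bundles < 0 || n_nuclei < 0 || n_artifacts < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (fiber_aspect < 1) stop("'fiber_aspect' must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  structure(list(
    shape_k = shape_k, scale_sigma = scale_sigma,
    n_bundles = as.integer(n_bundles), image_size = image_size,
    stain_type = stain_type, fiber_aspect = fiber_aspect,
    n_nuclei = as.integer(n_nuclei), n_artifacts = as.integer(n_artifacts),
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic micrograph spec: %dx%d %s, %d bundles ~ GPD(k=%.3f, sigma=%.3f)\n",
              x$image_size[1], x$image_size[2], x$stain_type, x$n_bundles,
              x$shape_k, x$scale_sigma))
  cat(sprintf("  aspect %.1f, %d nuclei, %d artifacts, noise sd %.1f, seed %d\n",
              x$fiber_aspect, x$n_nuclei, x$n_artifacts, x$noise_sd, x$seed))
  invisible(x)
}

#' Serialize / restore a synthetic spec
#'
#' Flat JSON key-value round trip for \code{\link{synthetic_spec}} objects.
#' @param spec a \code{synthetic_spec}.
#' @param path file path.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_spec(shape_k = v$shape_k, scale_sigma = v$scale_sigma,
                 n_bundles = v$n_bundles, image_size = v$image_size,
                 stain_type = v$stain_type, fiber_aspect = v$fiber_aspect,
                 n_nuclei = v$n_nuclei, n_artifacts = v$n_artifacts,
                 noise_sd = v$noise_sd, seed = v$seed)
}

# 8-neighbourhood binary dilation of a logical matrix
dilate8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | p[2:(H + 1) + dr, 2:(W + 1) + dc]
  }
  out
}

# Rasterize one ribbon stroke with an exact pixel count.
# A thick random-walk path is stamped with disks of diameter `w`, then the
# pixel set is trimmed from the far end (or grown along the boundary) to hit
# `target` pixels exactly, so the truth area distribution is exactly the drawn
# one up to integer rounding.
make_ribbon <- function(target, aspect) {
  target <- max(1L, as.integer(round(target)))
  w <- max(1, sqrt(target / aspect))
  L <- max(1L, as.integer(ceiling(target / w * 1.25)) + 3L)
  side <- 2L * (L + as.integer(ceiling(w))) + 9L
  cx <- cy <- side / 2
  theta <- runif(1, 0, 2 * pi)
  dth <- rnorm(L, 0, 0.08)

  r <- w / 2
  rr <- floor(r)
  off <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]

  painted <- matrix(FALSE, side, side)
  ord <- matrix(Inf, side, side)
  for (s in seq_len(L)) {
    theta <- theta + dth[s]
    cy <- cy + sin(theta); cx <- cx + cos(theta)
    ri <- round(cy) + off$dr; ci <- round(cx) + off$dc
    keep <- ri >= 1 & ri <= side & ci >= 1 & ci <= side
    idx <- cbind(ri[keep], ci[keep])
    new <- !painted[idx]
    if (any(new)) {
      painted[idx[new, , drop = FALSE]] <- TRUE
      ord[idx[new, , drop = FALSE]] <- s
    }
  }
  cnt <- sum(painted)
  if (cnt > target) {
    wi <- which(painted)
    o <- order(ord[wi], wi, decreasing = TRUE)
    painted[wi[o[seq_len(cnt - target)]]] <- FALSE
  } else if (cnt < target) {
    while (cnt < target) {
      ring <- which(dilate8(painted) & !painted)
      if (length(ring) == 0) break
      take <- ring[seq_len(min(length(ring), target - cnt))]
      painted[take] <- TRUE
      cnt <- cnt + length(take)
    }
  }
  wi <- which(painted)
  rows <- (wi - 1L) %% side + 1L
  cols <- (wi - 1L) %/% side + 1L
  r0 <- min(rows); c0 <- min(cols)
  list(rows = rows - r0 + 1L, cols = cols - c0 + 1L,
       h = max(rows) - r0 + 1L, w_box = max(cols) - c0 + 1L,
       stroke_width = w, n_px = length(wi))
}

# axis-aligned ellipse pixel offsets around (0, 0)
ellipse_offsets <- function(ry, rx) {
  off <- expand.grid(dr = -ceiling(ry):ceiling(ry), dc = -ceiling(rx):ceiling(rx))
  off[(off$dr / ry)^2 + (off$dc / rx)^2 <= 1, , drop = FALSE]
}

# dart-throwing placement against an occupancy mask; <= 200 attempts.
# Returns the committed (row, col) offset or NULL.
place_shape <- function(occ, rows, cols, h, w_box, attempts = 200) {
  H <- nrow(occ); W <- ncol(occ)
  if (h > H || w_box > W) return(NULL)
  for (a in seq_len(attempts)) {
    r0 <- sample.int(H - h + 1L, 1L)
    c0 <- sample.int(W - w_box + 1L, 1L)
    idx <- (c0 + cols - 2L) * H + (r0 + rows - 1L)
    if (!any(occ[idx])) return(c(r0, c0))
  }
  NULL
}

#' Render a synthetic stained micrograph with ground truth
#'
#' Draws per-bundle areas from the GPD of the spec, rasterizes each bundle as
#' an elongated ribbon stroke whose pixel count equals the drawn area rounded
#' to the nearest pixel, and places bundles without contact by dart throwing
#' (at most 200 attempts per bundle; bundles that cannot be placed are
#' dropped and counted). Nuclei (ellipses) and artifact debris are placed
#' disjointly from the fibers, colors follow the stain palette, and Gaussian
#' noise is added and clipped to \eqn{[0, 255]}. Areas exceeding a quarter of
#' the canvas are rejected and redrawn.
#'
#' Rendering is a deterministic function of the spec: sub-seeds for areas,
#' shapes/placement, nuclei, artifacts and noise are derived from
#' \code{spec$seed}.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with elements
#'   \item{image}{a \code{\link{stain_image}};}
#'   \item{truth}{ground truth: logical \code{fiber_mask},
#'     \code{nucleus_mask}, \code{artifact_mask} (pairwise disjoint), the
#'     integer \code{bundle_labels} image, \code{bundle_areas} (the drawn GPD
#'     areas of the placed bundles), \code{stroke_widths}, and the counts
#'     \code{n_requested} / \code{n_placed}.}
#' @export
#' @examples
#' out <- render_micrograph(synthetic_spec(n_bundles = 10, scale_sigma = 40,
#'                                         image_size = c(128, 128), seed = 3))
#' sum(out$truth$fiber_mask)
render_micrograph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  cap <- 0.25 * H * W

  areas <- with_seed(derive_seed(spec$seed, 1), {
    a <- if (spec$n_bundles > 0) rgpd(spec$n_bundles, spec$shape_k, spec$scale_sigma)
         else numeric(0)
    for (it in seq_len(1000)) {
      bad <- a > cap
      if (!any(bad)) break
      a[bad] <- rgpd(sum(bad), spec$shape_k, spec$scale_sigma)
    }
    pmin(a, cap)
  })

  fiber <- matrix(FALSE, H, W)
  labels <- matrix(0L, H, W)
  occ <- matrix(FALSE, H, W)       # fiber + 1-px halo: keeps bundles 8-disjoint
  placed <- logical(length(areas))
  widths <- rep(NA_real_, length(areas))

  with_seed(derive_seed(spec$seed, 2), {
    for (b in order(areas, decreasing = TRUE)) {   # large first eases packing
      sh <- make_ribbon(areas[b], spec$fiber_aspect)
      at <- place_shape(occ, sh$rows, sh$cols, sh$h, sh$w_box)
      if (is.null(at)) next
      idx <- (at[2] + sh$cols - 2L) * H + (at[1] + sh$rows - 1L)
      fiber[idx] <- TRUE
      labels[idx] <- b
      loc <- matrix(FALSE, sh$h + 2L, sh$w_box + 2L)
      loc[cbind(sh$rows + 1L, sh$cols + 1L)] <- TRUE
      dil <- which(dilate8(loc) | loc)
      dr <- (dil - 1L) %% (sh$h + 2L) - 1L      # 0-based within halo box
      dc <- (dil - 1L) %/% (sh$h + 2L) - 1L
      rr <- at[1] + dr; cc <- at[2] + dc
      keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      occ[(cc[keep] - 1L) * H + rr[keep]] <- TRUE
      placed[b] <- TRUE
      widths[b] <- sh$stroke_width
    }
  })

  nucleus <- matrix(FALSE, H, W)
  occ2 <- occ | nucleus
  with_seed(derive_seed(spec$seed, 3), {
    for (i in seq_len(spec$n_nuclei)) {
      ry <- runif(1, 3, 6); rx <- ry * runif(1, 1.3, 2.2)
      off <- ellipse_offsets(ry, rx)
      rows <- off$dr - min(off$dr) + 1L; cols <- off$dc - min(off$dc) + 1L
      at <- place_shape(occ2, rows, cols, max(rows), max(cols))
      if (is.null(at)) next
      idx <- (at[2] + cols - 2L) * H + (at[1] + rows - 1L)
      nucleus[idx] <- TRUE
      loc <- matrix(FALSE, max(rows) + 2L, max(cols) + 2L)
      loc[cbind(rows + 1L, cols + 1L)] <- TRUE
      dil <- which(dilate8(loc) | loc)
      dr <- (dil - 1L) %% (max(rows) + 2L) - 1L
      dc <- (dil - 1L) %/% (max(rows) + 2L) - 1L
      rr <- at[1] + dr; cc <- at[2] + dc
      keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      occ2[(cc[keep] - 1L) * H + rr[keep]] <- TRUE
    }
  })

  artifact <- matrix(FALSE, H, W)
  occ3 <- occ2 | artifact
  with_seed(derive_seed(spec$seed, 4), {
    for (i in seq_len(spec$n_artifacts)) {
      sh <- make_ribbon(runif(1, 200, 800), 2)
      at <- place_shape(occ3, sh$rows, sh$cols, sh$h, sh$w_box)
      if (is.null(at)) next
      idx <- (at[2] + sh$cols - 2L) * H + (at[1] + sh$rows - 1L)
      artifact[idx] <- TRUE
      occ3[idx] <- TRUE
    }
  })

  pal <- stain_palette(spec$stain_type)
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(pal$background[ch], H, W)
    plane[fiber] <- pal$fiber[ch]
    plane[nucleus] <- pal$nucleus[ch]
    plane[artifact] <- pal$artifact[ch]
    img[, , ch] <- plane
  }
  if (spec$noise_sd > 0) {
    img <- with_seed(derive_seed(spec$seed, 5),
                     img + rnorm(length(img), 0, spec$noise_sd))
  }
  storage <- array(as.integer(pmin(pmax(round(img), 0), 255)), dim = c(H, W, 3))

  image <- stain_image(storage, stain_type = spec$stain_type,
                       label = sprintf("synthetic k=%.3g sigma=%.3g seed=%d",
                                       spec$shape_k, spec$scale_sigma, spec$seed))
  truth <- list(
    fiber_mask = fiber,
    nucleus_mask = nucleus,
    artifact_mask = artifact,
    bundle_labels = labels,
    bundle_areas = areas[placed],
    bundle_ids = which(placed),
    stroke_widths = widths[placed],
    n_requested = spec$n_bundles,
    n_placed = sum(placed)
  )
  list(image = image, truth = truth, spec = spec)
}

#' Exact geometric test fixtures
#'
#' Rasterizes a centered disk, bar or ring into a binary image; used to
#' validate the local thickness transform against analytic dimensions.
#'
#' @param kind \code{"disk"} (param \code{radius}), \code{"bar"} (params
#'   \code{width}, \code{length}) or \code{"ring"} (params \code{outer},
#'   \code{inner}).
#' @param params named list or vector of shape dimensions in pixels.
#' @param image_size \code{c(height, width)}.
#' @return logical matrix.
#' @export
#' @examples
#' sum(make_geometric_fixture("disk", list(radius = 20), c(128, 128)))
make_geometric_fixture <- function(kind = c("disk", "bar", "ring"), params,
                                   image_size = c(128, 128)) {
  kind <- match.arg(kind)
  params <- as.list(params)
  H <- image_size[1]; W <- image_size[2]
  cy <- ceiling(H / 2); cx <- ceiling(W / 2)   # integer pixel center
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- (rr - cy)^2 + (cc - cx)^2
  m <- switch(kind,
    disk = {
      r <- params$radius
      if (2 * r + 1 > min(H, W)) stop("disk does not fit in the canvas", call. = FALSE)
      d2 <= r^2
    },
    bar = {
      w <- params$width; len <- params$length
      if (w > H || len > W) stop("bar does not fit in the canvas", call. = FALSE)
      r0 <- floor((H - w) / 2) + 1; c0 <- floor((W - len) / 2) + 1
      rr >= r0 & rr <= r0 + w - 1 & cc >= c0 & cc <= c0 + len - 1
    },
    ring = {
      ro <- params$outer; ri <- params$inner
      if (ri >= ro) stop("'inner' must be smaller than 'outer'", call. = FALSE)
      if (2 * ro + 1 > min(H, W)) stop("ring does not fit in the canvas", call. = FALSE)
      d2 <= ro^2 & d2 > ri^2
    })
  m
}
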
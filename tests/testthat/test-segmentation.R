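white_image <- function(stain = "he", n = 64) {
  stain_image(array(250L, dim = c(n, n, 3)), stain_type = stain)
}

test_that("stain_image validates shape, depth and metadata", {
  expect_error(stain_image(matrix(0, 64, 64), "he"), "RGB")
  expect_error(stain_image(array(0L, c(16, 64, 3)), "he"), "32")
  expect_error(stain_image(array(300L, c(64, 64, 3)), "he"), "8-bit")
  expect_error(stain_image(array(10L, c(64, 64, 3)), "he", microns_per_pixel = -1),
               "positive")
  img <- white_image()
  expect_equal(dim(img), c(64L, 64L, 3L))
})

test_that("a uniform white image segments to pure background", {
  seg <- segment_stain(white_image())
  expect_equal(sum(seg$fiber_mask), 0)
  expect_true(all(seg$class_map == 0L))
})

test_that("profile/stain mismatch and malformed profiles are rejected", {
  expect_error(segment_stain(white_image("he"), default_stain_profile("mallory")),
               "mallory")
  expect_error(stain_profile("he",
                             fiber = list(h = c(0, 2), s = c(0, 1), v = c(0, 1)),
                             nucleus = list(h = c(0, 1), s = c(0, 1), v = c(0, 1))),
               "\\[0, 1\\]")
})

test_that("segmentation recovers the truth mask on noise-free renders of every stain", {
  for (st in stain_types()) {
    sp <- synthetic_spec(shape_k = 0.7, scale_sigma = 50, n_bundles = 40,
                         image_size = c(512, 512), stain_type = st,
                         noise_sd = 0, seed = 21)
    out <- render_micrograph(sp)
    seg <- segment_stain(out$image)
    expect_gte(iou(seg$fiber_mask, out$truth$fiber_mask), 0.90)
    # nuclei are never classified as fiber
    expect_equal(sum(seg$fiber_mask & out$truth$nucleus_mask), 0)
    # partition: class counts sum to the pixel count
    expect_equal(sum(tabulate(seg$class_map + 1L, 4)), prod(dim(seg$class_map)))
  }
})

test_that("re-segmenting a palette rendering of the class map reproduces it", {
  sp <- synthetic_spec(shape_k = 0.7, scale_sigma = 50, n_bundles = 30,
                       image_size = c(384, 384), noise_sd = 0, seed = 33,
                       stain_type = "mallory")
  out <- render_micrograph(sp)
  seg1 <- segment_stain(out$image)
  seg2 <- segment_stain(classmap_to_image(seg1, "mallory"))
  expect_identical(seg2$fiber_mask, seg1$fiber_mask)
})

test_that("widening the fiber color range never shrinks the raw fiber mask", {
  sp <- synthetic_spec(shape_k = 0.7, scale_sigma = 40, n_bundles = 30,
                       image_size = c(256, 256), noise_sd = 6, seed = 9)
  img <- render_micrograph(sp)$image
  base <- default_stain_profile("he")
  m0 <- segment_stain(img, base, cleanup = FALSE)$fiber_mask
  wide <- base
  wide$fiber$s <- c(max(0, base$fiber$s[1] - 0.15), min(1, base$fiber$s[2] + 0.1))
  wide$fiber$v <- c(max(0, base$fiber$v[1] - 0.15), min(1, base$fiber$v[2] + 0.04))
  m1 <- segment_stain(img, wide, cleanup = FALSE)$fiber_mask
  expect_true(all(m1[m0]))
})

test_that("overrides replace classes pixel-for-pixel and recompute the fiber mask", {
  sp <- synthetic_spec(shape_k = 0.7, scale_sigma = 50, n_bundles = 20,
                       image_size = c(256, 256), noise_sd = 0, seed = 12)
  out <- render_micrograph(sp)
  seg <- segment_stain(out$image)
  # all-sentinel override is the identity
  ov0 <- matrix(0L, 256, 256)
  expect_identical(apply_overrides(seg, ov0)$class_map, seg$class_map)
  # marking one bundle as artifact removes exactly its pixels from the mask
  comps <- label_components(seg$fiber_mask, min_area = 0)
  lab <- attr(comps, "labels")
  region <- lab == 1L
  ov <- matrix(0L, 256, 256); ov[region] <- 4L
  seg2 <- apply_overrides(seg, ov)
  expect_equal(sum(seg$fiber_mask) - sum(seg2$fiber_mask), sum(region))
  expect_true(all(seg2$class_map[region] == 3L))
  # adding a fiber square onto an empty segmentation
  empty <- segment_stain(white_image(n = 256))
  ov2 <- matrix(0L, 256, 256); ov2[101:110, 101:110] <- 2L
  expect_equal(sum(apply_overrides(empty, ov2)$fiber_mask), 100)
  expect_error(apply_overrides(seg, matrix(0L, 10, 10)), "shape")
  expect_error(apply_overrides(seg, matrix(9L, 256, 256)), "codes")
})

test_that("override masks round-trip through single-channel PNG codes", {
  ov <- matrix(0L, 40, 40); ov[3:6, 3:6] <- 2L; ov[10, 10] <- 4L
  f <- tempfile(fileext = ".png")
  png::writePNG(ov / 255, f)
  expect_identical(read_override_mask(f), ov)
})

test_that("component labeling is 8-connected with area filtering and deterministic order", {
  m <- matrix(FALSE, 32, 32); m[5:14, 5:14] <- TRUE
  tb <- label_components(m, min_area = 0)
  expect_equal(nrow(tb), 1)
  expect_equal(tb$area_px, 100)
  expect_equal(tb$centroid_row, 9.5)
  # corner contact joins components
  m2 <- matrix(FALSE, 8, 8); m2[2:3, 2:3] <- TRUE; m2[4:5, 4:5] <- TRUE
  expect_equal(nrow(label_components(m2, 0)), 1)
  # 50 disjoint squares of areas 4 and 9 alternating; min_area 5 keeps the 25 nines
  m3 <- matrix(FALSE, 40, 250)
  for (i in 0:49) {
    c0 <- 2 + i * 5
    if (i %% 2 == 0) m3[2:3, c0:(c0 + 1)] <- TRUE else m3[2:4, c0:(c0 + 2)] <- TRUE
  }
  expect_equal(nrow(label_components(m3, min_area = 0)), 50)
  tb3 <- label_components(m3, min_area = 5)
  expect_equal(nrow(tb3), 25)
  expect_true(all(tb3$area_px == 9))
  # ties in area break by top-left-most pixel in row-major order
  expect_true(all(diff(tb3$centroid_col) > 0))
  # empty mask
  expect_equal(nrow(label_components(matrix(FALSE, 5, 5), 0)), 0)
})

test_that("images, masks and class maps round-trip through PNG and TIFF", {
  sp <- synthetic_spec(n_bundles = 8, scale_sigma = 30, image_size = c(64, 64),
                       noise_sd = 5, seed = 4)
  img <- render_micrograph(sp)$image
  fp <- tempfile(fileext = ".png"); ft <- tempfile(fileext = ".tif")
  write_stain_image(img, fp); write_stain_image(img, ft)
  expect_identical(read_stain_image(fp, "he")$pixels, img$pixels)
  expect_identical(read_stain_image(ft, "he")$pixels, img$pixels)
  m <- matrix(FALSE, 64, 64); m[10:20, 30:40] <- TRUE
  fm <- tempfile(fileext = ".png")
  write_mask_png(m, fm)
  expect_identical(read_mask_png(fm), m)
  seg <- segment_stain(img)
  fc <- tempfile(fileext = ".png")
  write_class_map_png(seg, fc)
  arr <- png::readPNG(fc)
  expect_identical(arr[, , 1] == 1 & arr[, , 2] == 0, seg$class_map == 1L)
})
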
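test_that("area fraction is exact on analytic masks and symmetric under inversion", {
  expect_equal(area_fraction(matrix(TRUE, 10, 10)), 100)
  expect_equal(area_fraction(matrix(FALSE, 10, 10)), 0)
  m <- matrix(FALSE, 1024, 1024); m[1:512, 1:512] <- TRUE
  expect_equal(area_fraction(m), 25)
  expect_error(area_fraction(matrix(logical(0), 0, 0)), "zero")
  # rotation invariance and complement symmetry on random masks
  set.seed(3)
  for (i in 1:3) {
    r <- matrix(runif(64 * 48) < 0.4, 64, 48)
    f <- area_fraction(r)
    expect_equal(area_fraction(t(r)[ncol(r):1, ]), f)        # 90 degrees
    expect_equal(area_fraction(r[64:1, 48:1]), f)            # 180 degrees
    expect_equal(f + area_fraction(!r), 100)
  }
})

test_that("local thickness matches analytic values on geometric fixtures", {
  d <- make_geometric_fixture("disk", list(radius = 20), c(128, 128))
  expect_lte(abs(max(local_thickness(d)) - 40), 1)
  b <- make_geometric_fixture("bar", list(width = 10, length = 100), c(128, 128))
  tb <- local_thickness(b)
  expect_lte(abs(tb[64, 64] - 10), 1)
  expect_lte(abs(max(tb) - 10), 1)
  r <- make_geometric_fixture("ring", list(outer = 30, inner = 20), c(128, 128))
  expect_lte(abs(max(local_thickness(r)) - 10), 1)
  expect_equal(local_thickness(matrix(FALSE, 16, 16)), matrix(0, 16, 16))
})

test_that("local thickness equals the brute-force inscribed-disk oracle exactly", {
  set.seed(7)
  for (i in 1:3) {
    m <- matrix(runif(64 * 64) < 0.55, 64, 64)
    expect_identical(local_thickness(m), bf_local_thickness(m))
  }
  # also on a structured mask
  m2 <- make_geometric_fixture("disk", list(radius = 9), c(48, 48)) |
        make_geometric_fixture("bar", list(width = 3, length = 40), c(48, 48))
  expect_identical(local_thickness(m2), bf_local_thickness(m2))
})

test_that("local thickness dominates twice the distance transform, equal at disk centers", {
  set.seed(21)
  m <- matrix(runif(80 * 60) < 0.6, 80, 60)
  tm <- local_thickness(m)
  edt2 <- 2 * sqrt(ecmorph:::edt_sq_cpp(m))
  # every pixel is covered at least by the inscribed disk centered on itself,
  # so the thickness is >= 2*EDT, with equality exactly at disk centers
  expect_true(all(tm[m] >= edt2[m] - 1e-9))
  expect_equal(max(tm), max(edt2))
  expect_true(all(tm[!m] == 0))
  expect_lte(max(tm), min(dim(m)))
  d <- make_geometric_fixture("disk", list(radius = 12), c(64, 64))
  td <- local_thickness(d)
  center <- which(ecmorph:::edt_sq_cpp(d) == max(ecmorph:::edt_sq_cpp(d)))[1]
  expect_equal(td[center], 2 * sqrt(max(ecmorph:::edt_sq_cpp(d))))
})

test_that("per-bundle max widths and widest-point markers are recovered", {
  m <- matrix(FALSE, 80, 200)
  m[10:19, 10:150] <- TRUE    # bar width 10
  m[40:69, 10:150] <- TRUE    # bar width 30
  comps <- label_components(m, 0)
  tmap <- local_thickness(m)
  out <- max_bundle_width(tmap, comps)
  w <- sort(out$components$max_thickness)
  expect_lte(abs(w[1] - 10), 1)
  expect_lte(abs(w[2] - 30), 1)
  expect_lte(abs(max(out$components$max_thickness) - 30), 1)
  # markers sit on the pixels attaining each component max
  lab <- attr(comps, "labels")
  for (id in comps$component_id) {
    mx <- out$components$max_thickness[id]
    expect_true(all(tmap[out$markers & lab == id] == mx))
  }
  expect_error(max_bundle_width(tmap[1:10, 1:10], comps), "shape")
})

test_that("synthetic ribbon widths are recovered within 2 px", {
  sp <- synthetic_spec(shape_k = 0.3, scale_sigma = 500, n_bundles = 12,
                       image_size = c(768, 768), fiber_aspect = 6,
                       noise_sd = 0, seed = 17, n_nuclei = 0, n_artifacts = 0)
  tr <- render_micrograph(sp)$truth
  tmap <- local_thickness(tr$fiber_mask)
  for (i in seq_along(tr$bundle_ids)) {
    rec <- max(tmap[tr$bundle_labels == tr$bundle_ids[i]])
    expect_lte(abs(rec - tr$stroke_widths[i]), 2)
  }
})

test_that("mean/CI summary matches the Student-t oracle", {
  s <- summarize_mean_ci(rep(50, 8))
  expect_equal(s$mean, 50)
  expect_equal(diff(s$ci95), 0)
  s2 <- summarize_mean_ci(c(40, 50, 60))
  expect_equal(s2$mean, 50)
  # t(0.975, df = 2) = 4.3027, sd = 10
  expect_equal(s2$ci95, 50 + c(-1, 1) * 4.3027 * 10 / sqrt(3), tolerance = 1e-4)
  expect_error(summarize_mean_ci(5), "at least 2")
})

test_that("area histograms bin right-open with a closed last bin", {
  h1 <- component_area_histogram(c(1, 1, 1), 2)
  expect_equal(h1$counts, 3L)
  expect_equal(h1$bin_edges, c(0, 2))
  h2 <- component_area_histogram(c(1, 3, 5), 2)
  expect_equal(h2$counts, c(1L, 1L, 1L))
  # boundary values: right-open except the last edge, which is closed
  h3 <- component_area_histogram(c(2, 4), 2)
  expect_equal(h3$bin_edges, c(0, 2, 4))
  expect_equal(h3$counts, c(0L, 2L))
  h4 <- component_area_histogram(c(2, 4, 5), 2)
  expect_equal(h4$counts, c(0L, 1L, 2L))
  expect_equal(length(h4$bin_edges), length(h4$counts) + 1)
  h0 <- component_area_histogram(numeric(0), 2)
  expect_equal(length(h0$counts), 0)
  # permutation invariance
  x <- c(0.5, 7, 3.2, 11, 2, 2)
  expect_equal(component_area_histogram(x, 2.5)$counts,
               component_area_histogram(rev(x), 2.5)$counts)
})

test_that("histogram totals and tail mass agree with the GPD quantile oracle", {
  x <- sample_gpd(0.7, 2, 1e4, seed = 78)
  h <- component_area_histogram(x, 1)
  expect_equal(sum(h$counts), 1e4)
  q99 <- qgpd(0.99, 0.7, 2)
  tail_frac <- mean(x > q99)
  half <- 1.96 * sqrt(0.01 * 0.99 / 1e4)
  expect_gt(tail_frac, 0.01 - half)
  expect_lt(tail_frac, 0.01 + half)
})
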
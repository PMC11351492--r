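# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / enumeration, independent of the package internals.

# Brute-force local thickness: enumerate every foreground center, compute its
# largest inscribed-disk radius by scanning all background pixels (canvas
# border counts as background), then take, at each pixel, the maximum diameter
# over all disks containing it. Integer squared distances throughout.
bf_local_thickness <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)
  fg <- which(mask)
  if (length(fg) == 0) return(out)
  fr <- (fg - 1L) %% H + 1L
  fc <- (fg - 1L) %/% H + 1L
  bg <- which(!mask)
  br <- (bg - 1L) %% H + 1L
  bc <- (bg - 1L) %/% H + 1L
  # squared distance to nearest background pixel or outside-the-canvas pixel
  R2 <- vapply(seq_along(fg), function(i) {
    dists <- if (length(bg)) (br - fr[i])^2 + (bc - fc[i])^2 else Inf
    border <- min(fr[i], H + 1 - fr[i], fc[i], W + 1 - fc[i])^2
    min(dists, border)
  }, numeric(1))
  for (i in seq_along(fg)) {
    d2 <- (fr - fr[i])^2 + (fc - fc[i])^2
    cover <- fg[d2 <= R2[i]]
    val <- 2 * sqrt(R2[i])
    out[cover] <- pmax(out[cover], val)
  }
  out
}

# Coarse-to-fine grid search for the GPD MLE: coarse grid over the stated
# (k, sigma) box, then a 1e-3 grid around the coarse optimum.
grid_fit_gpd <- function(x, k_range = c(-0.5, 2), s_range = c(0.1, 10)) {
  eval_grid <- function(ks, ss) {
    ll <- matrix(-Inf, length(ks), length(ss))
    for (i in seq_along(ks)) for (j in seq_along(ss))
      ll[i, j] <- gpd_loglik(ks[i], ss[j], x)
    w <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    c(k = ks[w[1]], s = ss[w[2]], ll = max(ll))
  }
  co <- eval_grid(seq(k_range[1], k_range[2], by = 0.01),
                  seq(s_range[1], s_range[2], by = 0.05))
  fi <- eval_grid(seq(max(k_range[1], co["k"] - 0.02), co["k"] + 0.02, by = 0.001),
                  seq(max(s_range[1], co["s"] - 0.1), co["s"] + 0.1, by = 0.001))
  fi
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# seeded evaluation without disturbing the suite's RNG stream
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# re-render a class map in a stain's flat palette (background white-ish),
# used for the segmentation idempotence check
classmap_to_image <- function(seg, stain) {
  pal <- ecmorph::stain_palette(stain)
  cm <- seg$class_map
  px <- array(0L, dim = c(nrow(cm), ncol(cm), 3))
  for (ch in 1:3) {
    plane <- matrix(pal$background[ch], nrow(cm), ncol(cm))
    plane[cm == 1L] <- pal$fiber[ch]
    plane[cm == 2L] <- pal$nucleus[ch]
    plane[cm == 3L] <- pal$artifact[ch]
    px[, , ch] <- as.integer(plane)
  }
  ecmorph::stain_image(px, stain_type = stain)
}
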
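#' Configuration for a batch dermis analysis run
#'
#' @param manifest path to a manifest CSV with columns
#'   \code{path,stain,year,label,sample_id}, or an equivalent data frame.
#' @param out_dir output directory (created if missing); \code{NULL} disables
#'   file output.
#' @param min_area minimum bundle area kept (pixel^2).
#' @param bin_width area histogram bin width (pixel^2).
#' @param k_threshold regime discriminant on the GPD shape.
#' @param profiles named list of \code{\link{stain_profile}} overrides, keyed
#'   by stain type.
#' @param compute_width compute local thickness and bundle widths.
#' @param include_silver include silver-impregnation fits in the pooled
#'   separating-threshold computation (excluded by default: its aging trend
#'   runs opposite to the collagen/elastic stains).
#' @param min_fit_n minimum number of bundles for a GPD fit.
#' @param seed seed for any stochastic diagnostics.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(manifest, out_dir = NULL, min_area = 10, bin_width = 5,
                       k_threshold = k_threshold_default, profiles = list(),
                       compute_width = TRUE, include_silver = FALSE,
                       min_fit_n = 30, seed = 1) {
  structure(list(manifest = manifest, out_dir = out_dir, min_area = min_area,
                 bin_width = bin_width, k_threshold = k_threshold,
                 profiles = profiles, compute_width = compute_width,
                 include_silver = include_silver, min_fit_n = min_fit_n,
                 seed = seed),
            class = "run_config")
}

read_manifest <- function(manifest) {
  df <- if (is.data.frame(manifest)) manifest else read.csv(manifest,
                                                            stringsAsFactors = FALSE)
  need <- c("path", "stain", "year", "label", "sample_id")
  miss <- setdiff(need, names(df))
  if (nrow(df) > 0 && length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) > 0 && !all(df$stain %in% stain_types()))
    stop("manifest contains unsupported stain types", call. = FALSE)
  df
}

process_image_row <- function(row, config) {
  img <- read_stain_image(row$path, stain_type = row$stain, label = row$label)
  prof <- config$profiles[[row$stain]]
  if (is.null(prof)) prof <- default_stain_profile(row$stain)
  seg <- segment_stain(img, prof)
  afrac <- area_fraction(seg)
  comps <- label_components(seg$fiber_mask, min_area = config$min_area)

  widths <- NULL
  if (config$compute_width && nrow(comps) > 0) {
    tmap <- local_thickness(seg$fiber_mask)
    comps <- max_bundle_width(tmap, comps)$components
    widths <- comps$max_thickness
  }

  fit <- NULL; regime <- NULL; fit_flag <- "ok"
  if (afrac == 0 || nrow(comps) == 0) {
    fit_flag <- "empty_fiber_mask"
  } else if (nrow(comps) < config$min_fit_n) {
    fit_flag <- sprintf("too_few_bundles (%d < %d)", nrow(comps), config$min_fit_n)
  } else {
    fit <- suppressWarnings(fit_gpd(comps$area_px, keep_data = FALSE))
    regime <- classify_by_k(fit, config$k_threshold)
  }

  list(label = row$label, stain = row$stain, year = row$year,
       sample_id = row$sample_id, area_fraction_pct = afrac,
       n_bundles = nrow(comps), areas = comps$area_px, widths = widths,
       max_width_px = if (length(widths)) max(widths) else NA_real_,
       histogram = component_area_histogram(comps, config$bin_width),
       fit = fit, regime = regime, fit_flag = fit_flag, error = NULL)
}

#' Run the full dermis analysis pipeline
#'
#' Executes segmentation, morphometry and GPD tail modeling over every image
#' of a manifest: per-image ECM area fraction, bundle table, maximum bundle
#' widths via local thickness, bundle-area histogram, GPD fit with regime
#' call, and -- across year groups -- the separating threshold on the fitted
#' shape values. Per-image failures are recorded without aborting the batch.
#' When \code{out_dir} is set, writes \code{report.json},
#' \code{area_fractions.csv}, \code{bundle_widths.csv}, \code{gpd_fits.csv}
#' and figure PNGs; outputs are deterministic functions of inputs and
#' configuration.
#'
#' @param config a \code{\link{run_config}}.
#' @return object of class \code{run_report}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- read_manifest(config$manifest)
  images <- list()
  if (nrow(manifest) > 0) {
    for (i in seq_len(nrow(manifest))) {
      row <- manifest[i, ]
      res <- tryCatch(process_image_row(row, config), error = function(e) {
        list(label = row$label, stain = row$stain, year = row$year,
             sample_id = row$sample_id, area_fraction_pct = NA_real_,
             n_bundles = NA_integer_, areas = numeric(0), widths = NULL,
             max_width_px = NA_real_, histogram = NULL, fit = NULL,
             regime = NULL, fit_flag = "error", error = conditionMessage(e))
      })
      images[[i]] <- res
    }
  }

  fitted <- Filter(function(x) !is.null(x$fit), images)
  pool <- if (config$include_silver) fitted
          else Filter(function(x) x$stain != "silver", fitted)
  years <- sort(unique(vapply(pool, `[[`, numeric(1), "year")))
  thr <- NULL
  if (length(years) == 2) {
    ks <- lapply(years, function(y)
      vapply(Filter(function(x) x$year == y, pool),
             function(x) unname(coef(x$fit)["shape"]), numeric(1)))
    thr <- separating_threshold(ks[[1]], ks[[2]])
  }

  width_summary <- summarize_widths(images)

  report <- structure(list(images = images, threshold = thr,
                           width_summary = width_summary,
                           k_threshold = config$k_threshold,
                           config = config),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# per-year width summaries; widths normalized to the overall maximum (x100)
summarize_widths <- function(images) {
  with_w <- Filter(function(x) length(x$widths) > 0, images)
  if (length(with_w) == 0) return(NULL)
  all_w <- unlist(lapply(with_w, `[[`, "widths"))
  gmax <- max(all_w)
  years <- sort(unique(vapply(with_w, `[[`, numeric(1), "year")))
  do.call(rbind, lapply(years, function(y) {
    w <- unlist(lapply(Filter(function(x) x$year == y, with_w), `[[`, "widths"))
    pct <- 100 * w / gmax
    s <- if (length(pct) >= 2) summarize_mean_ci(pct)
         else list(n = length(pct), mean = mean(pct), ci95 = c(NA_real_, NA_real_))
    data.frame(year = y, n_bundles = length(w), mean_width_pct = s$mean,
               width_lo = s$ci95[1], width_hi = s$ci95[2],
               max_width_px = max(w))
  }))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("dermis analysis report: %d image(s)\n", length(x$images)))
  for (im in x$images) {
    if (!is.null(im$error)) {
      cat(sprintf("  %s [%s %s]: ERROR %s\n", im$label, im$stain, im$year, im$error))
    } else {
      k <- if (!is.null(im$fit)) sprintf("k=%.4f (%s)", coef(im$fit)["shape"],
                                         im$regime$call) else im$fit_flag
      cat(sprintf("  %s [%s %s]: ECM %.1f%%, %d bundles, %s\n",
                  im$label, im$stain, im$year, im$area_fraction_pct,
                  im$n_bundles, k))
    }
  }
  if (!is.null(x$threshold)) print(x$threshold)
  invisible(x)
}

fit_record <- function(im) {
  f <- im$fit
  data.frame(label = im$label, stain = im$stain, year = im$year,
             n = f$n, k = unname(coef(f)["shape"]),
             k_lo = f$ci["shape", 1], k_hi = f$ci["shape", 2],
             sigma = unname(coef(f)["scale"]),
             sigma_lo = f$ci["scale", 1], sigma_hi = f$ci["scale", 2],
             loglik = f$loglik, regime = im$regime$call)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- report$images

  af <- do.call(rbind, lapply(imgs, function(im)
    data.frame(label = im$label, stain = im$stain, year = im$year,
               area_fraction_pct = im$area_fraction_pct)))
  if (is.null(af)) af <- data.frame(label = character(0), stain = character(0),
                                    year = numeric(0),
                                    area_fraction_pct = numeric(0))
  write.csv(af, file.path(out_dir, "area_fractions.csv"), row.names = FALSE)

  fits <- do.call(rbind, lapply(Filter(function(x) !is.null(x$fit), imgs),
                                fit_record))
  if (is.null(fits)) fits <- data.frame(label = character(0))
  write.csv(fits, file.path(out_dir, "gpd_fits.csv"), row.names = FALSE)

  ws <- report$width_summary
  if (is.null(ws)) ws <- data.frame(year = numeric(0))
  write.csv(ws, file.path(out_dir, "bundle_widths.csv"), row.names = FALSE)

  js <- list(
    k_threshold = report$k_threshold,
    images = lapply(imgs, function(im) {
      rec <- list(label = im$label, stain = im$stain, year = im$year,
                  area_fraction_pct = im$area_fraction_pct,
                  n_bundles = im$n_bundles, max_width_px = im$max_width_px,
                  fit_flag = im$fit_flag)
      if (!is.null(im$error)) rec$error <- im$error
      if (!is.null(im$fit)) {
        f <- im$fit
        rec$gpd <- list(k = unname(coef(f)["shape"]),
                        k_ci = unname(f$ci["shape", ]),
                        sigma = unname(coef(f)["scale"]),
                        sigma_ci = unname(f$ci["scale", ]),
                        loglik = f$loglik, n = f$n,
                        regime_call = im$regime$call)
      }
      rec
    }),
    threshold = if (!is.null(report$threshold)) unclass(report$threshold)
  )
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  plot_outputs(report, out_dir)
  invisible(out_dir)
}

safe_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Figures for a pipeline report
#'
#' Writes the report's standard figures: a per-year histogram of bundle
#' widths, one bundle-area histogram per image with the fitted GPD density
#' overlaid, and a shape-scale scatter in which each fit is a rectangle
#' spanning its confidence intervals, with the regime threshold as a vertical
#' line.
#'
#' @param report a \code{\link{run_pipeline}} report.
#' @param out_dir directory for the PNG files.
#' @return invisibly, the written file paths.
#' @export
plot_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  imgs <- report$images

  with_w <- Filter(function(x) length(x$widths) > 0, imgs)
  if (length(with_w) > 0 || length(imgs) > 0) {
    f <- file.path(out_dir, "fig_width_hist.png")
    grDevices::png(f, 800, 500)
    years <- sort(unique(vapply(with_w, `[[`, numeric(1), "year")))
    if (length(years) == 0) {
      plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "bundle width (px)",
           ylab = "count", main = "Bundle widths")
    } else {
      all_w <- unlist(lapply(with_w, `[[`, "widths"))
      br <- pretty(c(0, all_w), 20)
      cols <- c("#2c7fb890", "#d7191c90")
      h1 <- hist(unlist(lapply(Filter(function(x) x$year == years[1], with_w),
                               `[[`, "widths")), breaks = br, plot = FALSE)
      ylim <- c(0, max(h1$counts))
      if (length(years) > 1) {
        h2 <- hist(unlist(lapply(Filter(function(x) x$year == years[2], with_w),
                                 `[[`, "widths")), breaks = br, plot = FALSE)
        ylim <- c(0, max(h1$counts, h2$counts))
      }
      plot(h1, col = cols[1], xlab = "bundle width (px)",
           main = "Bundle widths by year", ylim = ylim)
      if (length(years) > 1) plot(h2, col = cols[2], add = TRUE)
      legend("topright", legend = years, fill = cols[seq_along(years)])
    }
    dev.off()
    files <- c(files, f)
  }

  for (im in imgs) {
    if (is.null(im$histogram) || length(im$histogram$counts) == 0) next
    f <- file.path(out_dir, sprintf("fig_areas_%s.png", safe_name(im$label)))
    grDevices::png(f, 700, 500)
    hg <- im$histogram
    mids <- (hg$bin_edges[-1] + hg$bin_edges[-length(hg$bin_edges)]) / 2
    wdt <- diff(hg$bin_edges[1:2])
    dens <- hg$counts / (sum(hg$counts) * wdt)
    plot(mids, dens, type = "h", lwd = 4, col = "grey50",
         xlab = "bundle area (px^2)", ylab = "density",
         main = sprintf("%s: bundle areas + GPD fit", im$label))
    if (!is.null(im$fit)) {
      est <- coef(im$fit)
      xs <- seq(0, max(hg$bin_edges), length.out = 400)
      lines(xs, dgpd(xs, est["shape"], est["scale"]), col = "red3", lwd = 2)
    }
    dev.off()
    files <- c(files, f)
  }

  fitted <- Filter(function(x) !is.null(x$fit), imgs)
  if (length(fitted) > 0) {
    f <- file.path(out_dir, "fig_k_sigma.png")
    grDevices::png(f, 700, 500)
    ks <- t(vapply(fitted, function(im) c(coef(im$fit), im$fit$ci["shape", ],
                                          im$fit$ci["scale", ]), numeric(6)))
    plot(NA, xlim = range(ks[, 3:4]), ylim = range(ks[, 5:6]),
         xlab = "shape k", ylab = "scale sigma",
         main = "GPD fits (CI rectangles)")
    yrs <- vapply(fitted, `[[`, numeric(1), "year")
    cols <- c("#2c7fb8", "#d7191c")[as.integer(factor(yrs))]
    for (i in seq_len(nrow(ks)))
      rect(ks[i, 3], ks[i, 5], ks[i, 4], ks[i, 6], border = cols[i], lwd = 2)
    points(ks[, 1], ks[, 2], pch = 19, col = cols)
    abline(v = report$k_threshold, lty = 2)
    if (length(unique(yrs)) > 1)
      legend("topright", legend = sort(unique(yrs)),
             col = c("#2c7fb8", "#d7191c"), lwd = 2)
    dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
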
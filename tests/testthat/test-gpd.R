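test_that("GPD density, CDF and quantiles are mutually consistent and integrate to 1", {
  set.seed(11)
  for (i in 1:6) {
    k <- runif(1, -0.3, 1.2)
    s <- runif(1, 0.5, 5)
    # quadrature: density mass up to the 0.999 quantile is 0.999
    upper <- qgpd(0.999, k, s)
    q <- integrate(dgpd, 0, upper, shape = k, scale = s,
                   rel.tol = 1e-9, subdivisions = 500L)
    expect_lt(abs(q$value - 0.999), 1e-4)
    # quantile inverts CDF
    p <- c(0.01, 0.5, 0.9, 0.999)
    expect_equal(pgpd(qgpd(p, k, s), k, s), p, tolerance = 1e-10)
  }
})

test_that("log-likelihood matches closed-form values and the -Inf support sentinel", {
  expect_equal(gpd_loglik(0, 1, 1), -1)
  expect_equal(gpd_loglik(1, 1, 1), -2 * log(2))
  # exponential limit kicks in below 1e-8
  expect_equal(gpd_loglik(1e-12, 2, c(1, 3)), -2 * log(2) - 4 / 2)
  # negative shape bounded support: x beyond -sigma/k
  expect_identical(gpd_loglik(-0.5, 1, c(0.5, 3)), -Inf)
  expect_identical(gpd_loglik(0.5, 1, c(-1, 2)), -Inf)
  expect_error(gpd_loglik(0.5, -1, 1), "positive")
})

test_that("sample_gpd is seeded, matches analytic moments and the stated CDF", {
  expect_identical(sample_gpd(0.5, 2, 0, seed = 1), numeric(0))
  x0 <- sample_gpd(0, 2, 1e6, seed = 7)
  expect_lt(abs(mean(x0) - 2) / 2, 0.01)       # exponential mean = sigma
  x1 <- sample_gpd(0.5, 2, 1e6, seed = 7)
  expect_lt(abs(mean(x1) - 4) / 4, 0.02)       # sigma/(1-k) = 4
  expect_identical(sample_gpd(0.5, 2, 50, seed = 3), sample_gpd(0.5, 2, 50, seed = 3))
  expect_error(sample_gpd(0.5, 0, 10), "positive")
  # Kolmogorov-Smirnov distance against the stated survival function
  for (par in list(c(0, 1), c(0.7, 2.4), c(1.11, 3.5), c(-0.2, 1))) {
    x <- sample_gpd(par[1], par[2], 1e5, seed = 13)
    xs <- sort(x)
    Fx <- pgpd(xs, par[1], par[2])
    i <- seq_along(xs)
    D <- max(pmax(i / 1e5 - Fx, Fx - (i - 1) / 1e5))
    expect_lt(D, 0.01)
  }
})

test_that("MLE agrees with a brute-force grid search on a fixed sample", {
  x <- sample_gpd(0.6, 1.8, 200, seed = 101)
  fit <- suppressWarnings(fit_gpd(x))
  g <- grid_fit_gpd(x)
  expect_lt(abs(coef(fit)["shape"] - g["k"]), 2e-3)
  expect_lt(abs(coef(fit)["scale"] - g["s"]), 2e-3)
  # the MLE log-likelihood dominates every grid point
  expect_gte(fit$loglik, g["ll"] - 1e-6)
})

test_that("fitting recovers the exponential nested limit on exponential data", {
  x <- sample_gpd(0, 3, 1e6, seed = 5)
  fit <- fit_gpd(x, keep_data = FALSE)
  expect_lt(abs(coef(fit)["shape"]), 0.01)
  expect_lt(abs(coef(fit)["scale"] - 3) / 3, 0.01)
})

test_that("fit is scale-equivariant and its implied mean matches the sample mean", {
  x <- sample_gpd(0.7, 2, 5000, seed = 23)
  f1 <- fit_gpd(x, keep_data = FALSE)
  f2 <- fit_gpd(100 * x, keep_data = FALSE)
  expect_equal(unname(coef(f2)["shape"]), unname(coef(f1)["shape"]), tolerance = 1e-6)
  expect_equal(unname(coef(f2)["scale"]), unname(100 * coef(f1)["scale"]),
               tolerance = 1e-6)
  # for k < 1: sigma-hat/(1 - k-hat) -> sample mean
  y <- sample_gpd(0.6, 2.5, 1e6, seed = 29)
  f <- fit_gpd(y, keep_data = FALSE)
  implied <- coef(f)["scale"] / (1 - coef(f)["shape"])
  expect_lt(abs(implied - mean(y)) / mean(y), 0.02)
})

test_that("parameter recovery holds across the reference envelope corners", {
  ref <- reference_gpd_fits()
  corners <- expand.grid(k = range(ref$shape_k), s = range(ref$scale_sigma))
  for (i in seq_len(nrow(corners))) {
    x <- sample_gpd(corners$k[i], corners$s[i], 1e5, seed = 300 + i)
    f <- fit_gpd(x, keep_data = FALSE)
    expect_lt(abs(coef(f)["shape"] - corners$k[i]), 0.03)
    expect_lt(abs(coef(f)["scale"] - corners$s[i]) / corners$s[i], 0.02)
  }
})

test_that("fit_gpd validates its input", {
  expect_error(fit_gpd(c(1)), "at least 2")
  expect_error(fit_gpd(c(1, -2, 3)), "positive")
  expect_warning(fit_gpd(sample_gpd(0.5, 2, 50, seed = 1)), "fewer than 100")
})

test_that("confidence intervals contain the point estimate; profile CIs are close to Wald at large n", {
  x <- sample_gpd(0.7, 2, 4000, seed = 31)
  fit <- fit_gpd(x)
  expect_true(fit$ci["shape", 1] < coef(fit)["shape"] &&
              coef(fit)["shape"] < fit$ci["shape", 2])
  expect_true(fit$ci["scale", 1] < coef(fit)["scale"] &&
              coef(fit)["scale"] < fit$ci["scale", 2])
  pr <- confint(fit, method = "profile")
  wa <- confint(fit, method = "wald")
  expect_equal(unname(pr), unname(wa), tolerance = 0.05)
})

test_that("gpd_fit methods behave as a standard model object", {
  x <- sample_gpd(0.7, 2.4, 1000, seed = 41)
  fit <- fit_gpd(x)
  expect_s3_class(fit, "gpd_fit")
  expect_named(coef(fit), c("shape", "scale"))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 2L)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(AIC(fit), 4 - 2 * fit$loglik)
  V <- vcov(fit)
  expect_true(all(diag(V) > 0))
  sims <- simulate(fit, nsim = 3, seed = 1, n = 10)
  expect_length(sims, 3)
  expect_length(sims[[1]], 10)
  # Cox-Snell residuals are approximately Exp(1)
  r <- residuals(fit)
  expect_lt(abs(mean(r) - 1), 0.15)
  expect_equal(predict(fit, 0.5, type = "quantile"),
               qgpd(0.5, coef(fit)["shape"], coef(fit)["scale"]))
  expect_output(print(fit), "shape k")
  expect_output(print(summary(fit)), "log-likelihood")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); dev.off()
  expect_true(file.exists(tf))
})
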
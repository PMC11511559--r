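test_that("band power isolates the driving frequency", {
  fs <- 250
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  expect_equal(band_power_welch(numeric(fs * 4), fs, c(8, 12)), 0)

  x <- sin(2 * pi * 10 * t)
  mu <- band_power_welch(x, fs, c(8, 12))
  beta <- band_power_welch(x, fs, c(13, 30))
  expect_gt(mu, 50 * beta)

  # periodogram oracle on the same signal: peak bin at 10 Hz
  sp <- stats::spec.pgram(ts(x, frequency = fs), plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 10, tolerance = 0.01)
})

test_that("white-noise band power integrates to the signal variance", {
  set.seed(31)
  fs <- 250
  x <- rnorm(fs * 8)
  total <- band_power_welch(x, fs, c(0.5, fs / 2))
  expect_equal(total, var(x), tolerance = 0.1)
})

test_that("Hjorth parameters match first-difference brute force", {
  fs <- 1000
  f <- 2
  x <- sin(2 * pi * f * seq_len(5000) / fs)
  h <- hjorth_params(x)
  # brute-force oracle: direct variance of differences
  mob_oracle <- sqrt(var(diff(x)) / var(x))
  expect_equal(h[["mobility"]], mob_oracle, tolerance = 1e-9)
  expect_equal(h[["mobility"]], 2 * pi * f / fs, tolerance = 1e-3)
  expect_equal(h[["complexity"]], 1, tolerance = 1e-3)
  expect_equal(h[["activity"]], var(x), tolerance = 1e-12)

  expect_warning(hc <- hjorth_params(rep(2, 10)), "constant")
  expect_equal(hc[["activity"]], 0)
  expect_true(is.na(hc[["mobility"]]) && is.na(hc[["complexity"]]))
})

test_that("AR(4) coefficients are recovered from self-simulated data", {
  phi <- c(0.5, -0.3, 0.2, -0.1)
  set.seed(32)
  x <- as.numeric(arima.sim(list(ar = phi), n = 10000))
  est <- ar_coefficients(x, 4)
  expect_lt(max(abs(est - phi)), 0.05)

  wn <- rnorm(10000)
  expect_lt(max(abs(ar_coefficients(wn, 4))), 0.05)

  x1 <- as.numeric(arima.sim(list(ar = 0.9), n = 10000))
  est1 <- ar_coefficients(x1, 4)
  expect_equal(est1[1], 0.9, tolerance = 0.05)
  expect_lt(max(abs(est1[3:4])), 0.1)
})

test_that("AR recovery bias shrinks with sample size", {
  phi <- c(0.5, -0.3, 0.2, -0.1)
  err <- vapply(c(500, 5000, 50000), function(n) {
    set.seed(33)
    x <- as.numeric(arima.sim(list(ar = phi), n = n))
    max(abs(ar_coefficients(x, 4) - phi))
  }, 0)
  expect_true(err[3] < err[1])
})

test_that("Higuchi dimension hits the known limits", {
  expect_equal(fractal_dimension(seq_len(2000) / 2000, 10), 1,
               tolerance = 0.05)
  set.seed(34)
  expect_equal(suppressWarnings(fractal_dimension(rnorm(5000), 10)), 2,
               tolerance = 0.15)
  s <- sin(2 * pi * 5 * seq_len(2000) / 250)
  expect_lt(abs(fractal_dimension(s, 10) - 1),
            abs(fractal_dimension(s, 10) - 2))
  expect_error(fractal_dimension(rnorm(50), 10), "too short")
})

test_that("approximate entropy equals the exhaustive template-count oracle", {
  expect_equal(approximate_entropy(rep(1, 30), 2, 0.5), 0, tolerance = 1e-12)
  set.seed(35)
  for (n in c(20, 35, 50)) {
    x <- rnorm(n)
    r <- 0.25 * sd(x)
    expect_equal(approximate_entropy(x, 2, r), oracle_apen(x, 2, r),
                 tolerance = 1e-10)
  }
  per <- rep(c(0, 1), 25)
  shuf <- sample(per)
  expect_lt(oracle_apen(per, 2, 0.5), oracle_apen(shuf, 2, 0.5))
  expect_equal(approximate_entropy(per, 2, 0.5), oracle_apen(per, 2, 0.5),
               tolerance = 1e-10)
})

test_that("sample entropy equals the pairwise Chebyshev oracle", {
  expect_equal(sample_entropy(rep(3, 30), 2, 0.5), 0)
  set.seed(36)
  for (n in c(20, 35, 50)) {
    x <- rnorm(n)
    r <- 0.25 * sd(x)
    expect_equal(suppressWarnings(sample_entropy(x, 2, r)),
                 oracle_sampen(x, 2, r), tolerance = 1e-10)
  }
  t_ <- seq_len(300)
  noise <- local({ set.seed(37); rnorm(300) })
  sine <- sin(2 * pi * 5 * t_ / 250) * sd(noise) / sd(sin(2 * pi * 5 * t_ / 250))
  r <- 0.2 * sd(noise)
  expect_gt(sample_entropy(noise, 2, r), sample_entropy(sine, 2, r))
})

test_that("fused entropy path equals the individual implementations", {
  set.seed(38)
  for (i in 1:5) {
    x <- rnorm(200)
    r <- 0.2 * sd(x)
    fused <- bcichain:::.apen_sampen_cpp(x, 2L, r)
    expect_equal(fused[1], approximate_entropy(x, 2, r), tolerance = 1e-13)
    expect_equal(fused[2], sample_entropy(x, 2, r), tolerance = 1e-13)
  }
})

test_that("permutation entropy matches enumeration and its analytic limits", {
  expect_equal(permutation_entropy(seq_len(50), 3), 0)
  set.seed(39)
  x <- runif(10000)
  expect_equal(permutation_entropy(x, 3, 1), log(6), tolerance = 0.02 * log(6))
  for (i in 1:5) {
    y <- rnorm(20)
    expect_equal(permutation_entropy(y, 3, 1), oracle_perm_entropy(y, 3, 1),
                 tolerance = 1e-12)
  }
  # ties by order of appearance: constant windows map to the identity pattern
  expect_equal(permutation_entropy(rep(1, 30), 3, 1), 0)
})

test_that("higher-order statistics match the printed formulas", {
  h <- higher_order_stats(c(-1, 1))
  expect_equal(h[["skewness"]], 0)
  expect_equal(h[["kurtosis"]], -2)
  expect_equal(h[["variance"]], 2)
  expect_equal(h[["sd"]], sqrt(2))

  set.seed(40)
  g <- rnorm(100000)
  hg <- higher_order_stats(g)
  expect_lt(abs(hg[["skewness"]]), 0.05)
  expect_lt(abs(hg[["kurtosis"]]), 0.05)

  for (i in 1:5) {
    x <- rgamma(40, shape = 2)
    o <- oracle_moments(x)
    hx <- higher_order_stats(x)
    expect_equal(hx[["skewness"]], o$skewness, tolerance = 1e-12)
    expect_equal(hx[["kurtosis"]], o$kurtosis, tolerance = 1e-12)
    expect_equal(hx[["variance"]], o$variance, tolerance = 1e-12)
    expect_equal(hx[["sd"]], o$sd, tolerance = 1e-12)
  }
  expect_warning(hz <- higher_order_stats(rep(1, 10)), "undefined")
  expect_true(is.na(hz[["skewness"]]))
})

test_that("scale behavior: affine-invariant vs quadratically scaling features", {
  set.seed(41)
  x <- rnorm(600)
  a <- 3.7; b <- -2.1
  y <- a * x + b
  expect_equal(permutation_entropy(y, 3), permutation_entropy(x, 3),
               tolerance = 1e-12)
  hx <- hjorth_params(x); hy <- hjorth_params(y)
  expect_equal(hy[["mobility"]], hx[["mobility"]], tolerance = 1e-12)
  expect_equal(hy[["complexity"]], hx[["complexity"]], tolerance = 1e-12)
  expect_equal(hy[["activity"]], a^2 * hx[["activity"]], tolerance = 1e-9)
  expect_equal(higher_order_stats(y)[["variance"]],
               a^2 * higher_order_stats(x)[["variance"]], tolerance = 1e-9)
  expect_equal(band_power_welch(a * x, 250, c(8, 12)),
               a^2 * band_power_welch(x, 250, c(8, 12)), tolerance = 1e-9)
})

test_that("featurize_epoch produces the fixed 17-per-channel layout", {
  cfg <- feature_config()
  e <- random_epoch(3, 500, fs = 250, seed = 42)
  v <- featurize_epoch(e, cfg)
  expect_length(v, 3 * 17)
  layout <- attr(v, "layout")
  expect_equal(nrow(layout), 51)
  expect_equal(unique(table(layout$channel)), 17L)
  expect_equal(layout$feature[1:5],
               c("mu_power", "beta_power", "activity", "mobility",
                 "complexity"))
  # determinism
  expect_identical(as.numeric(v), as.numeric(featurize_epoch(e, cfg)))
})

test_that("featurize_epoch stays finite over random epochs and flags degenerates", {
  cfg <- feature_config()
  set.seed(43)
  for (i in 1:25) {
    e <- random_epoch(2, 300, fs = 250)
    v <- featurize_epoch(e, cfg)
    expect_false(attr(v, "flagged"))
    expect_true(all(is.finite(v)))
  }
  flat <- new_epoch(matrix(c(rnorm(300), rep(0, 300)), 2, 300, byrow = TRUE),
                    fs = 250, label = "x")
  v <- featurize_epoch(flat, cfg)
  expect_true(attr(v, "flagged"))
  expect_true(anyNA(v))
})

test_that("normalizer is a training-statistics z-score", {
  set.seed(44)
  x <- matrix(rnorm(50 * 6, mean = 3, sd = 2), 50, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  norm <- fit_normalizer(x)
  z <- apply_normalizer(x, norm)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)

  xc <- x; xc[, 2] <- 7
  expect_warning(nc <- fit_normalizer(xc), "unscaled")
  expect_equal(apply_normalizer(xc, nc)[, 2], rep(0, 50))

  # test vectors use train parameters only
  test <- matrix(rnorm(20 * 6, mean = 10), 20, 6,
                 dimnames = list(NULL, paste0("f", 1:6)))
  zt <- apply_normalizer(test, norm)
  own <- scale(test)
  expect_gt(max(abs(zt - own)), 0.5)
  bad <- test
  colnames(bad) <- paste0("g", 1:6)
  expect_error(apply_normalizer(bad, norm), "layout")
})
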
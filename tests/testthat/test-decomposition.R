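test_that("monotone signals yield zero modes with the signal as residue", {
  ramp <- seq(0, 1, length.out = 100)
  d <- emd(ramp)
  expect_length(d$modes, 0)
  expect_equal(d$residue, ramp)
  expect_length(emd(rep(3.5, 50))$modes, 0)
})

test_that("modes plus residue reconstruct the input to machine precision", {
  for (s in 1:5) {
    v <- generate_pollutants(synth_config(seed = s, n_days = 400))$PM10$values
    d <- emd(v)
    expect_lt(d$reconstruction_error, 1e-8 * sd(v))
    di <- iceemdan(v, sift_config(ensemble_size = 5, seed = s))
    expect_lt(di$reconstruction_error, 1e-8 * sd(v))
    expect_equal(Reduce(`+`, di$modes) + di$residue, v, tolerance = 1e-12)
  }
})

test_that("two superposed tones separate into their own modes", {
  tt <- two_tone()
  d <- emd(tt$x)
  expect_gte(length(d$modes), 2)
  expect_gt(cor(d$modes[[1]], tt$fast), 0.95)
  expect_gt(cor(d$modes[[2]], tt$slow), 0.95)
})

test_that("local mean vanishes on a symmetric tone and tracks trends", {
  t <- seq(0, 4, length.out = 400)
  tone <- sin(2 * pi * t)
  expect_lt(max(abs(local_mean(tone))), 0.05)
  # translation equivariance
  expect_equal(local_mean(tone + 3), local_mean(tone) + 3, tolerance = 1e-10)
  # a slow trend under a fast oscillation is recovered as the local mean
  trend <- seq(0, 2, length.out = 400)
  sig <- sin(2 * pi * 8 * t)
  expect_gt(cor(local_mean(sig + trend), trend), 0.9)
  # no extrema: the signal is its own local mean
  expect_equal(local_mean(trend), trend)
})

test_that("mode frequencies decrease down the decomposition", {
  zc <- function(m) sum(diff(sign(m)) != 0)
  for (s in c(2, 7, 21)) {
    v <- generate_pollutants(synth_config(seed = s))$PM2.5$values
    d <- emd(v)
    counts <- vapply(d$modes, zc, numeric(1))
    expect_true(all(diff(counts) <= 1))  # non-increasing, ties within 1
  }
})

test_that("white noise decomposes into about log2(n) modes", {
  ks <- withr::with_seed(5, replicate(20, length(emd(rnorm(512))$modes)))
  expect_true(all(ks <= floor(log2(512)) + 1))
})

test_that("iceemdan is deterministic under a fixed seed", {
  v <- generate_pollutants(synth_config(seed = 3, n_days = 300))$NO2$values
  cfg <- sift_config(ensemble_size = 8, seed = 42)
  a <- iceemdan(v, cfg)
  b <- iceemdan(v, cfg)
  expect_identical(a$modes, b$modes)
  expect_identical(a$residue, b$residue)
})

test_that("zero noise with a single realization collapses to plain emd", {
  v <- generate_pollutants(synth_config(seed = 6, n_days = 300))$SO2$values
  cfg <- sift_config(ensemble_size = 1, noise_scale = 0)
  a <- iceemdan(v, cfg)
  b <- emd(v, cfg)
  expect_equal(length(a$modes), length(b$modes))
  for (k in seq_along(a$modes))
    expect_equal(a$modes[[k]], b$modes[[k]], tolerance = 1e-6)
})

test_that("ensemble averaging shrinks the variance of the first residue", {
  v <- generate_pollutants(synth_config(seed = 9, n_days = 256))$PM2.5$values
  r1_of <- function(I, seed) {
    cfg <- sift_config(ensemble_size = I, seed = seed, max_imfs = 1)
    iceemdan(v, cfg)$residue
  }
  r_small <- sapply(1:20, function(s) r1_of(2, s))
  r_large <- sapply(1:20, function(s) r1_of(20, s))
  # pointwise spread of r1 across noise seeds shrinks with ensemble size
  spread_small <- mean(apply(r_small, 1, sd))
  spread_large <- mean(apply(r_large, 1, sd))
  expect_lt(spread_large, spread_small)
})

test_that("imf sets serialize to the imf1..residue CSV layout", {
  v <- generate_pollutants(synth_config(seed = 2, n_days = 200))$O3$values
  d <- emd(v)
  path <- withr::local_tempfile(fileext = ".csv")
  write_imfs(d, path)
  df <- read.csv(path)
  expect_identical(names(df),
                   c(paste0("imf", seq_along(d$modes)), "residue"))
  expect_equal(rowSums(df), v, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("degenerate inputs are rejected", {
  expect_error(emd(c(1, 2, 3)), "too short")
  expect_error(emd(c(1, NA, 3, 4)), "finite")
  expect_error(sift_config(ensemble_size = 0), "ensemble_size")
})
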
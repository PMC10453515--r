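# Independent brute-force recomputation of the ten statistics, written with
# explicit loops/sums so it shares no code with window_stats().
brute_stats <- function(x, partner, n_bins = 10) {
  w <- length(x)
  mn <- sum(x) / w
  xs <- sort(x)
  med <- if (w %% 2 == 1) xs[(w + 1) / 2] else (xs[w / 2] + xs[w / 2 + 1]) / 2
  std <- sqrt(sum((x - mn)^2) / w)
  energy <- sum(x^2) / w
  # type-7 quantile by hand
  q7 <- function(p) {
    h <- (w - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  iqr <- q7(0.75) - q7(0.25)
  if (max(x) == min(x)) {
    ent <- 0
  } else {
    counts <- numeric(n_bins)
    for (v in x) {
      b <- floor((v - min(x)) / (max(x) - min(x)) * n_bins) + 1
      if (b > n_bins) b <- n_bins
      counts[b] <- counts[b] + 1
    }
    ent <- 0
    for (cnt in counts) if (cnt > 0) {
      p <- cnt / w
      ent <- ent - p * log2(p)
    }
  }
  sx <- sqrt(sum((x - mn)^2)); pm <- sum(partner) / length(partner)
  sp <- sqrt(sum((partner - pm)^2))
  r <- if (sx == 0 || sp == 0) 0 else
    sum((x - mn) * (partner - pm)) / (sx * sp)
  k <- min(5, w)
  ma <- vapply(k:w, function(i) sum(x[(i - k + 1):i]) / k, numeric(1))
  c(mean = mn, median = med, max = max(x), min = min(x), std = std,
    energy = energy, iqr = iqr, entropy = ent, correlation = r,
    sma = sum(ma) / length(ma))
}

test_that("hand-computed values for a tiny window are reproduced", {
  s <- window_stats(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(s[["mean"]], 2.5)
  expect_equal(s[["energy"]], 7.5)           # (1+4+9+16)/4
  expect_equal(s[["std"]], 1.1180, tolerance = 1e-4)
  expect_equal(s[["correlation"]], -1)
})

test_that("the degenerate constant window zeroes the dispersion statistics", {
  s <- window_stats(rep(5, 12), rnorm(12))
  expect_equal(s[["std"]], 0)
  expect_equal(s[["iqr"]], 0)
  expect_equal(s[["energy"]], 25)
  expect_equal(s[["entropy"]], 0)
  expect_equal(s[["correlation"]], 0)
  expect_equal(unname(s[c("mean", "median", "min", "max", "sma")]),
               rep(5, 5))
})

test_that("self-correlation of a non-constant axis is exactly 1", {
  x <- rnorm(30)
  expect_equal(window_stats(x, x)[["correlation"]], 1)
})

test_that("every statistic matches brute-force recomputation on 200 random windows", {
  set.seed(404)
  for (i in 1:200) {
    w <- sample(2:60, 1)
    x <- rnorm(w, mean = runif(1, -5, 5), sd = runif(1, 0.01, 4))
    partner <- rnorm(w)
    expect_equal(window_stats(x, partner), brute_stats(x, partner),
                 tolerance = 1e-10)
  }
})

test_that("statistics transform correctly under positive scaling", {
  set.seed(11)
  x <- rnorm(40); partner <- rnorm(40); c0 <- 3.7
  s1 <- window_stats(x, partner)
  s2 <- window_stats(c0 * x, partner)
  for (nm in c("mean", "median", "max", "min", "std", "sma"))
    expect_equal(s2[[nm]], c0 * s1[[nm]], tolerance = 1e-12)
  expect_equal(s2[["energy"]], c0^2 * s1[["energy"]], tolerance = 1e-12)
  expect_equal(s2[["correlation"]], s1[["correlation"]], tolerance = 1e-12)
})

test_that("enrichment dimension law: base channels + 30", {
  w <- 40
  m3 <- matrix(rnorm(w * 3), w, 3, dimnames = list(NULL, c("x", "y", "z")))
  expect_length(enrich_window(m3), 33)
  m12 <- matrix(rnorm(w * 12), w, 12)
  expect_length(enrich_window(m12), 42)
  expect_error(enrich_window(matrix(rnorm(w * 2), w, 2)), "3 channels")
})

test_that("constant channels propagate zeros through enrichment", {
  m <- matrix(2, 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  f <- enrich_window(m)
  expect_equal(unname(f[c("x_base", "y_base", "z_base")]), rep(2, 3))
  expect_equal(unname(f[grepl("_(std|iqr|entropy)$", names(f))]), rep(0, 9))
})

test_that("correlation partners follow the cyclic axis order", {
  w <- 30
  x <- rnorm(w); y <- rnorm(w); z <- rnorm(w)
  f <- enrich_window(cbind(x = x, y = y, z = z))
  expect_equal(f[["accx_correlation"]], cor(x, y))
  expect_equal(f[["accy_correlation"]], cor(y, z))
  expect_equal(f[["accz_correlation"]], cor(z, x))
})

test_that("feature datasets have one row per window and a constant schema", {
  s <- small_stream(activities = "walking", dur = 8)  # 160 samples
  fd <- build_feature_dataset(s, window_spec(40, 0.5))
  expect_equal(nrow(fd), 7)
  expect_equal(ncol(fd), 3 + 33)  # window, start, label + features
  expect_true(all(fd$label == "walking"))
})

test_that("extra channels beyond the first three only add base means", {
  s <- small_stream(activities = "walking", dur = 6)
  s$extra1 <- rnorm(nrow(s)); s$extra2 <- rnorm(nrow(s))
  fd <- build_feature_dataset(s, window_spec(40, 0.5),
                              channels = c("x", "y", "z", "extra1", "extra2"))
  expect_equal(ncol(fd), 3 + 5 + 30)
  # permuting the trailing channels leaves the enrichment columns unchanged
  fd2 <- build_feature_dataset(s, window_spec(40, 0.5),
                               channels = c("x", "y", "z", "extra2", "extra1"))
  stat_cols <- grep("^acc", names(fd), value = TRUE)
  expect_equal(fd[stat_cols], fd2[stat_cols])
})
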
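#' The ten per-axis window statistics
#'
#' Computes, for one acceleration axis of one window: mean, median, largest
#' and smallest observation, population standard deviation, energy (mean of
#' squared samples), interquartile range (Q3 - Q1, linear-interpolation
#' quantiles), Shannon entropy in bits of the 10-bin histogram of the samples
#' over their own range, Pearson correlation with the partner axis (0 when
#' either axis is constant), and the simple moving average reduced to a
#' scalar as the mean of the trailing 5-sample moving-average series.
#'
#' @param x Numeric vector, the axis samples of one window (length >= 2).
#' @param partner Numeric vector of the same length, the partner axis used
#'   for the correlation statistic.
#' @param n_bins Number of histogram bins for the entropy statistic.
#' @return A named numeric vector of length 10: `mean`, `median`, `max`,
#'   `min`, `std`, `energy`, `iqr`, `entropy`, `correlation`, `sma`.
#' @examples
#' window_stats(c(1, 2, 3, 4), c(4, 3, 2, 1))
#' @export
window_stats <- function(x, partner, n_bins = 10L) {
  w <- length(x)
  if (w < 2L) abort("window statistics need at least 2 samples")
  if (length(partner) != w) abort("`partner` must match `x` in length")

  m <- mean(x)
  pop_sd <- sqrt(mean((x - m)^2))
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)

  # Histogram entropy over the window's own range; a constant window carries
  # no information and scores 0.
  rng <- range(x)
  if (rng[1] == rng[2]) {
    ent <- 0
  } else {
    bin <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1, n_bins)
    p <- tabulate(bin, nbins = n_bins) / w
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
  }

  r <- if (pop_sd == 0 || sd(partner) == 0) 0 else cor(x, partner)

  k <- min(5L, w)
  ma <- zoo::rollmean(x, k = k, align = "right")

  c(mean = m, median = median(x), max = max(x), min = min(x),
    std = pop_sd, energy = mean(x^2), iqr = q[2] - q[1],
    entropy = ent, correlation = r, sma = mean(ma))
}

#' Enrich one window with per-axis statistics
#'
#' The first three channels are taken as the acceleration axes x/y/z. The
#' feature vector holds the per-window mean of every base channel, followed
#' by the ten [window_stats()] for each acceleration axis; the correlation
#' partner follows the cyclic order x->y, y->z, z->x. Output dimension is
#' therefore `n_channels + 30`, reproducing the published counts of 33
#' features from 3 base channels and 42 from 12.
#'
#' @param samples A `size x n_channels` numeric matrix (>= 3 channels,
#'   acceleration axes first).
#' @return A named numeric feature vector of length `n_channels + 30`.
#' @export
enrich_window <- function(samples) {
  samples <- as.matrix(samples)
  nc <- ncol(samples)
  if (nc < 3L) abort("enrichment needs >= 3 channels (acceleration axes first)")
  ch_names <- colnames(samples)
  if (is.null(ch_names)) ch_names <- paste0("c", seq_len(nc))

  base <- colMeans(samples)
  names(base) <- paste0(ch_names, "_base")

  axes <- c("x", "y", "z")
  partner <- c(2L, 3L, 1L)
  stats <- unlist(lapply(1:3, function(j) {
    s <- window_stats(samples[, j], samples[, partner[j]])
    names(s) <- paste0("acc", axes[j], "_", names(s))
    s
  }))
  c(base, stats)
}

#' Build the per-window feature dataset for a stream
#'
#' Composes [segment_stream()] and [enrich_window()]: one row per window,
#' labeled by majority vote, with a constant column schema. This is the
#' table the nested classifier trains and tests on.
#'
#' @param stream A `har_stream`.
#' @param spec A [window_spec()].
#' @param channels Optional channel column names (see [segment_stream()]).
#' @return A tibble: `window`, `start`, `label`, then one numeric column per
#'   feature (e.g. `x_base`, `accx_mean`, ..., `accz_sma`).
#' @examples
#' pro <- default_activity_profiles()
#' sch <- activity_schedule("walking", 8, 0.05)
#' feats <- build_feature_dataset(generate_stream(pro, sch, 1), window_spec(40))
#' @export
build_feature_dataset <- function(stream, spec, channels = NULL) {
  win <- segment_stream(stream, spec, channels)
  feat <- do.call(rbind, lapply(win$samples, enrich_window))
  dplyr::bind_cols(win[, c("window", "start", "label")],
                   tibble::as_tibble(feat))
}

# Feature column names of a feature dataset (everything numeric beyond the
# window bookkeeping columns).
feature_cols <- function(data) {
  setdiff(names(data)[vapply(data, is.numeric, logical(1))],
          c("window", "start"))
}
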
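#' Specify fixed-size overlapping windows
#'
#' A window of `size` samples advances by `step = max(1, round(size * (1 -
#' overlap)))` samples, so consecutive windows share `size - step` samples.
#' A non-integer raw step (e.g. size 144 at 80% overlap gives 28.8) is
#' rounded to the nearest integer.
#'
#' @param size Window length in samples (>= 2).
#' @param overlap Overlap fraction in `[0, 1)`.
#' @return A `window_spec` list with `size`, `overlap` and the derived `step`.
#' @seealso [window_preset()] for the published dataset settings.
#' @export
window_spec <- function(size, overlap = 0.5) {
  size <- as.integer(size)
  if (size < 2L) abort("window `size` must be >= 2 samples")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1)")
  step <- max(1L, as.integer(round(size * (1 - overlap))))
  structure(list(size = size, overlap = overlap, step = step),
            class = "window_spec")
}

#' Published windowing presets
#'
#' The three settings used for the reference datasets: `inertia` (40 samples,
#' 50% overlap), `wisdm` (144 samples, 80% overlap, about 7 s at 20 Hz) and
#' `uci` (128 samples, 50% overlap, 2.56 s at 50 Hz).
#'
#' @param name One of `"inertia"`, `"wisdm"`, `"uci"`.
#' @return A [window_spec()].
#' @export
window_preset <- function(name = c("inertia", "wisdm", "uci")) {
  name <- match.arg(name)
  switch(name,
         inertia = window_spec(40, 0.5),
         wisdm = window_spec(144, 0.8),
         uci = window_spec(128, 0.5))
}

#' Time span of one window
#'
#' @param spec A [window_spec()].
#' @param sampling_interval Seconds between consecutive samples.
#' @return Window duration in seconds (`size * sampling_interval`).
#' @examples
#' window_span(window_spec(128, 0.5), 0.02) # 2.56 s
#' @export
window_span <- function(spec, sampling_interval) {
  spec$size * sampling_interval
}

#' Assign one activity label to a window
#'
#' Majority vote over the per-sample labels; ties are broken in favor of the
#' label that occurs earliest in the window, which keeps labeling
#' deterministic without a seed.
#'
#' @param labels Character vector of per-sample labels (length >= 1).
#' @return A single label.
#' @export
label_window <- function(labels) {
  if (length(labels) == 0) abort("window has no samples")
  counts <- table(factor(labels, levels = unique(labels)))
  names(counts)[which.max(counts)]
}

#' Start indices of the windows covering a stream
#'
#' @param n Number of samples in the stream.
#' @param spec A [window_spec()].
#' @return Integer vector of 1-based window start indices; length
#'   `floor((n - size) / step) + 1`.
#' @export
window_starts <- function(n, spec) {
  if (n < spec$size)
    abort(paste0("stream has ", n, " samples, shorter than the window (",
                 spec$size, ")"))
  seq.int(1L, n - spec$size + 1L, by = spec$step)
}

#' Segment a stream into overlapping windows
#'
#' Windows start at sample indices `1, 1 + step, 1 + 2*step, ...`; trailing
#' samples that do not fill a complete window are discarded, so the window
#' count is `floor((N - size) / step) + 1`. Each window receives one label by
#' [label_window()]; windows spanning an activity boundary are kept and
#' majority-labeled, since such ambiguous segments are precisely where
#' outlier bouts occur.
#'
#' @param stream A `har_stream` (or any tibble with channel columns and a
#'   `label` column).
#' @param spec A [window_spec()].
#' @param channels Channel column names; defaults to every numeric column
#'   except `time`.
#' @return A tibble with one row per window: `window`, `start` (1-based
#'   sample index), `label`, and `samples`, a list-column of `size x
#'   n_channels` matrices.
#' @export
segment_stream <- function(stream, spec, channels = NULL) {
  if (is.null(channels)) {
    num <- names(stream)[vapply(stream, is.numeric, logical(1))]
    channels <- setdiff(num, "time")
  }
  n <- nrow(stream)
  w <- spec$size
  starts <- window_starts(n, spec)
  mat <- as.matrix(stream[, channels, drop = FALSE])
  labs <- stream$label
  tibble::tibble(
    window = seq_along(starts),
    start = starts,
    label = vapply(starts, function(s) label_window(labs[s:(s + w - 1L)]),
                   character(1)),
    samples = lapply(starts, function(s) mat[s:(s + w - 1L), , drop = FALSE])
  )
}
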
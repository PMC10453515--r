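#' Define a per-activity signal profile
#'
#' An activity profile parameterizes the synthetic signal on each of the three
#' acceleration axes as a constant offset plus a sinusoid plus Gaussian noise:
#' `baseline + amplitude * sin(2*pi*frequency*t + phase) + N(0, noise_sd)`.
#' Axis phases are fixed at 0, pi/3 and 2*pi/3 so that the x/y/z channels of a
#' dynamic activity are mutually correlated, which exercises the cross-axis
#' correlation feature downstream.
#'
#' @param name Activity label (single string).
#' @param baseline Numeric length 3, per-axis constant offset in m/s^2.
#' @param amplitude Numeric length 3, per-axis sinusoid amplitude in m/s^2
#'   (0 for static activities).
#' @param frequency Numeric length 3, per-axis sinusoid frequency in Hz
#'   (must be >= 0).
#' @param noise_sd Numeric length 3, per-axis Gaussian noise standard
#'   deviation in m/s^2 (must be >= 0).
#' @return A tibble with one row per axis and class `activity_profile` rows;
#'   combine several with [dplyr::bind_rows()] to form a profile set.
#' @examples
#' activity_profile("sitting", baseline = c(0.2, 9.6, 1.1), amplitude = 0,
#'                  frequency = 0, noise_sd = 0.05)
#' @export
activity_profile <- function(name, baseline, amplitude = 0, frequency = 0,
                             noise_sd = 0.1) {
  stopifnot(is.character(name), length(name) == 1L)
  rec3 <- function(v, what) {
    v <- as.numeric(v)
    if (length(v) == 1L) v <- rep(v, 3L)
    if (length(v) != 3L) abort(paste0("`", what, "` must have length 1 or 3"))
    v
  }
  baseline <- rec3(baseline, "baseline")
  amplitude <- rec3(amplitude, "amplitude")
  frequency <- rec3(frequency, "frequency")
  noise_sd <- rec3(noise_sd, "noise_sd")
  if (any(noise_sd < 0)) abort("`noise_sd` must be >= 0")
  if (any(frequency < 0)) abort("`frequency` must be >= 0")
  tibble::tibble(
    name = name,
    axis = c("x", "y", "z"),
    baseline = baseline,
    amplitude = amplitude,
    frequency = frequency,
    noise_sd = noise_sd,
    phase = c(0, pi / 3, 2 * pi / 3)
  )
}

#' Default activity profiles for simulation
#'
#' Four well-separated profiles (sitting, walking, going_up, going_down) plus
#' a "running" profile intended for outlier injection. Static and dynamic
#' activities differ in baseline, amplitude and frequency so that the ten
#' per-axis window statistics separate them.
#'
#' @return A tibble of stacked [activity_profile()] rows.
#' @export
default_activity_profiles <- function() {
  dplyr::bind_rows(
    activity_profile("sitting", baseline = c(0.3, 9.6, 1.2),
                     amplitude = 0, frequency = 0, noise_sd = 0.05),
    activity_profile("walking", baseline = c(1.5, 9.8, 0.5),
                     amplitude = c(2.5, 3.5, 2.0), frequency = c(2.0, 2.0, 2.0),
                     noise_sd = 0.3),
    activity_profile("going_up", baseline = c(3.5, 10.5, -1.0),
                     amplitude = c(4.5, 5.5, 3.5), frequency = c(1.4, 1.4, 1.4),
                     noise_sd = 0.4),
    activity_profile("going_down", baseline = c(-2.5, 8.5, 3.0),
                     amplitude = c(6.0, 7.0, 5.0), frequency = c(2.8, 2.8, 2.8),
                     noise_sd = 0.4),
    activity_profile("running", baseline = c(6.0, 14.0, -4.0),
                     amplitude = c(9.0, 10.0, 8.0), frequency = c(3.4, 3.4, 3.4),
                     noise_sd = 0.5)
  )
}

#' Build an activity schedule
#'
#' @param activities Character vector of activity names, in playout order.
#' @param durations Numeric vector of segment durations in seconds (> 0).
#' @param sampling_interval Sampling interval in seconds (> 0); 0.05 matches a
#'   20 Hz phone accelerometer, 0.02 a 50 Hz one.
#' @return A tibble with class `activity_schedule` metadata.
#' @export
activity_schedule <- function(activities, durations, sampling_interval = 0.05) {
  stopifnot(length(activities) == length(durations))
  if (any(durations <= 0)) abort("segment durations must be > 0")
  if (sampling_interval <= 0) abort("`sampling_interval` must be > 0")
  out <- tibble::tibble(activity = as.character(activities),
                        duration = as.numeric(durations))
  attr(out, "sampling_interval") <- sampling_interval
  out
}

#' Simulate a labeled tri-axial inertial stream
#'
#' Plays out a schedule of activities, drawing each sample on each axis from
#' that activity's profile model. The stream is uniformly sampled; labels
#' follow the schedule exactly, and a fixed seed fully determines the output.
#'
#' @param profiles Profile set from [activity_profile()] rows (bind rows of
#'   several profiles); every scheduled activity must be present.
#' @param schedule An [activity_schedule()].
#' @param seed Integer seed for the noise.
#' @return A `har_stream` tibble with columns `time` (seconds), `x`, `y`, `z`
#'   (m/s^2) and `label`; the sampling interval is stored as an attribute.
#' @examples
#' pro <- default_activity_profiles()
#' sch <- activity_schedule(c("sitting", "walking"), c(10, 10), 0.05)
#' str <- generate_stream(pro, sch, seed = 1)
#' @export
generate_stream <- function(profiles, schedule, seed = 1L) {
  dt <- attr(schedule, "sampling_interval")
  if (is.null(dt)) abort("`schedule` must come from activity_schedule()")
  missing <- setdiff(unique(schedule$activity), unique(profiles$name))
  if (length(missing) > 0)
    abort(paste0("no profile for scheduled activity: ",
                 paste(missing, collapse = ", ")))
  n_per <- as.integer(round(schedule$duration / dt))
  n_tot <- sum(n_per)
  time <- (seq_len(n_tot) - 1L) * dt
  label <- rep(schedule$activity, times = n_per)

  seed_rng(seed)
  axes <- matrix(0, nrow = n_tot, ncol = 3L,
                 dimnames = list(NULL, c("x", "y", "z")))
  offset <- 0L
  for (i in seq_len(nrow(schedule))) {
    act <- schedule$activity[i]
    idx <- offset + seq_len(n_per[i])
    t_i <- time[idx]
    pro <- profiles[profiles$name == act, ]
    for (j in 1:3) {
      p <- pro[pro$axis == c("x", "y", "z")[j], ]
      axes[idx, j] <- p$baseline +
        p$amplitude * sin(2 * pi * p$frequency * t_i + p$phase) +
        (if (p$noise_sd > 0) rnorm(length(idx), 0, p$noise_sd) else 0)
    }
    offset <- offset + n_per[i]
  }
  out <- tibble::tibble(time = time, x = axes[, 1], y = axes[, 2],
                        z = axes[, 3], label = label)
  attr(out, "sampling_interval") <- dt
  class(out) <- c("har_stream", class(out))
  out
}

#' Inject outlier-activity segments into a stream
#'
#' Replaces `n_segments` non-overlapping spans of the stream with signal drawn
#' from `outlier_profile`, relabeling those samples. Replacement (rather than
#' insertion) keeps the stream uniformly sampled, emulating short bouts of an
#' unknown activity embedded inside known ones.
#'
#' @param stream A `har_stream` from [generate_stream()].
#' @param outlier_profile Profile rows (one activity) for the injected signal.
#' @param n_segments Number of spans to inject (0 returns the stream unchanged).
#' @param segment_duration Span duration in seconds.
#' @param seed Integer seed for span placement and noise.
#' @return The modified stream, same length and sampling as the input.
#' @export
inject_outliers <- function(stream, outlier_profile, n_segments,
                            segment_duration, seed = 1L) {
  if (n_segments == 0) return(stream)
  dt <- attr(stream, "sampling_interval")
  n <- nrow(stream)
  len <- as.integer(round(segment_duration / dt))
  if (len < 1L) abort("`segment_duration` shorter than one sample")
  if (n_segments * len >= n)
    abort("injected spans exceed the stream length")
  act <- unique(outlier_profile$name)
  if (length(act) != 1L) abort("`outlier_profile` must describe one activity")

  seed_rng(seed)
  # Rejection-sample a set of pairwise disjoint spans.
  starts <- NULL
  for (attempt in 1:2000) {
    cand <- sort(sample.int(n - len + 1L, n_segments))
    if (n_segments == 1L || all(diff(cand) >= len)) { starts <- cand; break }
  }
  if (is.null(starts))
    abort("could not place non-overlapping outlier spans; reduce n_segments")

  for (s in starts) {
    idx <- s:(s + len - 1L)
    t_i <- stream$time[idx]
    for (j in c("x", "y", "z")) {
      p <- outlier_profile[outlier_profile$axis == j, ]
      stream[[j]][idx] <- p$baseline +
        p$amplitude * sin(2 * pi * p$frequency * t_i + p$phase) +
        (if (p$noise_sd > 0) rnorm(length(idx), 0, p$noise_sd) else 0)
    }
    stream$label[idx] <- act
  }
  stream
}

#' Write a stream as raw accelerometer CSV
#'
#' Serializes a stream in the raw phone-accelerometer dialect
#' (`user,activity,timestamp,x,y,z` with a line-terminating `";"`, timestamps
#' in integer nanoseconds), so generated data can round-trip through
#' [read_wisdm_raw()].
#'
#' @param stream A `har_stream`.
#' @param path Output file path.
#' @param user Numeric user id to stamp on every row.
#' @return `path`, invisibly.
#' @export
write_wisdm_csv <- function(stream, path, user = 1L) {
  ts <- format(round(stream$time * 1e9), scientific = FALSE, trim = TRUE)
  lines <- sprintf("%d,%s,%s,%.6g,%.6g,%.6g;",
                   as.integer(user), stream$label, ts,
                   stream$x, stream$y, stream$z)
  writeLines(lines, path)
  invisible(path)
}

# set.seed guarding against non-integer/overflowing seeds
seed_rng <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
}
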
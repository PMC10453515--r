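#' Declare an end-to-end experiment
#'
#' Bundles everything one run needs: the data source, windowing, the known
#' activity set A, the outlier activities (which must be disjoint from A —
#' the whole point is that the nested classifier never sees them as
#' classes), the base classifier and the seeds.
#'
#' @param activities Known activity names (the set A).
#' @param outlier_activities Activities injected as outliers; must not
#'   intersect `activities`.
#' @param profiles Activity profile set (defaults to
#'   [default_activity_profiles()]); must cover both groups.
#' @param schedule An [activity_schedule()] over `activities`; `NULL` builds
#'   a default round-robin schedule.
#' @param window A [window_spec()] or preset name.
#' @param base Base classifier algorithm name or [base_classifier()].
#' @param order `"random"` (seeded shuffle of A) or `"listed"` (use
#'   `activities` as given).
#' @param n_outlier_segments,outlier_duration Injection settings (count,
#'   seconds per span).
#' @param train_fraction Training share of windows.
#' @param run_mlp Also train the feed-forward baseline on the same windows
#'   (with the outlier class labeled in training).
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Optional directory for JSON/CSV reports.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(activities = c("sitting", "walking",
                                             "going_up", "going_down"),
                              outlier_activities = "running",
                              profiles = default_activity_profiles(),
                              schedule = NULL,
                              window = window_spec(40, 0.5),
                              base = "knn",
                              order = c("random", "listed"),
                              n_outlier_segments = 4L,
                              outlier_duration = 4,
                              train_fraction = 0.7,
                              run_mlp = FALSE,
                              seed = 1L,
                              out_dir = NULL) {
  overlap_bad <- intersect(activities, outlier_activities)
  if (length(overlap_bad) > 0)
    abort(paste0("outlier activities must be unknown to the classifier, ",
                 "but these are in A: ", paste(overlap_bad, collapse = ", ")))
  if (is.character(window)) window <- window_preset(window)
  if (is.character(base)) base <- base_classifier(base)
  order <- match.arg(order)
  if (is.null(schedule))
    schedule <- activity_schedule(rep(activities, times = 6),
                                  rep(20, 6 * length(activities)),
                                  sampling_interval = 0.05)
  structure(list(activities = activities,
                 outlier_activities = outlier_activities,
                 profiles = profiles, schedule = schedule, window = window,
                 base = base, order = order,
                 n_outlier_segments = n_outlier_segments,
                 outlier_duration = outlier_duration,
                 train_fraction = train_fraction, run_mlp = run_mlp,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

# Derive a stage seed from the master seed, kept inside 32-bit range.
stage_seed <- function(seed, k) (as.numeric(seed) * 131L + k) %% 2147483647

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    abort(paste0("stage ", stage, ": ", conditionMessage(e))))
}

#' Run a full outlier-detection experiment
#'
#' Pipeline: simulate (or accept) a labeled stream, inject outlier
#' segments, window and featurize, split 70/30, run the nested classifier,
#' and evaluate detection/over-detection; optionally also train the
#' feed-forward baseline on the same windows. Fixed config and seed give a
#' byte-identical report.
#'
#' @param config An [experiment_config()].
#' @return A `nestout_experiment` list: `config`, `feature_data`, `split`
#'   sizes, `fit` (the `nestbc` object), `report` ([outlier_report()] row),
#'   `levels` (per-level measures), and if requested `mlp` plus
#'   `mlp_accuracy` on the test windows. Written to `out_dir` as
#'   `report.json` and `verdicts.csv` when configured.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  stream <- with_stage("simulate", {
    s <- generate_stream(config$profiles, config$schedule,
                         seed = stage_seed(config$seed, 1))
    for (i in seq_along(config$outlier_activities)) {
      pro <- config$profiles[config$profiles$name ==
                               config$outlier_activities[i], ]
      s <- inject_outliers(s, pro, config$n_outlier_segments,
                           config$outlier_duration,
                           seed = stage_seed(config$seed, 1 + i))
    }
    s
  })
  feats <- with_stage("featurize",
                      build_feature_dataset(stream, config$window))
  sp <- with_stage("split",
                   split_train_test(feats, config$train_fraction,
                                    seed = stage_seed(config$seed, 10)))
  # Outlier windows falling into the training split stay there: their label
  # is outside A, so they are never a positive class at any level — they are
  # permanent negative background, exactly like unknown-activity segments
  # mixed through a recorded stream.
  fit <- with_stage("nestbc",
                    nest_classify(sp$train, sp$test, config$activities,
                                  base = config$base,
                                  order = if (identical(config$order, "listed"))
                                    config$activities else NULL,
                                  seed = stage_seed(config$seed, 20)))
  report <- with_stage("evaluate", outlier_report(fit))

  out <- list(config = config, feature_data = feats,
              n_train = nrow(sp$train), n_test = nrow(sp$test),
              fit = fit, levels = fit$levels, report = report)

  if (isTRUE(config$run_mlp)) {
    out$mlp <- with_stage("mlp", train_mlp(sp$train, mlp_config(),
                                           seed = stage_seed(config$seed, 30)))
    pred <- predict(out$mlp, sp$test)
    out$mlp_accuracy <- mean(pred == sp$test$label)
  }

  if (!is.null(config$out_dir)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      abort("writing reports requires the jsonlite package")
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    payload <- list(
      activities = fit$activities,
      base = config$base$algorithm,
      seed = config$seed,
      levels = fit$levels,
      outlier_report = report)
    if (!is.null(out$mlp_accuracy)) payload$mlp_accuracy <- out$mlp_accuracy
    jsonlite::write_json(payload, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(fit$verdicts,
                     file.path(config$out_dir, "verdicts.csv"),
                     row.names = FALSE)
  }
  class(out) <- "nestout_experiment"
  out
}

#' @export
print.nestout_experiment <- function(x, ...) {
  cat("nestout experiment —", x$config$base$algorithm, "base,",
      x$n_train, "train /", x$n_test, "test windows\n")
  print(x$report)
  invisible(x)
}
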
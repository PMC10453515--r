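# Fixtures shared across the suite: small profile sets, schedules, and
# random feature tables. Everything is generated in code under fixed seeds.

test_profiles <- function() default_activity_profiles()

test_schedule <- function(activities = c("sitting", "walking", "going_up",
                                         "going_down"),
                          reps = 6, dur = 20, dt = 0.05) {
  activity_schedule(rep(activities, times = reps),
                    rep(dur, reps * length(activities)),
                    sampling_interval = dt)
}

# A short single- or multi-activity stream for unit tests.
small_stream <- function(activities = c("sitting", "walking"), dur = 8,
                         seed = 1, dt = 0.05) {
  generate_stream(test_profiles(),
                  activity_schedule(activities, rep(dur, length(activities)),
                                    sampling_interval = dt),
                  seed = seed)
}

# Random feature table with arbitrary labels: exercises nestbc independently
# of the signal pipeline. Guarantees every activity in `acts` occurs.
random_feature_table <- function(n, n_feat, labels) {
  tibble::tibble(
    window = seq_len(n), start = seq_len(n), label = labels,
    !!!stats::setNames(
      lapply(seq_len(n_feat), function(j) stats::rnorm(n)),
      paste0("f", seq_len(n_feat))))
}

random_nest_instance <- function(acts, outlier_labels, n_train, n_test,
                                 n_feat = 5) {
  train_labels <- c(acts, sample(acts, n_train - length(acts), replace = TRUE))
  test_labels <- sample(c(acts, outlier_labels), n_test, replace = TRUE)
  list(train = random_feature_table(n_train, n_feat, sample(train_labels)),
       test = random_feature_table(n_test, n_feat, test_labels))
}

# A linearly separable labeled feature table: class centroids far apart
# relative to unit noise, so any sensible learner recovers the labels.
separable_feature_table <- function(n_per_class, classes, n_feat = 6,
                                    gap = 8) {
  k <- length(classes)
  rows <- lapply(seq_len(k), function(i) {
    center <- rep(0, n_feat)
    center[((i - 1) %% n_feat) + 1] <- gap * i
    matrix(stats::rnorm(n_per_class * n_feat), n_per_class, n_feat) +
      matrix(center, n_per_class, n_feat, byrow = TRUE)
  })
  X <- do.call(rbind, rows)
  tibble::tibble(
    window = seq_len(nrow(X)), start = seq_len(nrow(X)),
    label = rep(classes, each = n_per_class),
    !!!stats::setNames(as.data.frame(X), paste0("f", seq_len(n_feat))))
}
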
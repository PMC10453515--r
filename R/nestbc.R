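#' Split a feature dataset into training and test sets
#'
#' Seeded random partition in the standard 70/30 proportion by default. The
#' training size is `round(train_fraction * n)` with halves rounded away
#' from zero.
#'
#' @param data A feature dataset tibble (one row per window).
#' @param train_fraction Fraction of rows assigned to training, in (0, 1).
#' @param seed Integer seed for the partition.
#' @return A list with tibbles `train` and `test`; together they cover every
#'   input row exactly once.
#' @export
split_train_test <- function(data, train_fraction = 0.7, seed = 1L) {
  n <- nrow(data)
  if (n < 2L) abort("need at least 2 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("`train_fraction` must be in (0, 1)")
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  seed_rng(seed)
  idx <- sample.int(n, n_train)
  list(train = data[sort(idx), , drop = FALSE],
       test = data[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

#' Relabel a dataset for one-vs-rest binary classification
#'
#' Marks rows of the target activity with class 1 and every other row with
#' class 0; the input is not modified.
#'
#' @param data A tibble with a `label` column.
#' @param activity The positive-class activity name (may be absent, giving
#'   an all-zero labeling).
#' @return A copy of `data` whose `label` column is integer 0/1.
#' @export
relabel_binary <- function(data, activity) {
  data$label <- as.integer(data$label == activity)
  data
}

#' Configure the base binary classifier
#'
#' The published hyperparameters: k-nearest neighbors with 7 neighbors, CART
#' with unconstrained depth, SVM with library defaults (RBF kernel), Gaussian
#' naive Bayes with no parameters, and logistic regression capped at 500
#' iterations. The `oracle` base predicts positive exactly when a record's
#' true label equals the current activity; it exists to test the elimination
#' logic independently of learning quality and should not be used on real
#' data.
#'
#' @param algorithm One of `"knn"`, `"cart"`, `"svm"`, `"nb"`, `"lr"`,
#'   `"oracle"`.
#' @param knn_k Number of neighbors for `knn`.
#' @param lr_maxit Maximum iterations for `lr`.
#' @return A `base_classifier` config list.
#' @export
base_classifier <- function(algorithm = c("knn", "cart", "svm", "nb", "lr",
                                          "oracle"),
                            knn_k = 7L, lr_maxit = 500L) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, knn_k = as.integer(knn_k),
                 lr_maxit = as.integer(lr_maxit),
                 standardize = algorithm %in% c("knn", "svm", "lr")),
            class = "base_classifier")
}

# Fit-and-predict for one level. X matrices are numeric; y_train is 0/1.
# Returns integer 0/1 predictions for X_test rows. truth_test is only
# consulted by the oracle base.
predict_level <- function(base, X_train, y_train, X_test, truth_test,
                          activity) {
  if (base$algorithm == "oracle")
    return(as.integer(truth_test == activity))
  if (nrow(X_test) == 0L) return(integer(0))

  # Degenerate single-class pool: every learner would refuse or be trivial;
  # predict that class.
  if (length(unique(y_train)) == 1L)
    return(rep(y_train[1], nrow(X_test)))

  if (base$standardize) {
    mu <- colMeans(X_train)
    sg <- apply(X_train, 2, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    X_train <- sweep(sweep(X_train, 2, mu), 2, sg, "/")
    X_test <- sweep(sweep(X_test, 2, mu), 2, sg, "/")
  }
  yf <- factor(y_train, levels = c(0, 1))

  pred <- switch(
    base$algorithm,
    knn = {
      k <- min(base$knn_k, nrow(X_train))
      class::knn(X_train, X_test, cl = yf, k = k)
    },
    cart = {
      df <- as.data.frame(X_train); df$.y <- yf
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = 30, cp = 0, minsplit = 2,
                            xval = 0))
      predict(fit, as.data.frame(X_test), type = "class")
    },
    svm = {
      fit <- e1071::svm(X_train, yf)
      predict(fit, X_test)
    },
    nb = {
      fit <- e1071::naiveBayes(as.data.frame(X_train), yf)
      predict(fit, as.data.frame(X_test), type = "class")
    },
    lr = {
      df <- as.data.frame(X_train); df$.y <- y_train
      fit <- suppressWarnings(
        glm(.y ~ ., data = df, family = binomial(),
            control = list(maxit = base$lr_maxit)))
      p <- suppressWarnings(
        predict(fit, as.data.frame(X_test), type = "response"))
      factor(as.integer(p > 0.5), levels = c(0, 1))
    }
  )
  as.integer(as.character(pred))
}

#' Nested one-vs-rest elimination classification
#'
#' The core procedure: known activities are visited one per level, in a
#' seeded random order by default. At each level the remaining training pool
#' is relabeled one-vs-rest for the level's activity, a binary base
#' classifier is fitted and applied to the remaining test pool; test records
#' predicted positive receive that activity as their final label and leave
#' the pool, while training records whose true label is the level's activity
#' leave the training pool. Test records that survive every level are
#' reported as outliers — segments of activities the model was never taught.
#'
#' Test-pool removal is prediction-driven (test labels are treated as
#' unknown); training-pool removal is true-label-driven: after an activity's
#' level, its training records no longer participate. Training records whose
#' label is outside `activities` are never positives at any level — they act
#' as permanent negative background, the way unknown-activity segments that
#' fall into the training split behave in practice. Features are
#' standardized with the current training pool's mean and standard deviation
#' before scale-sensitive bases (knn, svm, lr).
#'
#' @param train,test Feature dataset tibbles with a `label` column; every
#'   activity in `activities` must occur in `train`, and `test` may contain
#'   labels outside `activities` (true outliers).
#' @param activities Character vector of known activity names (the set A).
#' @param base A [base_classifier()] or an algorithm name.
#' @param order `NULL` for a seeded uniform shuffle of `activities`, or an
#'   explicit permutation of `activities` (results are order-dependent).
#' @param seed Integer seed (activity order, knn tie-breaks).
#' @return A `nestbc` object: `levels` (per-level fitted summary with binary
#'   confusion counts and ACC/PP/SE/SP), `verdicts` (one row per test
#'   record: true label, final assignment or `"OUTLIER"`, assigning level),
#'   `activities` (the order used), `base`, `seed`.
#' @examples
#' pro <- default_activity_profiles()
#' sch <- activity_schedule(rep(c("sitting", "walking"), 4), rep(8, 8), 0.05)
#' feats <- build_feature_dataset(generate_stream(pro, sch, 1), window_spec(40))
#' sp <- split_train_test(feats, 0.7, seed = 2)
#' fit <- nest_classify(sp$train, sp$test, c("sitting", "walking"),
#'                      base = "knn", seed = 3)
#' tidy(fit)
#' @export
nest_classify <- function(train, test, activities, base = "knn",
                          order = NULL, seed = 1L) {
  if (is.character(base)) base <- base_classifier(base)
  stopifnot(inherits(base, "base_classifier"))
  activities <- as.character(activities)
  if (anyDuplicated(activities)) abort("`activities` must be unique")
  missing <- setdiff(activities, unique(train$label))
  if (length(missing) > 0)
    abort(paste0("activity absent from training data: ",
                 paste(missing, collapse = ", ")))

  seed_rng(seed)
  ord <- if (is.null(order)) sample(activities) else as.character(order)
  if (!setequal(ord, activities) || length(ord) != length(activities))
    abort("`order` must be a permutation of `activities`")

  cols <- setdiff(feature_cols(train), "label")
  X_train_all <- as.matrix(train[, cols, drop = FALSE])
  X_test_all <- as.matrix(test[, cols, drop = FALSE])
  y_train_all <- train$label
  y_test_all <- test$label

  train_pool <- seq_len(nrow(train))
  test_pool <- seq_len(nrow(test))
  verdict <- rep(NA_character_, nrow(test))
  verdict_level <- rep(NA_integer_, nrow(test))

  lv <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    a <- ord[i]
    y_tr <- as.integer(y_train_all[train_pool] == a)
    if (sum(y_tr) == 0L)
      abort(paste0("level ", i, " (", a, "): no remaining training positives"))

    n_test_in <- length(test_pool)
    pred <- predict_level(base, X_train_all[train_pool, , drop = FALSE], y_tr,
                          X_test_all[test_pool, , drop = FALSE],
                          y_test_all[test_pool], a)

    truth <- as.integer(y_test_all[test_pool] == a)
    cm <- c(TP = sum(pred == 1 & truth == 1), FP = sum(pred == 1 & truth == 0),
            TN = sum(pred == 0 & truth == 0), FN = sum(pred == 0 & truth == 1))
    met <- if (n_test_in > 0) binary_metrics(cm) else
      tibble::tibble(ACC = NA_real_, PP = NA_real_, SE = NA_real_,
                     SP = NA_real_)

    assigned <- test_pool[pred == 1]
    verdict[assigned] <- a
    verdict_level[assigned] <- i
    test_pool <- test_pool[pred != 1]
    n_train_in <- length(train_pool)
    removed_train <- sum(y_tr)
    train_pool <- train_pool[y_train_all[train_pool] != a]

    lv[[i]] <- tibble::tibble(
      level = i, activity = a, n_train = n_train_in,
      n_train_removed = removed_train, n_test_in = n_test_in,
      n_assigned = length(assigned),
      TP = cm[["TP"]], FP = cm[["FP"]], TN = cm[["TN"]], FN = cm[["FN"]],
      ACC = met$ACC, PP = met$PP, SE = met$SE, SP = met$SP)
  }

  verdict[test_pool] <- OUTLIER_LABEL
  out <- list(
    levels = dplyr::bind_rows(lv),
    verdicts = tibble::tibble(
      row = seq_len(nrow(test)),
      truth = y_test_all,
      verdict = verdict,
      level = verdict_level),
    activities = ord,
    base = base,
    seed = seed)
  class(out) <- "nestbc"
  out
}

#' @export
print.nestbc <- function(x, ...) {
  cat("Nested binary classifier (", x$base$algorithm, " base)\n", sep = "")
  cat("Activity order:", paste(x$activities, collapse = " -> "), "\n")
  cat("Test records:", nrow(x$verdicts),
      "| outliers:", sum(x$verdicts$verdict == OUTLIER_LABEL), "\n")
  print(x$levels[, c("level", "activity", "n_test_in", "n_assigned",
                     "ACC", "PP", "SE", "SP")])
  invisible(x)
}

#' @describeIn nest_classify Per-level summary: one row per nesting level
#'   with confusion counts and ACC/PP/SE/SP.
#' @param x,object A `nestbc` object.
#' @param ... Unused.
#' @method tidy nestbc
#' @export
tidy.nestbc <- function(x, ...) x$levels

#' @describeIn nest_classify One-row model summary: level count, test size,
#'   assigned and outlier counts.
#' @method glance nestbc
#' @export
glance.nestbc <- function(x, ...) {
  tibble::tibble(
    n_levels = nrow(x$levels),
    n_test = nrow(x$verdicts),
    n_assigned = sum(x$verdicts$verdict != OUTLIER_LABEL),
    n_outliers = sum(x$verdicts$verdict == OUTLIER_LABEL),
    base = x$base$algorithm,
    seed = x$seed)
}

#' @describeIn nest_classify Bar chart of records assigned per level, with
#'   the residual outlier set as the final bar.
#' @method autoplot nestbc
#' @export
autoplot.nestbc <- function(object, ...) {
  lv <- object$levels
  df <- dplyr::bind_rows(
    tibble::tibble(stage = paste0("L", lv$level, ": ", lv$activity),
                   n = lv$n_assigned),
    tibble::tibble(stage = OUTLIER_LABEL,
                   n = sum(object$verdicts$verdict == OUTLIER_LABEL)))
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "test records",
                  title = "Records removed per nesting level") +
    ggplot2::theme_minimal()
}
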
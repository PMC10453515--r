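test_that("70/30 split produces the stated sizes and is seed-stable", {
  d <- random_feature_table(100, 3, sample(letters[1:4], 100, replace = TRUE))
  sp <- split_train_test(d, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_equal(dplyr::bind_rows(sp$train, sp$test) |> dplyr::arrange(window),
               d)
  sp2 <- split_train_test(d, 0.7, seed = 1)
  expect_identical(sp$train$window, sp2$train$window)

  odd <- split_train_test(d[1:7, ], 0.5, seed = 2)
  expect_equal(nrow(odd$train), 4)   # half rounded away from zero
  expect_equal(nrow(odd$test), 3)
})

test_that("one-vs-rest relabeling marks exactly the target activity", {
  d <- tibble::tibble(label = c("a", "b", "a", "c"), f1 = 1:4)
  expect_equal(relabel_binary(d, "a")$label, c(1L, 0L, 1L, 0L))
  expect_equal(relabel_binary(d, "zz")$label, rep(0L, 4))
  set.seed(8)
  labs <- sample(letters[1:5], 60, replace = TRUE)
  d2 <- tibble::tibble(label = labs, f1 = rnorm(60))
  expect_equal(sum(relabel_binary(d2, "c")$label), sum(labs == "c"))
  expect_equal(d2$label, labs)  # input untouched
})

test_that("one level is run per known activity", {
  set.seed(1)
  inst <- random_nest_instance(letters[1:4], "z", 40, 20)
  fit <- nest_classify(inst$train, inst$test, letters[1:4], base = "oracle",
                       seed = 1)
  expect_equal(nrow(fit$levels), 4)
  expect_setequal(fit$activities, letters[1:4])
})

test_that("the oracle base eliminates exactly the known-label records", {
  train <- random_feature_table(10, 3, rep(c("a", "b"), 5))
  test <- random_feature_table(4, 3, c("a", "a", "b", "c"))
  fit <- nest_classify(train, test, c("a", "b"), base = "oracle", seed = 1)
  expect_equal(sum(fit$verdicts$verdict == "a"), 2)
  expect_equal(sum(fit$verdicts$verdict == "b"), 1)
  expect_equal(fit$verdicts$verdict[fit$verdicts$truth == "c"], "OUTLIER")
})

test_that("a test pool with no recognizable records ends fully as outliers", {
  train <- random_feature_table(8, 3, rep("a", 8))
  test <- random_feature_table(5, 3, rep(c("b", "c"), length.out = 5))
  fit <- nest_classify(train, test, "a", base = "oracle", seed = 1)
  expect_true(all(fit$verdicts$verdict == "OUTLIER"))
})

test_that("an emptied test pool makes later levels no-ops with empty outliers", {
  train <- random_feature_table(12, 3, rep(c("a", "b", "c"), 4))
  test <- random_feature_table(4, 3, rep("a", 4))
  fit <- nest_classify(train, test, c("a", "b", "c"), base = "oracle",
                       order = c("a", "b", "c"), seed = 1)
  expect_equal(fit$levels$n_test_in, c(4, 0, 0))
  expect_equal(fit$levels$n_assigned, c(4, 0, 0))
  expect_equal(sum(fit$verdicts$verdict == "OUTLIER"), 0)
})

test_that("a missing training activity is an error naming the activity", {
  train <- random_feature_table(10, 3, rep("a", 10))
  test <- random_feature_table(4, 3, rep("a", 4))
  expect_error(nest_classify(train, test, c("a", "b"), base = "oracle"),
               "b")
})

test_that("explicit activity order is honored and recorded", {
  set.seed(2)
  inst <- random_nest_instance(c("a", "b", "c"), character(), 30, 10)
  fit <- nest_classify(inst$train, inst$test, c("a", "b", "c"),
                       base = "oracle", order = c("c", "a", "b"), seed = 1)
  expect_equal(fit$activities, c("c", "a", "b"))
  expect_equal(fit$levels$activity, c("c", "a", "b"))
  expect_error(nest_classify(inst$train, inst$test, c("a", "b", "c"),
                             base = "oracle", order = c("a", "b")),
               "permutation")
})

test_that("oracle equivalence: outliers are exactly the labels outside A", {
  # property over arbitrary random datasets
  set.seed(77)
  for (i in 1:40) {
    k <- sample(2:5, 1)
    acts <- letters[1:k]
    inst <- random_nest_instance(acts, c("x", "y", "z"),
                                 n_train = sample(c(2 * k, 40), 1),
                                 n_test = sample(5:60, 1))
    fit <- nest_classify(inst$train, inst$test, acts, base = "oracle",
                         seed = i)
    expect_identical(fit$verdicts$verdict == "OUTLIER",
                     !(inst$test$label %in% acts))
    # and every recognized record got its true label (oracle is exact)
    rec <- fit$verdicts$verdict != "OUTLIER"
    expect_identical(fit$verdicts$verdict[rec], inst$test$label[rec])
  }
})

test_that("assigned plus outliers partition the test set for every base", {
  set.seed(99)
  bases <- c("knn", "cart", "svm", "nb", "lr", "oracle")
  for (i in 1:30) {
    b <- bases[(i %% length(bases)) + 1]
    inst <- random_nest_instance(c("a", "b", "c"), "q", 30, 15)
    fit <- nest_classify(inst$train, inst$test, c("a", "b", "c"),
                         base = b, seed = i)
    expect_equal(sum(fit$levels$n_assigned) +
                   sum(fit$verdicts$verdict == "OUTLIER"),
                 nrow(inst$test))
    expect_false(anyNA(fit$verdicts$verdict))
    # monotone shrinkage of the test pool
    expect_true(all(diff(fit$levels$n_test_in) <= 0))
  }
})

test_that("real learners recover a separable labeling near-perfectly", {
  set.seed(5)
  d <- separable_feature_table(40, c("a", "b", "c"))
  sp <- split_train_test(d, 0.7, seed = 1)
  for (b in c("knn", "cart", "lr")) {
    fit <- nest_classify(sp$train, sp$test, c("a", "b", "c"), base = b,
                         seed = 2)
    acc <- mean(fit$verdicts$verdict == fit$verdicts$truth)
    expect_gt(acc, 0.9)
  }
})

test_that("tidy, glance and autoplot expose the fitted cascade", {
  set.seed(3)
  inst <- random_nest_instance(c("a", "b"), "z", 20, 10)
  fit <- nest_classify(inst$train, inst$test, c("a", "b"), base = "oracle",
                       seed = 4)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("level", "activity", "n_train", "n_train_removed",
                     "n_test_in", "n_assigned", "TP", "FP", "TN", "FN",
                     "ACC", "PP", "SE", "SP"))
  gl <- glance(fit)
  expect_equal(gl$n_assigned + gl$n_outliers, gl$n_test)
  expect_s3_class(autoplot(fit), "ggplot")
})
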
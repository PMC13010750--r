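separable_xy <- function(n_per = 20, seed = 2) {
  withr::with_seed(seed, {
    x <- data.frame(a = c(stats::rnorm(n_per, -5), stats::rnorm(n_per, 5)),
                    b = stats::rnorm(2 * n_per))
    y <- rep(c("lo", "hi"), each = n_per)
  })
  list(x = x, y = y)
}

test_that("stratified split keeps class proportions and is deterministic", {
  y <- rep(c("a", "b", "c", "d"), each = 25)
  s <- stratified_split(y, 0.2, seed = 4)
  expect_identical(sort(c(s$train, s$test)), 1:100)
  expect_length(intersect(s$train, s$test), 0)
  expect_true(all(table(y[s$test]) == 5))
  expect_identical(stratified_split(y, 0.2, seed = 4), s)

  tiny <- stratified_split(rep(c("a", "b"), each = 2), 0.5, seed = 1)
  expect_identical(as.vector(table(rep(c("a", "b"), each = 2)[tiny$test])), c(1L, 1L))

  expect_error(stratified_split(c("a", "a", "b"), 0.2), "singleton")
  expect_error(stratified_split(y, 0), "test_fraction")
})

test_that("forests separate separable data and are seed-deterministic", {
  d <- separable_xy()
  model <- train_forest(d$x, d$y, forest_spec(100, seed = 9))
  prob <- predict(model, d$x)
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  expect_identical(mean(pred == d$y), 1)

  again <- train_forest(d$x, d$y, forest_spec(100, seed = 9))
  expect_equal(predict(again, d$x), prob)

  stump <- train_forest(d$x, d$y, forest_spec(1, max_depth = 1, seed = 1))
  expect_lte(nrow(unique(predict(stump, d$x))), 2)

  expect_error(train_forest(d$x[0, ], character(0)), "empty")
})

test_that("log loss reproduces its closed forms", {
  perfect <- diag(4)
  colnames(perfect) <- c("a", "b", "c", "d")
  expect_equal(log_loss(perfect, c("a", "b", "c", "d")), 0, tolerance = 1e-9)
  uniform <- matrix(0.25, 5, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  expect_equal(log_loss(uniform, rep("a", 5)), log(4), tolerance = 1e-12)
  # clipping keeps a confidently wrong prediction finite
  wrong <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_lt(log_loss(wrong, "b"), 35)
})

test_that("metrics match hand-computed values from a printed confusion matrix", {
  cm <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
               dimnames = list(c("c0", "c1"), c("c0", "c1")))
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(unname(m$precision["c0"]), 8 / 9, tolerance = 1e-12)
  expect_equal(unname(m$recall["c0"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(m$f1["c0"]), 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8),
               tolerance = 1e-12)
})

test_that("evaluate ties metrics to the confusion matrix on a real split", {
  g <- generate_cohort(cohort_config(400, seed = 6))
  labs <- label_cohort(g$cohort)
  x <- feature_table(g$cohort)
  s <- stratified_split(labs$hl_type, seed = 6)
  model <- train_forest(x[s$train, ], labs$hl_type[s$train], forest_spec(100, seed = 6))
  rep <- evaluate(model, x[s$test, ], labs$hl_type[s$test])
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_equal(as.vector(rowSums(rep$confusion)),
               as.vector(as.numeric(table(factor(labs$hl_type[s$test],
                                                 levels = rownames(rep$confusion))))))
  expect_gte(rep$log_loss, 0)
})

test_that("cross-validation sits at chance for shuffled balanced labels", {
  withr::with_seed(10, {
    x <- data.frame(a = stats::rnorm(240), b = stats::rnorm(240))
    y <- sample(rep(c("p", "q", "r", "s"), each = 60))
  })
  cv <- cross_validate(x, y, forest_spec(100, seed = 10), folds = 5, seed = 10)
  expect_gt(cv$mean, 0.13)
  expect_lt(cv$mean, 0.37)
  expect_identical(cross_validate(x, y, forest_spec(100, seed = 10), folds = 5,
                                  seed = 10), cv)
  expect_error(cross_validate(x, c("a", y[-1]), forest_spec(), folds = 60), "folds")
})

test_that("grid search returns the arg-max with the smaller-model tie-break", {
  d <- separable_xy(n_per = 25)
  one <- grid_search(d$x, d$y, list(n_estimators = 50L), folds = 3, seed = 5)
  expect_identical(one$best$n_estimators, 50L)
  expect_identical(nrow(one$scores), 1L)

  # perfectly separable -> every spec scores 1.0, tie-break picks the smallest
  g <- grid_search(d$x, d$y, list(n_estimators = c(150L, 50L),
                                  max_depth = c(20L, 10L)),
                   folds = 3, seed = 5)
  expect_identical(g$best$n_estimators, 50L)
  expect_identical(g$best$max_depth, 10L)
  expect_identical(nrow(g$scores), 4L)
  expect_error(grid_search(d$x, d$y, list(n_estimators = integer(0))), "empty")
})

test_that("feature importances are normalized and favor audiometric inputs", {
  g <- generate_cohort(cohort_config(500, seed = 12))
  labs <- label_cohort(g$cohort)
  x <- feature_table(g$cohort)
  x$ballast <- 1  # constant column never chosen by any split
  model <- train_forest(x, labs$hl_type, forest_spec(200, seed = 12))
  w <- feature_importances(model)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_identical(unname(w["ballast"]), 0)
  flags <- c("diabetes", "hypertension", "cardiovascular", "noise_exposure",
             "smoking", "alcohol")
  pta_cols <- as.vector(outer(c("left_air_", "right_air_"),
                              c(500, 1000, 2000, 4000), paste0))
  expect_lt(max(w[flags]), min(w[pta_cols]))
  expect_error(feature_importances(list()), "hl_forest")
})

test_that("strategy comparison emits the full report deterministically", {
  g <- generate_cohort(cohort_config(600, seed = 8))
  cmp <- compare_strategies(g$cohort, seed = 8, spec = forest_spec(100))
  expect_identical(cmp$report$metric,
                   c("test_accuracy_pct", "cv_mean_accuracy_pct", "cv_std_pct",
                     "f1_sensorineural", "f1_conductive", "f1_mixed", "f1_normal",
                     "log_loss"))
  expect_identical(names(cmp$report), c("metric", "rf_kmeans", "rf_ontology"))
  expect_false(anyNA(cmp$report$rf_ontology))
  cmp2 <- compare_strategies(g$cohort, seed = 8, spec = forest_spec(100))
  expect_identical(cmp$report, cmp2$report)
})
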
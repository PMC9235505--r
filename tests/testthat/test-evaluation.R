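test_that("80/20 split is stratified, disjoint and exhaustive", {
  y <- rep(c(0, 1), each = 5)
  sp <- split_80_20(y, seed = 3)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(unique(y[sp$train]), c(0, 1))
  expect_setequal(unique(y[sp$test]), c(0, 1))
  # determinism
  expect_identical(split_80_20(y, seed = 3), sp)
  expect_error(split_80_20(c(0, 0, 0, 0, 1), seed = 1), "fewer than 2")
  expect_error(split_80_20(c(0, 1, 0, 1), seed = 1), "at least 5")
})

test_that("z-normalization uses training statistics with sample SD", {
  train <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  test <- cbind(a = c(2, 4), b = c(7, 5))
  zs <- zscore_fit_apply(train, test)
  # column (1,2,3): sample SD = 1 -> (-1, 0, 1)
  expect_equal(zs$train[, "a"], c(-1, 0, 1))
  # constant column -> zeros everywhere, no NaN
  expect_equal(zs$train[, "b"], c(0, 0, 0))
  expect_equal(zs$test[, "b"], c(0, 0))
  expect_false(anyNA(zs$test))
  # test value equal to the train mean maps to 0
  expect_equal(unname(zs$test[1, "a"]), 0)
  expect_equal(unname(zs$test[2, "a"]), 2)
  expect_equal(zs$means, c(a = 2, b = 5))
  expect_equal(zs$sds, c(a = 1, b = 0))
})

test_that("AUROC matches the brute-force pairwise oracle, ties included", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(1:6, c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(auroc(rep(1, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  set.seed(2024)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    expect_equal(auroc(scores, labels), auroc_bruteforce(scores, labels))
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "classes")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(4)
  scores <- rnorm(50)
  labels <- sample(c(0, 1), 50, replace = TRUE)
  labels[1:2] <- c(0, 1)
  a <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), a)
  expect_equal(auroc(3 * scores - 10, labels), a)
})

test_that("inner CV returns a grid value, short-circuits singleton grids", {
  data <- small_synthetic()
  sets <- resolve_sets(data$sets, colnames(data$X))
  one <- inner_cv_select_lambda(data$X, data$y, sets, D = 6L, grid = 0.7)
  expect_identical(one$multiplier, 0.7)
  cv <- inner_cv_select_lambda(data$X, data$y, sets, D = 6L,
                               grid = c(0.9, 0.6), seed = 5, tol = 1e-3)
  expect_true(cv$multiplier %in% c(0.9, 0.6))
  expect_length(cv$cv_auroc, 2L)
  expect_error(
    inner_cv_select_lambda(data$X, data$y, sets, D = 6L, grid = numeric(0)),
    "non-empty")
  expect_error(
    inner_cv_select_lambda(data$X, data$y, sets, D = 6L, grid = c(0.5, 1.2)),
    "in \\(0, 1\\]")
})

test_that("deviance criterion is accepted and returns a grid value", {
  data <- small_synthetic()
  sets <- resolve_sets(data$sets, colnames(data$X))
  cv <- inner_cv_select_lambda(data$X, data$y, sets, D = 6L,
                               grid = c(0.9, 0.6), seed = 5,
                               criterion = "deviance", tol = 1e-3)
  expect_true(cv$multiplier %in% c(0.9, 0.6))
  expect_true(all(cv$cv_auroc <= 0))  # negative mean deviance
  expect_error(
    inner_cv_select_lambda(data$X, data$y, sets, D = 6L, grid = c(0.9, 0.6),
                           criterion = "gini"),
    "should be one of")
})

test_that("CV ties break toward the larger (sparser) multiplier", {
  # pure-noise labels: every multiplier gives an all-zero model, constant
  # validation scores and AUROC 0.5 in every fold -> tie on the whole grid
  set.seed(88)
  X <- matrix(rnorm(60 * 20), 60, 20,
              dimnames = list(NULL, sprintf("G%02d", 1:20)))
  y <- rep(c(0, 1), 30)
  sets <- resolve_sets(
    feature_set_collection(list(S1 = sprintf("G%02d", 1:10),
                                S2 = sprintf("G%02d", 11:20))),
    colnames(X))
  cv <- inner_cv_select_lambda(X, y, sets, D = 4L,
                               grid = c(0.6, 0.9, 0.8), seed = 10)
  expect_identical(cv$multiplier, 0.9)
})

test_that("stratified folds keep both classes in every fold", {
  y <- rep(c(0, 1), c(12, 8))
  fold <- makl:::make_folds(y, 4L, seed = 6)
  for (f in 1:4) expect_setequal(unique(y[fold == f]), c(0, 1))
  expect_error(makl:::make_folds(rep(c(0, 1), c(18, 2)), 4L, seed = 1),
               "5 attempts")
})

test_that("replication harness aggregates selection frequencies correctly", {
  data <- small_synthetic()
  sets <- resolve_sets(data$sets, colnames(data$X))
  rep1 <- run_replications(data$X, data$y, sets, D = 6L, R = 2L,
                           grid = c(0.9, 0.6), seed = 42,
                           cv_tol = 1e-3, tol = 1e-4)
  expect_s3_class(rep1, "evaluation_report")
  expect_length(rep1$auroc_per_replication, 2L)
  expect_true(all(rep1$auroc_per_replication >= 0 &
                    rep1$auroc_per_replication <= 1))
  expect_true(all(rep1$selection$frequency >= 0 &
                    rep1$selection$frequency <= 1))
  expect_lte(rep1$mean_sets_selected, length(sets$names))
  expect_identical(nrow(rep1$replications), 2L)
  # frequencies are multiples of 1/R
  expect_true(all(rep1$selection$frequency * 2 ==
                    round(rep1$selection$frequency * 2)))
})

test_that("earlier replications are unchanged when R grows", {
  data <- small_synthetic()
  sets <- resolve_sets(data$sets, colnames(data$X))
  r1 <- run_replications(data$X, data$y, sets, D = 6L, R = 1L,
                         grid = c(0.9, 0.6), seed = 7,
                         cv_tol = 1e-3, tol = 1e-4)
  r2 <- run_replications(data$X, data$y, sets, D = 6L, R = 2L,
                         grid = c(0.9, 0.6), seed = 7,
                         cv_tol = 1e-3, tol = 1e-4)
  expect_equal(r2$replications[1, ], r1$replications[1, ])
})
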
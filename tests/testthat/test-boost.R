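# the reference boosted-tree learner and its protocol helpers

test_that("gradients and hessians follow the stated loss derivatives", {
  gh <- gradients_hessians("squared", c(1, 2, 3), c(1, 2, 3))
  expect_identical(gh$g, c(0, 0, 0))
  expect_identical(gh$h, c(1, 1, 1))
  gh2 <- gradients_hessians("logistic", c(1, 0), c(0, 0))
  expect_equal(gh2$g, c(-0.5, 0.5))
  expect_equal(gh2$h, c(0.25, 0.25))
  s <- matrix(rnorm(12), 4, 3)
  gh3 <- gradients_hessians("softmax", c(1L, 2L, 3L, 1L), s)
  expect_equal(rowSums(gh3$proba), rep(1, 4), tolerance = 1e-12)
  expect_equal(rowSums(gh3$g), rep(0, 4), tolerance = 1e-12)
  expect_true(all(gh3$h >= 0))
  expect_error(gradients_hessians("hinge", 1, 1), "unknown loss")
})

test_that("split_gain evaluates the regularized formula exactly", {
  expect_identical(split_gain(2, 1, -2, 1, 0, 0), 4)
  expect_identical(split_gain(3, 2, 0, 0, 0, 0), 0)     # degenerate split
  g0 <- split_gain(1.3, 0.7, -2.1, 1.9, 0.5, 0)
  expect_equal(split_gain(1.3, 0.7, -2.1, 1.9, 0.5, 5), g0 - 5)
})

test_that("build_tree solves the textbook stump and stops on pure nodes", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  tr <- build_tree(x, g = c(0.5, 0.5, -0.5, -0.5), h = rep(1, 4),
                   params = list(max_depth = 1, reg_lambda = 0, gamma = 0,
                                 min_child_weight = 0))
  expect_false(tr$leaf)
  expect_identical(tr$threshold, 2.5)
  expect_identical(tr$left$weight, -0.5)
  expect_identical(tr$right$weight, 0.5)
  pure <- build_tree(x, g = rep(0, 4), h = rep(1, 4),
                     params = list(max_depth = 3, reg_lambda = 1,
                                   gamma = 0, min_child_weight = 0))
  expect_true(pure$leaf)
  expect_identical(pure$weight, 0)
})

test_that("separable classes are fit perfectly and prediction validates input", {
  set.seed(21)
  x <- rbind(matrix(rnorm(40), 20, 2),
             matrix(rnorm(40, mean = 4), 20, 2))
  y <- rep(c("lo", "hi"), each = 20)
  m <- gbtree(x, y, n_estimators = 50, seed = 1)
  expect_identical(mean(predict(m, x) == y), 1)
  proba <- predict(m, x, type = "prob")
  expect_equal(rowSums(proba), rep(1, 40), tolerance = 1e-12)
  expect_identical(colnames(proba), c("lo", "hi"))   # training order
  expect_error(predict(m, x[, 1, drop = FALSE]), "features")
  expect_error(gbtree(x, rep("one", 40)), "2 classes")
  # zero rounds: probabilities are the softmax of the class-prior scores
  m0 <- gbtree(x, y, n_estimators = 0, seed = 1)
  p0 <- predict(m0, x[1:3, ], type = "prob")
  expect_equal(unname(p0), matrix(0.5, 3, 2), tolerance = 1e-12)
})

test_that("constant targets are matched after one unshrunk round", {
  x <- matrix(rnorm(20), 10, 2)
  m <- gbtree(x, rep(7, 10), loss = "squared", n_estimators = 1,
              learning_rate = 1, seed = 1)
  expect_equal(unname(predict(m, x)), rep(7, 10), tolerance = 1e-12)
})

test_that("the training objective is non-increasing with full row and column sampling", {
  set.seed(5)
  x <- matrix(rnorm(200), 40, 5)
  y <- ifelse(x[, 1] + 0.5 * x[, 2] + rnorm(40, 0, 0.5) > 0, "a", "b")
  m <- gbtree(x, y, n_estimators = 60, seed = 2)
  expect_true(all(diff(m$objective_trace) <= 1e-9))
  yr <- x[, 1] + rnorm(40, 0, 0.2)
  mr <- gbtree(x, yr, loss = "squared", n_estimators = 40,
               learning_rate = 0.3, seed = 2)
  expect_true(all(diff(mr$objective_trace) <= 1e-9))
})

test_that("raising gamma never grows the tree ensemble", {
  set.seed(8)
  x <- matrix(rnorm(300), 60, 5)
  y <- ifelse(x[, 1] - x[, 3] + rnorm(60, 0, 0.8) > 0, "a", "b")
  sizes <- vapply(c(0, 0.5, 2, 8), function(gm)
    n_internal_nodes(gbtree(x, y, n_estimators = 10, gamma = gm,
                            seed = 3)), 0L)
  expect_true(all(diff(sizes) <= 0L))
})

test_that("models are seed-deterministic end to end and survive JSON round trips", {
  set.seed(30)
  x <- matrix(rnorm(240), 40, 6)
  y <- ifelse(x[, 2] > 0, "a", "b")
  m1 <- gbtree(x, y, n_estimators = 15, subsample = 0.8,
               colsample_bytree = 0.5, seed = 11)
  m2 <- gbtree(x, y, n_estimators = 15, subsample = 0.8,
               colsample_bytree = 0.5, seed = 11)
  expect_identical(m1$trees, m2$trees)
  expect_identical(predict(m1, x, type = "raw"),
                   predict(m2, x, type = "raw"))
  f <- withr::local_tempfile(fileext = ".json")
  write_gbtree(m1, f)
  m3 <- read_gbtree(f)
  expect_equal(predict(m3, x, type = "raw"), predict(m1, x, type = "raw"),
               tolerance = 1e-12)
  expect_identical(predict(m3, x), predict(m1, x))
})

test_that("label agreement with the established boosting library is high on shared data", {
  skip_if_not_installed("xgboost")
  spec <- cohort_spec(n_classes = 2, n_per_class = 25, n_features = 40,
                      n_discriminant = 6, fold_change = 2,
                      intensity_cv = 0.5, seed = 17)
  st <- simulate_table(spec)
  x <- scale(st$table$matrix)
  y <- st$labels
  m <- gbtree(x, y, n_estimators = 60, seed = 1)
  yi <- as.integer(factor(y, levels = unique(y))) - 1L
  xg <- xgboost::xgb.train(
    params = list(objective = "multi:softmax", num_class = 2L,
                  max_depth = 3, eta = 0.1, lambda = 1, gamma = 0,
                  min_child_weight = 1, subsample = 1,
                  colsample_bytree = 1, nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = yi), nrounds = 60)
  ours <- predict(m, x)
  theirs <- unique(y)[predict(xg, xgboost::xgb.DMatrix(x)) + 1L]
  expect_gte(mean(ours == theirs), 0.95)
})

test_that("gain importance lands on the features the model actually uses", {
  set.seed(12)
  x <- matrix(rnorm(600), 60, 10)
  y <- ifelse(x[, 4] > 0, "a", "b")   # single informative feature
  m <- gbtree(x, y, n_estimators = 20, seed = 1)
  imp <- feature_importance(m)
  expect_identical(names(imp)[1], "f4")
  expect_true(all(imp >= 0))
  expect_identical(length(imp), 10L)
  # on a marker table every positive-importance feature is a planted marker
  spec <- cohort_spec(n_classes = 2, n_per_class = 30, n_features = 100,
                      n_discriminant = 10, fold_change = 4,
                      intensity_cv = 0.3, seed = 23)
  st <- simulate_table(spec)
  ms <- gbtree(scale(st$table$matrix), st$labels, seed = 1)
  pos <- feature_importance(ms)
  pos <- as.integer(sub("f", "", names(pos)[pos > 0]))
  expect_gt(length(pos), 0L)
  expect_true(all(pos %in% st$truth$markers))
})

test_that("the stratified split respects proportions and seeds", {
  y <- rep(letters[1:6], each = 6)
  sp <- train_test_split(y, test_fraction = 0.33, seed = 4)
  expect_identical(length(sp$test), 12L)
  expect_true(all(table(y[sp$test]) == 2L))
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  expect_identical(train_test_split(y, seed = 4), sp)
  expect_error(train_test_split(c("a", "a", "b"), seed = 1), "2 samples")
  spec <- cohort_spec(n_classes = 3, n_per_class = 8, n_features = 10,
                      n_discriminant = 2, seed = 2)
  st <- simulate_table(spec)
  tsp <- train_test_split(st$table, seed = 9)
  expect_identical(sort(c(tsp$train$sample_ids, tsp$test$sample_ids)),
                   sort(st$table$sample_ids))
  expect_length(intersect(tsp$train$sample_ids, tsp$test$sample_ids), 0L)
})

test_that("grid search scores every grid point and prefers the stronger setting", {
  set.seed(2)
  x <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, 3), 30, 2))
  y <- rep(c("a", "b"), each = 30)
  grid <- data.frame(n_estimators = c(1, 60), max_depth = c(1, 3),
                     learning_rate = c(0.01, 0.3))
  res <- grid_search_cv(x, y, grid, k_folds = 5, seed = 3)
  expect_identical(nrow(res$cv_table), 2L)
  expect_identical(res$best_params$n_estimators, 60)
  one <- grid_search_cv(x, y, grid[2, , drop = FALSE], k_folds = 3,
                        seed = 3)
  expect_identical(nrow(one$cv_table), 1L)
  expect_warning(
    grid_search_cv(x[c(1:3, 31:33), ], y[c(1:3, 31:33)],
                   grid[2, , drop = FALSE], k_folds = 5, seed = 1),
    "folds")
})

test_that("comparator models share the predict contract", {
  set.seed(19)
  x <- rbind(matrix(rnorm(80), 20, 4), matrix(rnorm(80, 3), 20, 4))
  colnames(x) <- paste0("v", 1:4)
  y <- rep(c("a", "b"), each = 20)
  pls <- comparator_fit("plsda", x, y, params = list(n_components = 1))
  expect_identical(mean(predict(pls, x) == y), 1)
  scores <- predict(pls, x, type = "prob")
  expect_equal(unname(rowSums(scores)), rep(1, 40), tolerance = 1e-6)
  for (kind in c("svm_rbf", "rf")) {
    m <- comparator_fit(kind, x, y, params = list(seed = 1))
    expect_true(all(predict(m, x) %in% c("a", "b")))
    pr <- predict(m, x, type = "prob")
    expect_identical(colnames(pr), c("a", "b"))
    expect_equal(unname(rowSums(pr)), rep(1, 40), tolerance = 1e-6)
  }
  expect_error(comparator_fit("mlp", x, y), "arg")
})
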
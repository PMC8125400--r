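# confusion-matrix metrics and ROC analysis

test_that("the confusion matrix counts and the worked binary example agree", {
  y_true <- c("+", "+", "+", "+", "+", "-", "-", "-", "-", "-")
  y_pred <- c("+", "+", "+", "-", "-", "-", "-", "-", "-", "+")
  cm <- confusion(y_true, y_pred, classes = c("+", "-"))
  expect_identical(cm["+", "+"], 3L)   # TP
  expect_identical(cm["+", "-"], 2L)   # FN
  expect_identical(cm["-", "-"], 4L)   # TN
  expect_identical(cm["-", "+"], 1L)   # FP
  expect_identical(sum(cm), 10L)
  expect_equal(accuracy(cm), 0.7)
  expect_equal(as.numeric(precision(cm, "+")), 0.75)
  expect_equal(as.numeric(recall(cm, "+")), 0.6)
  expect_equal(as.numeric(specificity(cm, "+")), 0.8)
  expect_equal(as.numeric(f1(cm, "+")), 2 * 0.75 * 0.6 / 1.35,
               tolerance = 1e-12)
  # permuting the class order leaves accuracy unchanged
  expect_equal(accuracy(confusion(y_true, y_pred, classes = c("-", "+"))),
               0.7)
  expect_error(confusion(y_true, y_pred, classes = "+"), "not in")
  perfect <- confusion(y_true, y_true, classes = c("+", "-"))
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)
  expect_equal(accuracy(perfect), 1)
  expect_equal(as.numeric(f1(perfect, "+")), 1)
})

test_that("degenerate zero denominators return flagged zeros", {
  cm <- confusion(c("a", "a", "b"), c("b", "b", "b"),
                  classes = c("a", "b"))
  p <- precision(cm, "a")      # no predicted positives
  expect_identical(as.numeric(p), 0)
  expect_true(attr(p, "degenerate"))
  expect_identical(as.numeric(recall(cm, "a")), 0)
  expect_true(attr(f1(cm, "a"), "degenerate"))
})

test_that("macro metrics average the one-vs-rest values", {
  set.seed(14)
  y_true <- sample(c("x", "y", "z"), 60, replace = TRUE)
  y_pred <- ifelse(runif(60) < 0.7, y_true,
                   sample(c("x", "y", "z"), 60, replace = TRUE))
  cm <- confusion(y_true, y_pred, classes = c("x", "y", "z"))
  mm <- macro_metrics(cm)
  byhand <- vapply(c("x", "y", "z"), function(cl)
    as.numeric(recall(cm, cl)), 0)
  expect_equal(unname(mm$macro["recall"]), mean(byhand))
  expect_identical(nrow(mm$per_class), 3L)
  # 2-class case reduces to the binary definitions of the positive class
  cb <- confusion(c("p", "p", "n"), c("p", "n", "n"),
                  classes = c("p", "n"))
  expect_equal(macro_metrics(cb)$per_class$recall[1],
               as.numeric(recall(cb, "p")))
  # balanced perfect predictions: every mean is 1
  cp <- confusion(rep(c("x", "y"), 5), rep(c("x", "y"), 5))
  expect_true(all(macro_metrics(cp)$macro == 1))
})

test_that("ROC curves follow the threshold convention and the AUC identities", {
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  perfect <- roc_curve(c(0.9, 0.8, 0.7, 0.2, 0.1), y)
  expect_equal(perfect$auc, 1)
  expect_identical(perfect$fpr[1], 0)
  expect_identical(perfect$tpr[1], 0)
  expect_true(all(diff(perfect$fpr) >= 0) && all(diff(perfect$tpr) >= 0))
  expect_identical(perfect$thresholds[1], Inf)
  flat <- roc_curve(rep(0.5, 5), y)
  expect_identical(length(flat$fpr), 2L)   # ties collapse to (0,0),(1,1)
  expect_equal(flat$auc, 0.5)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # complement identity for tie-free scores
  set.seed(7)
  s <- rnorm(40); yy <- runif(40) > 0.5
  yy[1:2] <- c(TRUE, FALSE)
  expect_equal(roc_curve(s, yy)$auc + roc_curve(-s, yy)$auc, 1,
               tolerance = 1e-12)
})

test_that("AUC equals the rank statistic and the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    s <- rnorm(n)
    y <- runif(n) > runif(1, 0.2, 0.8)
    if (!any(y) || all(y)) next
    auc <- roc_curve(s, y)$auc
    expect_equal(auc, mann_whitney_auc(s, y), tolerance = 1e-12)
    expect_equal(auc,
                 as.numeric(pROC::auc(pROC::roc(as.integer(y), s,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("one-vs-rest multiclass ROC averages per-class areas", {
  set.seed(9)
  y <- rep(c("a", "b", "c"), each = 8)
  raw <- matrix(rnorm(72), 24, 3, dimnames = list(NULL, c("a", "b", "c")))
  raw[cbind(seq_len(24), match(y, c("a", "b", "c")))] <-
    raw[cbind(seq_len(24), match(y, c("a", "b", "c")))] + 2
  proba <- exp(raw) / rowSums(exp(raw))
  res <- multiclass_roc(proba, y)
  expect_length(res$per_class, 3L)
  expect_equal(res$macro_auc,
               mean(vapply(res$per_class, `[[`, 0, "auc")))
  # perfectly confident probabilities give unit areas everywhere
  hard <- diag(3)[match(y, c("a", "b", "c")), ]
  colnames(hard) <- c("a", "b", "c")
  hard_res <- multiclass_roc(hard, y)
  expect_true(all(vapply(hard_res$per_class, `[[`, 0, "auc") == 1))
  # uniform probabilities are uninformative
  unif <- matrix(1 / 3, 24, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_true(all(vapply(multiclass_roc(unif, y)$per_class, `[[`, 0,
                         "auc") == 0.5))
  expect_warning(multiclass_roc(proba, rep(c("a", "b"), 12)), "absent")
})
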
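test_that("confusion counts partition the test set one-vs-rest", {
  cm <- confusion_counts(c("A", "A", "B", "B"), c("A", "B", "B", "B"), "A")
  expect_equal(cm$tp, 1L)
  expect_equal(cm$fn, 1L)
  expect_equal(cm$tn, 2L)
  expect_equal(cm$fp, 0L)
  # all correct
  cm2 <- confusion_counts(c("A", "B"), c("A", "B"), "A")
  expect_equal(cm2$fp + cm2$fn, 0L)
  # positive class absent from truth
  cm3 <- confusion_counts(c("B", "B"), c("A", "B"), "A")
  expect_equal(cm3$tp, 0L)
  expect_equal(cm3$fn, 0L)
  expect_equal(cm3$fp, 1L)
  expect_error(confusion_counts(c("A"), c("A", "B"), "A"), "equal length")
})

test_that("metrics follow the percentage formulas with the F1 factor 2", {
  m <- compute_metrics(list(tp = 50, tn = 30, fp = 10, fn = 10))
  expect_equal(m$accuracy, 80)
  expect_equal(m$recall, 100 * 50 / 60)
  expect_equal(m$specificity, 75)
  expect_equal(m$precision, 100 * 50 / 60)
  expect_equal(m$f1_score, 100 * 50 / 60)  # precision == recall -> F1 equals both
  perfect <- compute_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_true(all(unlist(perfect[c("accuracy", "recall", "specificity",
                                   "f1_score", "precision")]) == 100))
  # 0/0 conventions: report 0 and flag
  deg <- compute_metrics(list(tp = 0, tn = 5, fp = 0, fn = 3))
  expect_equal(deg$recall, 0)
  expect_equal(deg$precision, 0)
  expect_true("precision" %in% deg$degenerate)
  expect_error(compute_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)), "empty")
})

test_that("metrics stay in [0,100] and accuracy*N recovers TP+TN exactly", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    truth <- sample(c("A", "B", "C"), n, replace = TRUE)
    pred <- sample(c("A", "B", "C"), n, replace = TRUE)
    cm <- confusion_counts(truth, pred, "B")
    m <- compute_metrics(cm)
    vals <- unlist(m[c("accuracy", "recall", "specificity", "f1_score",
                       "precision")])
    expect_true(all(vals >= 0 & vals <= 100))
    expect_equal(round(m$accuracy / 100 * n), cm$tp + cm$tn)
  }
})

test_that("the per-class report composes confusion counts and metrics", {
  truth <- c("A", "A", "B", "B", "C", "C", "C")
  pred <- c("A", "B", "B", "B", "C", "A", "C")   # one systematic confusion
  tab <- per_class_report(truth, pred)
  expect_equal(tab$class, c("A", "B", "C"))
  for (cl in tab$class) {
    m <- compute_metrics(confusion_counts(truth, pred, cl))
    row <- tab[tab$class == cl, ]
    expect_equal(row$accuracy, m$accuracy)
    expect_equal(row$recall, m$recall)
    expect_equal(row$specificity, m$specificity)
    expect_equal(row$f1_score, m$f1_score)
    expect_equal(row$precision, m$precision)
  }
  # class-role swap exchanges (recall, specificity) in a 2-class problem
  t2 <- c("A", "A", "B", "B")
  p2 <- c("A", "B", "B", "B")
  ra <- compute_metrics(confusion_counts(t2, p2, "A"))
  rb <- compute_metrics(confusion_counts(t2, p2, "B"))
  expect_equal(ra$recall, rb$specificity)
  expect_equal(ra$specificity, rb$recall)
  # perfect 2-class predictions: both rows all-100
  tabp <- per_class_report(c("A", "B"), c("A", "B"))
  expect_true(all(as.matrix(tabp[, -1]) == 100))
  expect_error(per_class_report(c("A", "A"), c("A", "A")), "2 classes")
})

test_that("trapezoid AUC equals the pairwise-concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)   # rounding forces ties
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "positive and")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(0, 1)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))))
})

test_that("experiment reports append the arithmetic-mean row, rounded half-up", {
  mk <- function(a) list(accuracy = a, recall = a, specificity = a,
                         f1_score = a, precision = a)
  tab <- experiment_report(lapply(c(95.2, 95.8, 96.5), mk),
                           c("(70-30)", "(80-20)", "Random"))
  expect_equal(names(tab), c("Feature Selection", "Classifier", "Experiment",
                             "Accuracy", "Recall", "Specificity", "Precision",
                             "F-Score"))
  expect_equal(tab$Experiment, c("(70-30)", "(80-20)", "Random", "Mean"))
  expect_equal(tab$Accuracy[4], 95.8)
  tab2 <- experiment_report(lapply(c(98.8, 99.9, 100), mk), c("a", "b", "c"))
  expect_equal(tab2$Accuracy[4], 99.6)
  # single row: the mean equals the row
  tab1 <- experiment_report(list(mk(97.35)), "only")
  expect_equal(tab1$Accuracy, c(97.4, 97.4))  # 97.35 rounds half-up to 97.4
  expect_error(experiment_report(list(list(accuracy = 1)), "x"),
               "inconsistent")
})

test_that("macro AUC averages one-vs-rest AUCs over the classes", {
  scores <- cbind(A = c(0.9, 0.8, 0.1, 0.2), B = c(0.1, 0.2, 0.9, 0.8))
  truth <- c("A", "A", "B", "B")
  expect_equal(macro_auc(scores, truth), 1)
})
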
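test_that("confusion matrix counts truth rows and prediction columns", {
  truth <- c("I", "I", "II", "III", "IV")
  cm <- confusion_matrix(truth, truth)
  expect_equal(diag(cm), c(I = 2L, II = 1L, III = 1L, IV = 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)

  cm0 <- confusion_matrix(character(0), character(0))
  expect_true(all(cm0 == 0))

  expect_error(confusion_matrix(c("I", "II"), "I"),
               class = "emaclass_validation_error")
  expect_error(confusion_matrix("I", "V"),
               class = "emaclass_validation_error")
})

test_that("a published-style screening confusion pattern totals 2597", {
  # per-class predicted assignments of a four-class screening run
  cm <- rbind(
    I   = c(195,   77, 0, 2),
    II  = c(17,  2236, 3, 4),
    III = c(1,      6, 6, 0),
    IV  = c(12,    32, 0, 6)
  )
  colnames(cm) <- EMA_CLASSES
  names(dimnames(cm)) <- c("truth", "predicted")
  expect_equal(sum(cm), 2597)
  expect_equal(as.vector(rowSums(cm)), c(274, 2260, 13, 50))
  m <- scalar_metrics(cm, positive_class = "I")
  expect_equal(m$accuracy + m$error, 1)
  expect_equal(m$sensitivity, 195 / 274)
  expect_equal(m$accuracy, (195 + 2236 + 6 + 6) / 2597)
})

test_that("scalar metrics reproduce the hand-checked 2x2 matrix", {
  cm <- matrix(c(45, 10, 5, 40), 2, 2,
               dimnames = list(truth = c("I", "II"),
                               predicted = c("I", "II")))
  m <- scalar_metrics(cm, positive_class = "I")
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$kappa, 0.70)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  # F1 from precision 45/55 and sensitivity 0.9
  prec <- 45 / 55
  expect_equal(m$f1, 2 * prec * 0.9 / (prec + 0.9))
})

test_that("perfect and degenerate matrices give the expected corner values", {
  cm <- diag(c(5L, 7L, 3L, 9L))
  dimnames(cm) <- list(truth = EMA_CLASSES, predicted = EMA_CLASSES)
  m <- scalar_metrics(cm)
  expect_equal(m$accuracy, 1)
  expect_equal(m$error, 0)
  expect_equal(m$kappa, 1)
  expect_equal(m$f1, 1)

  # single-class truth, all predicted that class: p_e = 1, kappa undefined
  cm1 <- matrix(0L, 4, 4, dimnames = list(truth = EMA_CLASSES,
                                          predicted = EMA_CLASSES))
  cm1["II", "II"] <- 10L
  m1 <- scalar_metrics(cm1)
  expect_equal(m1$accuracy, 1)
  expect_true(is.na(m1$kappa))
  expect_true("kappa" %in% m1$undefined)
  # sensitivity of a class with no true samples is undefined, not zero
  expect_true(is.na(m1$per_class$sensitivity[1]))
  expect_true(any(grepl("sensitivity\\(I\\)", m1$undefined)))
})

test_that("kappa is zero on a product-of-marginals matrix", {
  cm <- matrix(10L, 4, 4, dimnames = list(truth = EMA_CLASSES,
                                          predicted = EMA_CLASSES))
  expect_lt(abs(scalar_metrics(cm)$kappa), 1e-12)
})

test_that("metrics agree with an independent implementation on random data", {
  skip_if_not_installed("caret")
  withr::with_seed(8, {
    truth <- sample(EMA_CLASSES, 300, replace = TRUE,
                    prob = c(0.3, 0.4, 0.1, 0.2))
    pred <- ifelse(runif(300) < 0.6, truth,
                   sample(EMA_CLASSES, 300, replace = TRUE))
  })
  cm <- confusion_matrix(truth, pred)
  m <- scalar_metrics(cm, positive_class = "II")
  ref <- caret::confusionMatrix(factor(pred, levels = EMA_CLASSES),
                                factor(truth, levels = EMA_CLASSES))
  expect_equal(m$accuracy, unname(ref$overall["Accuracy"]))
  expect_equal(m$kappa, unname(ref$overall["Kappa"]))
  expect_equal(m$per_class$sensitivity,
               unname(ref$byClass[, "Sensitivity"]))
  expect_equal(m$per_class$specificity,
               unname(ref$byClass[, "Specificity"]))
})

test_that("accuracy can exclude samples predicted equivocal", {
  cm <- rbind(
    I   = c(8L, 0L, 0L, 2L),
    II  = c(0L, 9L, 0L, 1L),
    III = c(0L, 0L, 5L, 0L),
    IV  = c(0L, 0L, 0L, 5L)
  )
  colnames(cm) <- EMA_CLASSES
  names(dimnames(cm)) <- c("truth", "predicted")
  plain <- scalar_metrics(cm)
  excl <- scalar_metrics(cm, exclude_inconclusive = TRUE)
  expect_equal(plain$accuracy, 27 / 30)
  expect_equal(excl$accuracy, 22 / 22)
  expect_true(excl$exclude_inconclusive)
})

test_that("AUC: separation, reversal, null and tie handling", {
  scores <- c(1, 2, 3, 10, 11, 12)
  truth <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(roc_auc(scores, truth), 1)
  expect_equal(roc_auc(-scores, truth), 0)
  expect_equal(roc_auc(rep(1, 6), truth), 0.5)   # all tied: chance
  # ties counted one half
  expect_equal(roc_auc(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE)), 0.875)

  withr::with_seed(123, {
    u <- runif(2000)
    t2 <- runif(2000) < 0.5
  })
  expect_lt(abs(roc_auc(u, t2) - 0.5), 0.04)

  expect_warning(a <- roc_auc(1:4, rep(TRUE, 4)))
  expect_true(is.na(a))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(4, {
    s <- rnorm(200)
    t <- runif(200) < stats::plogis(2 * s)
  })
  a0 <- roc_auc(s, t)
  expect_equal(roc_auc(exp(s), t), a0)
  expect_equal(roc_auc(3 * s - 7, t), a0)
  expect_equal(roc_auc(rank(s), t), a0)
})

test_that("rank AUC equals the trapezoidal area under the empirical ROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    s <- c(rnorm(60, 1), rnorm(80))
    t <- rep(c(TRUE, FALSE), c(60, 80))
    s[sample(140, 20)] <- round(s[sample(140, 20)], 1)  # induce ties
  })
  rc <- roc_curve(s, t)
  trap <- sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) +
                                utils::tail(rc$tpr, -1)) / 2)
  expect_equal(roc_auc(s, t), trap)
  expect_equal(roc_auc(s, t),
               as.numeric(pROC::auc(pROC::roc(t, s, quiet = TRUE))))
})

test_that("class shares match the screening-laboratory arithmetic", {
  expect_equal(class_shares(c(274, 2260, 13, 50)),
               c(10.55, 87.02, 0.50, 1.93))
  expect_equal(class_shares(c(1, 1, 1, 1)), rep(25, 4))
  expect_equal(class_shares(c(0, 10, 0, 0)), c(0, 100, 0, 0))
})

test_that("confusion marginals are preserved under consistent permutation", {
  withr::with_seed(2, {
    truth <- sample(EMA_CLASSES, 120, replace = TRUE)
    pred <- sample(EMA_CLASSES, 120, replace = TRUE)
    perm <- sample(120)
  })
  cm1 <- confusion_matrix(truth, pred)
  cm2 <- confusion_matrix(truth[perm], pred[perm])
  expect_identical(cm1, cm2)
  expect_equal(as.vector(rowSums(cm1)), as.vector(table(factor(truth,
    levels = EMA_CLASSES))))
  expect_equal(as.vector(colSums(cm1)), as.vector(table(factor(pred,
    levels = EMA_CLASSES))))
})

test_that("evaluate_predictions assembles metrics, AUC and shares", {
  withr::with_seed(6, {
    truth <- sample(EMA_CLASSES, 200, replace = TRUE)
    scores <- matrix(rnorm(800), 200, 4, dimnames = list(NULL, EMA_CLASSES))
    for (i in seq_along(truth))

      scores[i, truth[i]] <- scores[i, truth[i]] + 3
  })
  pred <- as.character(scores_to_label(scores))
  rep <- evaluate_predictions(truth, pred, scores)
  expect_s3_class(rep, "metrics_report")
  expect_true(all(rep$auc_per_class > 0.9))
  expect_equal(sum(rep$confusion), 200)
  expect_equal(sum(rep$class_shares), 100, tolerance = 0.05)
  expect_output(print(rep), "accuracy")
})
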
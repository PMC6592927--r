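test_that("stratified 70/30 splits have the round-half-up arithmetic", {
  labels <- rep(EMA_CLASSES, times = c(10, 10, 10, 10))
  cfg <- train_config(n_repeats = 3, seed = 1)
  for (sp in split_repeated(labels, cfg)) {
    expect_equal(as.vector(table(labels[sp$train])), rep(7, 4))
    expect_equal(as.vector(table(labels[sp$test])), rep(3, 4))
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_along(labels))
  }

  # screening-laboratory class mix: train sizes round half-up per class
  labels <- rep(EMA_CLASSES, times = c(274, 2260, 13, 50))
  sp <- split_repeated(labels, train_config(n_repeats = 1, seed = 0))[[1]]
  expect_equal(as.vector(table(labels[sp$train])), c(192, 1582, 9, 35))
})

test_that("splits are seed-determined and fail on classes below 2 samples", {
  labels <- rep(EMA_CLASSES, times = c(5, 8, 3, 4))
  cfg <- train_config(n_repeats = 4, seed = 42)
  expect_identical(split_repeated(labels, cfg), split_repeated(labels, cfg))
  cfg2 <- train_config(n_repeats = 4, seed = 43)
  expect_false(identical(split_repeated(labels, cfg),
                         split_repeated(labels, cfg2)))

  bad <- rep(EMA_CLASSES, times = c(5, 8, 1, 4))
  expect_error(split_repeated(bad, cfg),
               class = "emaclass_stratification_error")
  expect_match(tryCatch(split_repeated(bad, cfg),
                        error = conditionMessage), "III")
})

test_that("one-vs-all SVM separates well-separated clouds and rejects one class", {
  ds <- make_clouds(50, separation = 10, n_classes = 2, seed = 1)
  cfg <- train_config(svm_C_grid = 1, svm_gamma_grid = 0.2, seed = 0)
  model <- train_svm_ecoc(ds, cfg)
  pr <- predict(model, ds$features)
  expect_equal(mean(pr$label == ds$labels), 1)
  expect_true(all(is.finite(pr$scores[, c("I", "II")])))

  one <- labeled_dataset(matrix(rnorm(40), 10, 4), rep("II", 10))
  expect_error(train_svm_ecoc(one, cfg), class = "emaclass_degenerate_error")

  # duplicated rows with a consistent label are predicted as that label
  dup <- labeled_dataset(rbind(ds$features, ds$features[1, ], ds$features[1, ]),
                         c(as.character(ds$labels), "I", "I"))
  model2 <- train_svm_ecoc(dup, cfg)
  expect_equal(as.character(predict(model2, ds$features[1, ])$label), "I")
})

test_that("inner-CV grid search runs and returns a grid point", {
  ds <- make_clouds(20, separation = 3, n_classes = 2, dim = 3, seed = 7)
  cfg <- train_config(svm_C_grid = c(0.1, 10), svm_gamma_grid = c(0.05, 0.5),
                      inner_folds = 5, seed = 3)
  model <- train_svm_ecoc(ds, cfg)
  for (cls in c("I", "II")) {
    expect_true(model$scorers[[cls]]$C %in% cfg$svm_C_grid)
    expect_true(model$scorers[[cls]]$gamma %in% cfg$svm_gamma_grid)
  }
  pr <- predict(model, ds$features)
  expect_gt(mean(pr$label == ds$labels), 0.8)
})

test_that("prediction is argmax with ties broken in class order", {
  expect_equal(as.character(scores_to_label(c(0.9, 0.1, 0.1, 0.1))), "I")
  expect_equal(as.character(scores_to_label(c(0.1, 0.7, 0.1, 0.7))), "II")
  expect_equal(as.character(scores_to_label(c(0.2, 0.2, 0.2, 0.2))), "I")
  m <- rbind(c(0, 0, 1, 0.5), c(-1, -2, -3, -1))
  expect_equal(as.character(scores_to_label(m)), c("III", "I"))
})

test_that("predict validates feature length against the trained model", {
  ds <- make_clouds(15, separation = 8, n_classes = 2, dim = 4, seed = 2)
  model <- train_svm_ecoc(ds, train_config(svm_C_grid = 1,
                                           svm_gamma_grid = 0.25))
  expect_error(predict(model, matrix(0, 2, 7)),
               class = "emaclass_contract_error")
})

test_that("AdaBoost weight formula and degenerate cases", {
  expect_equal(samme_alpha(0.5, 2), 0)        # chance learner gets zero vote
  expect_gt(samme_alpha(0.3, 2), 0)
  expect_gt(samme_alpha(0.5, 4), 0)           # chance for K=2 is not for K=4
  expect_equal(samme_alpha(0.75, 4), 0)
})

test_that("AdaBoost drives training error to zero on separable data", {
  ds <- make_clouds(30, separation = 6, n_classes = 2, dim = 3, seed = 5)
  cfg <- train_config(method = "adaboost_trees", boost_cycles = 30,
                      tree_max_depth = 2, seed = 0)
  model <- train_adaboost(ds, cfg)
  pr <- predict(model, ds$features)
  expect_equal(mean(pr$label == ds$labels), 1)
})

test_that("one boosting cycle equals the single weak tree", {
  ds <- make_clouds(25, separation = 2, n_classes = 4, dim = 4, seed = 9)
  cfg <- train_config(method = "adaboost_trees", boost_cycles = 1,
                      tree_max_depth = 3, seed = 0)
  model <- train_adaboost(ds, cfg)
  expect_length(model$trees, 1)
  df <- as.data.frame(ds$features)
  single <- predict(model$trees[[1]], df, type = "class")
  pr <- predict(model, ds$features)
  expect_equal(as.character(pr$label), as.character(single))
})

test_that("under-sampling reduces the negative class to the positive count", {
  withr::with_seed(1, {
    x <- matrix(rnorm(2597 * 3), ncol = 3)
  })
  ds <- labeled_dataset(x, rep(EMA_CLASSES, times = c(274, 2260, 13, 50)))
  out <- undersample(ds, seed = 0)
  expect_equal(as.vector(out$class_counts), c(274, 274, 13, 50))

  # already balanced: unchanged
  bal <- labeled_dataset(x[1:25, ], rep(EMA_CLASSES, times = c(10, 10, 3, 2)))
  expect_equal(as.vector(undersample(bal, 5)$class_counts), c(10, 10, 3, 2))

  # determinism and row-order preservation without duplication
  a <- undersample(ds, seed = 7)
  b <- undersample(ds, seed = 7)
  expect_identical(a$features, b$features)
  kept <- match(apply(a$features, 1, paste, collapse = ","),
                apply(ds$features, 1, paste, collapse = ","))
  expect_false(is.unsorted(kept))
  expect_false(any(duplicated(kept)))

  # minority classes are untouched
  expect_equal(a$features[a$labels == "III", ],
               ds$features[ds$labels == "III", ])

  flipped <- labeled_dataset(x[1:20, ],
                             rep(EMA_CLASSES, times = c(12, 4, 2, 2)))
  expect_error(undersample(flipped, 0), class = "emaclass_precondition_error")
})

test_that("held-out accuracy is monotone in class separation", {
  seps <- c(0, 1, 2, 4, 8)
  acc <- sapply(seps, function(s) {
    mean(sapply(1:5, function(seed) {
      ds <- make_clouds(20, separation = s, n_classes = 2, dim = 3,
                        seed = seed)
      cfg <- train_config(svm_C_grid = 1, svm_gamma_grid = 1 / 3,
                          n_repeats = 2, seed = seed)
      ev <- train_evaluate(ds, cfg)
      ev$report$accuracy
    }))
  })
  expect_true(all(diff(acc) > -0.05))
  expect_gt(acc[length(acc)], 0.95)
  expect_lt(abs(acc[1] - 0.5), 0.15)
})

test_that("label shuffling collapses accuracy to the majority-class rate", {
  ds <- make_clouds(30, separation = 6, n_classes = 4, dim = 4, seed = 3)
  shuffled <- withr::with_seed(10, labeled_dataset(ds$features,
                                                   sample(ds$labels)))
  cfg <- train_config(svm_C_grid = 1, svm_gamma_grid = 1 / 4,
                      n_repeats = 3, seed = 0)
  ev <- train_evaluate(shuffled, cfg)
  n <- length(ev$pooled$truth)
  p0 <- 0.25
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(ev$report$accuracy - p0), 3 * se + 1e-9)
})

test_that("models survive a save/load round trip", {
  ds <- make_clouds(15, separation = 8, n_classes = 2, dim = 4, seed = 4)
  model <- train_svm_ecoc(ds, train_config(svm_C_grid = 1,
                                           svm_gamma_grid = 0.25))
  f <- tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(predict(back, ds$features)$label,
                   predict(model, ds$features)$label)
  expect_match(back$feature_config_digest, "coalbp")
})
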
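# One-vs-all RBF-SVM ensemble and multi-class AdaBoost over decision trees,
# with the repeated stratified 70/30 evaluation protocol and random
# under-sampling of the negative majority class.

#' Bundle features and labels
#'
#' @param features Numeric matrix (rows = samples) or data.frame of feature
#'   columns.
#' @param labels Class labels (coerced to factor with levels I..IV).
#' @return Object of class `labeled_dataset` with `features`, `labels`,
#'   `class_counts`.
#' @export
labeled_dataset <- function(features, labels) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- check_labels(labels)
  if (nrow(features) != length(labels)) {
    stop_emaclass("features and labels disagree in length: ", nrow(features),
                  " vs ", length(labels), class = "emaclass_validation_error")
  }
  structure(list(features = features, labels = labels,
                 class_counts = table(labels)),
            class = "labeled_dataset")
}

#' Training configuration
#'
#' @param method `"svm_ecoc"` (one-vs-all RBF-SVMs) or `"adaboost_trees"`
#'   (multi-class AdaBoost over depth-limited trees).
#' @param svm_C_grid Candidate SVM cost values. When the C x gamma grid has a
#'   single point, the inner cross-validated tuning is skipped.
#' @param svm_gamma_grid Candidate RBF kernel widths (default centred on
#'   1/816, the reciprocal feature length).
#' @param inner_folds Folds of the inner stratified CV used for tuning.
#' @param boost_cycles AdaBoost learning cycles (default 100).
#' @param tree_max_depth Maximum depth of the weak trees.
#' @param n_repeats Outer Monte-Carlo split repeats (default 10).
#' @param train_fraction Training share of each stratified split (default 0.7).
#' @param seed Integer seed controlling splits, tuning folds and sampling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(method = c("svm_ecoc", "adaboost_trees"),
                         svm_C_grid = c(0.1, 1, 10, 100),
                         svm_gamma_grid = 10^(-2:2) / 816,
                         inner_folds = 10,
                         boost_cycles = 100,
                         tree_max_depth = 3,
                         n_repeats = 10,
                         train_fraction = 0.70,
                         seed = 0) {
  method <- match.arg(method)
  stopifnot(train_fraction > 0, train_fraction < 1, boost_cycles >= 1,
            n_repeats >= 1, all(svm_C_grid > 0), all(svm_gamma_grid > 0),
            inner_folds >= 2, tree_max_depth >= 1)
  structure(list(method = method, svm_C_grid = svm_C_grid,
                 svm_gamma_grid = svm_gamma_grid,
                 inner_folds = as.integer(inner_folds),
                 boost_cycles = as.integer(boost_cycles),
                 tree_max_depth = as.integer(tree_max_depth),
                 n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Repeated stratified train/test splits
#'
#' Draws `n_repeats` independent stratified random splits. Per class,
#' `round_half_up(train_fraction * count)` rows go to training and the
#' remainder to test; splits are disjoint, exhaustive, and fully determined
#' by `cfg$seed`.
#'
#' @param ds A [labeled_dataset()] (or a factor of labels).
#' @param cfg A [train_config()].
#' @return List of `n_repeats` lists with integer index vectors `train`,
#'   `test`.
#' @export
split_repeated <- function(ds, cfg = train_config()) {
  labels <- if (inherits(ds, "labeled_dataset")) ds$labels else check_labels(ds)
  present <- levels(labels)[table(labels) > 0]
  small <- levels(labels)[table(labels) > 0 & table(labels) < 2]
  if (length(small) > 0) {
    stop_emaclass("stratified splitting needs >= 2 samples per class; class ",
                  paste(small, collapse = ", "), " has fewer",
                  class = "emaclass_stratification_error")
  }
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_repeats), function(rep) {
      train <- integer(0)
      for (cls in present) {
        idx <- which(labels == cls)
        n_tr <- round_half_up(cfg$train_fraction * length(idx))
        n_tr <- min(max(n_tr, 1), length(idx) - 1)   # both sides non-empty
        train <- c(train, sample(idx, n_tr))
      }
      train <- sort(train)
      list(train = train, test = setdiff(seq_along(labels), train))
    })
  })
}

#' Random under-sampling of the negative majority class
#'
#' Removes randomly chosen negative (class II) rows without replacement until
#' the negative count equals the positive (class I) count. Classes I, III and
#' IV are untouched and the original row order of survivors is preserved.
#'
#' @param ds A [labeled_dataset()].
#' @param seed Integer seed for the sampling.
#' @return A reduced [labeled_dataset()].
#' @export
undersample <- function(ds, seed = 0) {
  stopifnot(inherits(ds, "labeled_dataset"))
  n_pos <- sum(ds$labels == "I")
  n_neg <- sum(ds$labels == "II")
  if (n_neg < n_pos) {
    stop_emaclass("cannot under-sample: negative count (", n_neg,
                  ") below positive count (", n_pos, ")",
                  class = "emaclass_precondition_error")
  }
  neg_idx <- which(ds$labels == "II")
  keep_neg <- with_seed(seed, sample(neg_idx, n_pos))
  keep <- sort(c(which(ds$labels != "II"), keep_neg))
  labeled_dataset(ds$features[keep, , drop = FALSE], ds$labels[keep])
}

# per-dimension standardisation computed on training rows only
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, sc) {
  sweep(sweep(x, 2, sc$center), 2, sc$scale, "/")
}

# stratified fold assignment for a binary indicator
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# balanced accuracy of a binary prediction
balanced_accuracy <- function(truth, pred) {
  sens <- mean(pred[truth])
  spec <- mean(!pred[!truth])
  (sens + spec) / 2
}

#' Train the one-vs-all RBF-SVM ensemble
#'
#' Fits one binary RBF-SVM per class (that class against the rest; the
#' one-vs-all coding of an error-correcting output code scheme). When the
#' `(C, gamma)` grid has more than one point, each scorer's pair is chosen by
#' maximising mean balanced accuracy over an inner stratified
#' `cfg$inner_folds`-fold cross-validation on the training rows. Features are
#' standardised per dimension with statistics computed on the training rows
#' only and stored in the model.
#'
#' @param train A [labeled_dataset()] with at least two classes present.
#' @param cfg A [train_config()].
#' @return Object of class `ema_model`.
#' @export
train_svm_ecoc <- function(train, cfg = train_config()) {
  stopifnot(inherits(train, "labeled_dataset"))
  present <- levels(train$labels)[table(train$labels) > 0]
  if (length(present) < 2) {
    stop_emaclass("training set contains a single class (", present,
                  "); need at least two", class = "emaclass_degenerate_error")
  }
  sc <- fit_scaler(train$features)
  x <- apply_scaler(train$features, sc)
  grid <- expand.grid(C = cfg$svm_C_grid, gamma = cfg$svm_gamma_grid)
  scorers <- with_seed(cfg$seed + 1L, lapply(EMA_CLASSES, function(cls) {
    if (!(cls %in% present)) return(NULL)
    y <- train$labels == cls
    pick <- grid[1, ]
    if (nrow(grid) > 1) {
      k <- min(cfg$inner_folds, sum(y), sum(!y))
      k <- max(k, 2)
      fold <- stratified_folds(y, k)
      cv_score <- vapply(seq_len(nrow(grid)), function(g) {
        accs <- vapply(seq_len(k), function(f) {
          tr <- fold != f; te <- !tr
          if (length(unique(y[tr])) < 2 || !any(te)) return(NA_real_)
          fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr]),
                            kernel = "radial", cost = grid$C[g],
                            gamma = grid$gamma[g], scale = FALSE)
          balanced_accuracy(y[te],
                            predict(fit, x[te, , drop = FALSE]) == "TRUE")
        }, numeric(1))
        mean(accs, na.rm = TRUE)
      }, numeric(1))
      pick <- grid[which.max(cv_score), ]
    }
    fit <- e1071::svm(x, factor(y), kernel = "radial", cost = pick$C,
                      gamma = pick$gamma, scale = FALSE,
                      decision.values = TRUE)
    list(fit = fit, C = pick$C, gamma = pick$gamma)
  }))
  names(scorers) <- EMA_CLASSES
  structure(list(method = "svm_ecoc", scorers = scorers, scaler = sc,
                 class_order = EMA_CLASSES,
                 n_features = ncol(train$features),
                 feature_config_digest = feature_config_digest(ncol(train$features)),
                 config = cfg),
            class = "ema_model")
}

feature_config_digest <- function(n_features) {
  sc <- descriptor_scales()
  paste0("coalbp/r=", paste(sc$r, collapse = "."), "/d=",
         paste(sc$d, collapse = "."), "/margin=", sc$margin,
         "/len=", n_features)
}

#' Train multi-class AdaBoost over decision trees
#'
#' SAMME-style multi-class AdaBoost: depth-limited classification trees are
#' fitted to exponentially re-weighted samples for `cfg$boost_cycles` rounds;
#' each round's weight is `alpha = log((1 - err)/err) + log(K - 1)` and the
#' sample weights are renormalised to sum to 1. Rounds whose weighted error
#' reaches chance level (`alpha <= 0`) are discarded; a round with zero error
#' ends the loop.
#'
#' @inheritParams train_svm_ecoc
#' @return Object of class `ema_model`.
#' @export
train_adaboost <- function(train, cfg = train_config(method = "adaboost_trees")) {
  stopifnot(inherits(train, "labeled_dataset"))
  present <- levels(train$labels)[table(train$labels) > 0]
  if (length(present) < 2) {
    stop_emaclass("training set contains a single class (", present,
                  "); need at least two", class = "emaclass_degenerate_error")
  }
  k_classes <- length(present)
  df <- as.data.frame(train$features)
  df$.y <- factor(as.character(train$labels), levels = present)
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = cfg$tree_max_depth, cp = 0,
                               minsplit = 2, xval = 0, maxsurrogate = 0)
  with_seed(cfg$seed + 2L, {
    for (m in seq_len(cfg$boost_cycles)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = ctrl)
      pred <- predict(fit, df, type = "class")
      miss <- pred != df$.y
      err <- sum(w[miss])
      if (err <= 1e-12) {
        # perfect weak learner: give it a large but finite vote and stop
        trees[[length(trees) + 1]] <- fit
        alphas <- c(alphas, log((1 - 1e-10) / 1e-10) + log(k_classes - 1))
        break
      }
      alpha <- samme_alpha(err, k_classes)
      if (alpha <= 0) break   # no better than chance: zero vote, stop
      trees[[length(trees) + 1]] <- fit
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
    }
  })
  if (length(trees) == 0) {
    stop_emaclass("boosting failed: first weak learner no better than chance",
                  class = "emaclass_degenerate_error")
  }
  structure(list(method = "adaboost_trees", trees = trees, alphas = alphas,
                 present_classes = present, class_order = EMA_CLASSES,
                 n_features = ncol(train$features),
                 feature_config_digest = feature_config_digest(ncol(train$features)),
                 config = cfg),
            class = "ema_model")
}

#' Train a model with the configured method
#'
#' @param train A [labeled_dataset()].
#' @param cfg A [train_config()]; `cfg$method` picks the learner.
#' @return An `ema_model`.
#' @export
train_model <- function(train, cfg = train_config()) {
  switch(cfg$method,
         svm_ecoc = train_svm_ecoc(train, cfg),
         adaboost_trees = train_adaboost(train, cfg))
}

#' Predict classes and per-class scores
#'
#' Scores are the four one-vs-all decision values (SVM) or weighted ensemble
#' votes (AdaBoost). The label is the argmax of the scores; exact ties break
#' towards the earlier class in the order I, II, III, IV. Classes absent from
#' training score `-Inf`.
#'
#' @param object An `ema_model`.
#' @param newdata Numeric matrix of feature rows (or a single vector).
#' @param ... Unused.
#' @return List with `label` (factor) and `scores` (n x 4 matrix).
#' @export
predict.ema_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop_emaclass("feature length mismatch: model expects ",
                  object$n_features, ", got ", ncol(newdata),
                  class = "emaclass_contract_error")
  }
  scores <- matrix(-Inf, nrow(newdata), 4,
                   dimnames = list(NULL, EMA_CLASSES))
  if (object$method == "svm_ecoc") {
    x <- apply_scaler(newdata, object$scaler)
    for (cls in EMA_CLASSES) {
      sco <- object$scorers[[cls]]
      if (is.null(sco)) next
      p <- predict(sco$fit, x, decision.values = TRUE)
      dv <- drop(attr(p, "decision.values"))
      # orient the decision value so larger = more like `cls` (y was TRUE/FALSE)
      if (colnames(attr(p, "decision.values"))[1] == "FALSE/TRUE") dv <- -dv
      scores[, cls] <- dv
    }
  } else {
    df <- as.data.frame(newdata)
    votes <- matrix(0, nrow(newdata), length(object$present_classes),
                    dimnames = list(NULL, object$present_classes))
    for (m in seq_along(object$trees)) {
      pred <- predict(object$trees[[m]], df, type = "class")
      votes <- votes + object$alphas[m] *
        (matrix(object$present_classes, nrow(newdata),
                length(object$present_classes), byrow = TRUE) ==
           as.character(pred))
    }
    scores[, object$present_classes] <- votes
  }
  list(label = scores_to_label(scores), scores = scores)
}

#' Turn per-class scores into labels
#'
#' Argmax over the four one-vs-all scores; exact ties break towards the
#' earlier class in the order I, II, III, IV.
#'
#' @param scores Numeric matrix (n x 4, columns in class order) or a single
#'   length-4 vector.
#' @return Factor of predicted labels.
#' @export
scores_to_label <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  stopifnot(ncol(scores) == 4)
  factor(EMA_CLASSES[max.col(scores, ties.method = "first")],
         levels = EMA_CLASSES)
}

#' AdaBoost round weight
#'
#' The SAMME vote weight `alpha = log((1 - err)/err) + log(K - 1)` for a weak
#' learner with weighted error `err` in a `K`-class problem. At `K = 2` this
#' is the classical AdaBoost weight, zero for a chance-level (err = 0.5)
#' learner.
#'
#' @param err Weighted training error in `[0, 1)`.
#' @param n_classes Number of classes `K`.
#' @return The vote weight.
#' @export
samme_alpha <- function(err, n_classes) {
  stopifnot(err >= 0, err < 1, n_classes >= 2)
  log((1 - err) / err) + log(n_classes - 1)
}

#' Save / load a trained model
#'
#' Thin wrappers around R's serialisation; the archive embeds the training
#' configuration, feature-descriptor digest and class order.
#'
#' @param model An `ema_model`.
#' @param path File path.
#' @return `load_model` returns the model; `save_model` the path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ema_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ema_model")) {
    stop_emaclass("file does not contain an ema_model: ", path,
                  class = "emaclass_io_error")
  }
  model
}
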
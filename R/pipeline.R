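# End-to-end pipeline stages: descriptor extraction over an image manifest,
# repeated-split training with pooled held-out evaluation, and reproducible
# run manifests.

#' Extract descriptor features for every image in a manifest
#'
#' Loads each image listed in the manifest (CSV with `path,label`), validates
#' that all images share one size, runs [extract_features()] and returns one
#' row per image. When `out_csv` is given the table is written as CSV
#' (`path,label,f0..f815`) together with a JSON sidecar recording the
#' preprocessing and descriptor parameters.
#'
#' @param manifest Path to a manifest CSV, or a data.frame with columns
#'   `path`, `label`.
#' @param out_csv Optional output CSV path.
#' @param cfg A [preprocess_config()].
#' @return data.frame `path, label, f0..f815`, invisibly when written.
#' @export
extract_feature_table <- function(manifest, out_csv = NULL,
                                  cfg = preprocess_config()) {
  man <- if (is.character(manifest)) read_manifest(manifest) else manifest
  stopifnot(all(c("path", "label") %in% names(man)))
  if (nrow(man) == 0) {
    stop_emaclass("manifest is empty", class = "emaclass_validation_error")
  }
  t0 <- proc.time()[["elapsed"]]
  dims <- NULL
  feats <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    img <- load_image(man$path[i])
    if (is.null(dims)) {
      dims <- dim(img)
    } else if (!identical(dim(img), dims)) {
      stop_emaclass("image size mismatch: ", man$path[i], " is ",
                    paste(dim(img), collapse = "x"), ", expected ",
                    paste(dims, collapse = "x"),
                    class = "emaclass_validation_error")
    }
    feats[[i]] <- extract_features(img, cfg)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  fm <- do.call(rbind, feats)
  out <- data.frame(path = man$path, label = as.character(man$label),
                    fm, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "seconds_per_image") <- elapsed / nrow(man)
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE, quote = FALSE)
    sidecar <- sub("\\.csv$", ".json", out_csv)
    if (identical(sidecar, out_csv)) sidecar <- paste0(out_csv, ".json")
    write_run_manifest(sidecar, stage = "extract",
                       params = list(preprocess = unclass(cfg),
                                     scales = descriptor_scales(),
                                     n_images = nrow(man),
                                     image_size = dims,
                                     seconds_per_image = elapsed / nrow(man)),
                       inputs = man$path)
    return(invisible(out))
  }
  out
}

read_feature_table <- function(features) {
  df <- if (is.character(features)) {
    utils::read.csv(features, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    features
  }
  if (!("label" %in% names(df))) {
    stop_emaclass("feature table is missing the 'label' column",
                  class = "emaclass_contract_error")
  }
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (length(fcols) == 0) {
    stop_emaclass("feature table has no feature columns f0..fN; found: ",
                  paste(utils::head(names(df), 8), collapse = ", "),
                  class = "emaclass_contract_error")
  }
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  labeled_dataset(as.matrix(df[, fcols]), df$label)
}

#' Train with repeated stratified splits and evaluate pooled predictions
#'
#' The evaluation protocol: `cfg$n_repeats` independent stratified 70/30
#' splits; a model is trained on each training part and applied to the
#' held-out part; held-out predictions are pooled across repeats into one
#' confusion matrix and one ROC per class (per-repeat accuracies are also
#' reported with mean and SD). A final model is then trained on the full
#' (optionally under-sampled) dataset.
#'
#' @param features A feature table (data.frame or CSV path with
#'   `label,f0..fN` columns) or a [labeled_dataset()].
#' @param cfg A [train_config()].
#' @param positive_class Headline class for binary metrics.
#' @param do_undersample If `TRUE`, the negative majority class is randomly
#'   reduced to the positive count (seeded by `cfg$seed`) before splitting.
#' @param out_dir Optional directory for the report JSON, pooled ROC CSVs and
#'   run manifest.
#' @return List of class `ema_evaluation`: `report` (a `metrics_report`),
#'   `model` (final model), `per_repeat` (data.frame of per-repeat
#'   accuracies), `pooled` (truth/pred/scores), `timing`.
#' @export
train_evaluate <- function(features, cfg = train_config(),
                           positive_class = "I", do_undersample = FALSE,
                           out_dir = NULL) {
  ds <- if (inherits(features, "labeled_dataset")) features
        else read_feature_table(features)
  if (do_undersample) ds <- undersample(ds, seed = cfg$seed)
  splits <- split_repeated(ds, cfg)
  truth_all <- factor(character(0), levels = EMA_CLASSES)
  pred_all <- factor(character(0), levels = EMA_CLASSES)
  scores_all <- NULL
  per_repeat <- numeric(length(splits))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    tr <- labeled_dataset(ds$features[sp$train, , drop = FALSE],
                          ds$labels[sp$train])
    model <- train_model(tr, cfg)
    pr <- predict(model, ds$features[sp$test, , drop = FALSE])
    truth_all <- c(truth_all, ds$labels[sp$test])
    pred_all <- c(pred_all, pr$label)
    scores_all <- rbind(scores_all, pr$scores)
    per_repeat[i] <- mean(pr$label == ds$labels[sp$test])
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  report <- evaluate_predictions(truth_all, pred_all, scores_all,
                                 positive_class = positive_class)
  final <- train_model(ds, cfg)
  out <- structure(list(
    report = report,
    model = final,
    per_repeat = data.frame(repeat_id = seq_along(per_repeat),
                            accuracy = per_repeat),
    repeat_accuracy_mean = mean(per_repeat),
    repeat_accuracy_sd = stats::sd(per_repeat),
    pooled = list(truth = truth_all, pred = pred_all, scores = scores_all),
    class_counts = as.integer(table(ds$labels)),
    timing = list(train_eval_seconds = elapsed),
    config = cfg
  ), class = "ema_evaluation")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(final, file.path(out_dir, "model.rds"))
    jsonlite::write_json(report_as_list(report, out),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (cls in EMA_CLASSES) {
      rc <- report$roc_curves[[cls]]
      if (!is.null(rc)) {
        utils::write.csv(rc, file.path(out_dir, paste0("roc_", cls, ".csv")),
                         row.names = FALSE)
      }
    }
    write_run_manifest(file.path(out_dir, "run_manifest.json"),
                       stage = "train_evaluate",
                       params = list(config = unclass(cfg),
                                     positive_class = positive_class,
                                     undersample = do_undersample,
                                     class_counts = out$class_counts,
                                     timing = out$timing))
  }
  out
}

report_as_list <- function(report, evalobj = NULL) {
  lst <- list(
    accuracy = report$accuracy, error = report$error,
    sensitivity = report$sensitivity, specificity = report$specificity,
    precision = report$precision, f1 = report$f1, kappa = report$kappa,
    auc_per_class = as.list(report$auc_per_class),
    per_class = report$per_class,
    macro = report$macro,
    positive_class = report$positive_class,
    class_shares = as.list(report$class_shares),
    confusion = report$confusion,
    undefined = report$undefined
  )
  if (!is.null(evalobj)) {
    lst$per_repeat <- evalobj$per_repeat
    lst$repeat_accuracy_mean <- evalobj$repeat_accuracy_mean
    lst$repeat_accuracy_sd <- evalobj$repeat_accuracy_sd
  }
  lst
}

#' @export
print.ema_evaluation <- function(x, ...) {
  cat("Repeated-split evaluation (", nrow(x$per_repeat), " repeats, pooled)\n",
      sep = "")
  cat(sprintf("  per-repeat accuracy: %.4f +- %.4f\n",
              x$repeat_accuracy_mean, x$repeat_accuracy_sd))
  print(x$report)
  invisible(x)
}

# reproducibility record written next to every pipeline output
write_run_manifest <- function(path, stage, params, inputs = NULL) {
  man <- list(
    stage = stage,
    package = "emaclass",
    version = as.character(utils::packageVersion("emaclass")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    params = params
  )
  if (!is.null(inputs)) {
    man$inputs <- list(n = length(inputs),
                       md5 = unname(tools::md5sum(inputs)))
  }
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
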
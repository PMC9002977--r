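#' Train the full CNN + boosted-tree pipeline
#'
#' End-to-end training on a window tibble: stratified split, minority
#' augmentation of the *training* split only, CNN training with the
#' temporary softmax head, head removal, feature extraction and tuning
#' of the boosted-tree classifier on the flattened conv features. One
#' global seed deterministically derives the per-stage seeds.
#'
#' @param windows Window tibble (see [window_dataset()]).
#' @param scheme The [label_scheme()] the windows were labelled with.
#' @param fractions Split fractions, see [stratified_split()].
#' @param augmentation An [augmentation_config()] (its seed is
#'   overridden by the derived seed).
#' @param cnn A [cnn_config()].
#' @param training A [train_config()] (seed overridden likewise).
#' @param space An [xgb_search_space()].
#' @param seed Global integer seed.
#' @param nthread Threads for xgboost.
#' @return An object of class `fall_pipeline`: the trained feature
#'   extractor, the fitted booster, chosen parameters, training history
#'   and the held-out `test` window tibble.
#' @export
train_fall_pipeline <- function(windows, scheme,
                                fractions = c(train = 0.70,
                                              validation = 0.15,
                                              test = 0.15),
                                augmentation = augmentation_config(),
                                cnn = cnn_config(),
                                training = train_config(),
                                space = xgb_search_space(),
                                seed = 1L, nthread = 1L) {
  stopifnot(inherits(scheme, "label_scheme"))
  splits <- stratified_split(windows, fractions,
                             seed = derive_seed(seed, 1L))
  augmentation$seed <- derive_seed(seed, 2L)
  train_aug <- augment_minority(splits$train, augmentation)
  L <- nrow(windows$samples[[1]])
  model <- build_cnn(cnn, input_len = L, n_channels = ncol(windows$samples[[1]]),
                     classes = scheme$class_set)
  training$seed <- derive_seed(seed, 3L)
  fit <- train_cnn(model, train_aug, splits$validation, training)
  feats_tr <- extract_features(fit$model, train_aug)
  feats_va <- extract_features(fit$model, splits$validation)
  xgb <- tune_and_train_xgb(feats_tr, train_aug$label,
                            feats_va, splits$validation$label,
                            scheme$class_set, space,
                            seed = derive_seed(seed, 4L) %% 100000L,
                            nthread = nthread)
  structure(
    list(cnn = fit$model, history = fit$history, xgb = xgb$model,
         xgb_params = xgb$params, xgb_search = xgb$search,
         scheme = scheme, splits = list(
           train = splits$train, validation = splits$validation,
           test = splits$test),
         n_train_aug = nrow(train_aug), seed = seed),
    class = "fall_pipeline"
  )
}

#' Predict class labels for windows
#'
#' Deterministic: each window passes through the trained conv stack
#' (inference mode) and the boosted-tree head.
#'
#' @param object A `fall_pipeline`.
#' @param windows Window tibble.
#' @param ... Unused.
#' @return Character vector of class labels, one per window row.
#' @export
#' @method predict fall_pipeline
predict.fall_pipeline <- function(object, windows, ...) {
  feats <- extract_features(object$cnn, windows)
  if (nrow(feats) == 0) return(character(0))
  pred <- as.integer(predict(object$xgb, xgboost::xgb.DMatrix(feats)))
  object$scheme$class_set[pred + 1L]
}

#' Evaluate a trained pipeline on its held-out test split
#'
#' @param pipeline A `fall_pipeline`.
#' @param windows Window tibble to evaluate on; defaults to the
#'   pipeline's held-out test split.
#' @return A [eval_report()] `fall_eval` object.
#' @export
evaluate_pipeline <- function(pipeline, windows = pipeline$splits$test) {
  stopifnot(inherits(pipeline, "fall_pipeline"))
  eval_report(windows$label, predict(pipeline, windows),
              pipeline$scheme$class_set)
}

#' @export
print.fall_pipeline <- function(x, ...) {
  cat("<fall_pipeline: ", x$cnn$config$n_conv, "-layer CNN (",
      x$cnn$feature_dim, " features) + boosted trees>\n", sep = "")
  cat("  scheme:", x$scheme$variant, "|",
      length(x$scheme$class_set), "classes\n")
  cat("  trained epochs:", nrow(x$history),
      "| best val UAR:", sprintf("%.2f%%", max(x$history$val_uar)), "\n")
  cat("  xgb:", x$xgb_params$n_trees, "trees, depth",
      x$xgb_params$max_depth, ", lr", x$xgb_params$learning_rate, "\n")
  invisible(x)
}

#' Tidiers for fitted pipelines
#'
#' `tidy()` returns the tuning search results (one row per grid point
#' for a `fall_pipeline`; per-class metrics for a `fall_eval`);
#' `glance()` returns a one-row summary.
#'
#' @param x A `fall_pipeline` or `fall_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @name fallwatch-tidiers
NULL

#' @export
#' @method tidy fall_pipeline
#' @rdname fallwatch-tidiers
tidy.fall_pipeline <- function(x, ...) x$xgb_search

#' @export
#' @method glance fall_pipeline
#' @rdname fallwatch-tidiers
glance.fall_pipeline <- function(x, ...) {
  tibble(
    scheme = x$scheme$variant,
    n_classes = length(x$scheme$class_set),
    feature_dim = x$cnn$feature_dim,
    epochs = nrow(x$history),
    best_val_uar = max(x$history$val_uar),
    xgb_trees = x$xgb_params$n_trees,
    xgb_depth = x$xgb_params$max_depth,
    xgb_learning_rate = x$xgb_params$learning_rate,
    n_train = nrow(x$splits$train),
    n_validation = nrow(x$splits$validation),
    n_test = nrow(x$splits$test)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the CNN training history
#'
#' @param object A `fall_pipeline`.
#' @param ... Unused.
#' @return A ggplot of validation UAR and training loss by epoch.
#' @export
#' @method autoplot fall_pipeline
autoplot.fall_pipeline <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_uar"),
                           names_to = "series")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Persist and restore a trained pipeline
#'
#' The feature-extractor weights and split tibbles are stored with
#' `saveRDS()`; the booster in xgboost's native format; and a JSON
#' sidecar records the configurations, chosen parameters and label
#' scheme.
#'
#' @param pipeline A `fall_pipeline`.
#' @param dir Directory to write to (created if missing).
#' @return `save_pipeline()`: `dir`, invisibly. `load_pipeline()`: the
#'   restored `fall_pipeline`.
#' @export
save_pipeline <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "fall_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  xgb <- pipeline$xgb
  pipeline$xgb <- NULL
  saveRDS(pipeline, file.path(dir, "pipeline.rds"))
  xgboost::xgb.save(xgb, file.path(dir, "xgb.ubj"))
  sidecar <- list(
    scheme = pipeline$scheme$variant,
    classes = pipeline$scheme$class_set,
    cnn = unclass(pipeline$cnn$config),
    input_len = pipeline$cnn$input_len,
    feature_dim = pipeline$cnn$feature_dim,
    xgb_params = as.list(pipeline$xgb_params),
    seed = pipeline$seed
  )
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "pipeline.json"))
  invisible(dir)
}

#' @param dir Directory written by `save_pipeline()`.
#' @rdname save_pipeline
#' @export
load_pipeline <- function(dir) {
  pipeline <- readRDS(file.path(dir, "pipeline.rds"))
  pipeline$xgb <- xgboost::xgb.load(file.path(dir, "xgb.ubj"))
  pipeline
}
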
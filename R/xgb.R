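#' Search grid for the boosted-tree head
#'
#' The gradient-boosted-tree classifier replacing the softmax head is
#' tuned by exhaustive search over a small grid of tree count, maximum
#' depth and learning rate, selected by validation UAR (the same metric
#' that selects the CNN).
#'
#' @param n_trees,max_depth,learning_rate Candidate values; all grids
#'   must be non-empty.
#' @return An object of class `xgb_search_space` (a tibble of candidate
#'   combinations, ordered by trees, then depth, then learning rate --
#'   the tie-break order).
#' @export
xgb_search_space <- function(n_trees = c(100L, 300L, 500L),
                             max_depth = c(3L, 6L, 9L),
                             learning_rate = c(0.05, 0.1, 0.3)) {
  stopifnot(length(n_trees) > 0, length(max_depth) > 0,
            length(learning_rate) > 0)
  grid <- expand.grid(n_trees = sort(as.integer(n_trees)),
                      max_depth = sort(as.integer(max_depth)),
                      learning_rate = sort(learning_rate),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$n_trees, grid$max_depth, grid$learning_rate), ]
  structure(as_tibble(grid), class = c("xgb_search_space",
                                       class(as_tibble(grid))))
}

fit_xgb <- function(features, y_int0, k, n_trees, max_depth, learning_rate,
                    seed, nthread = 1L) {
  dtrain <- xgboost::xgb.DMatrix(features, label = y_int0)
  xgboost::xgb.train(
    params = list(objective = "multi:softmax", num_class = k,
                  max_depth = max_depth, eta = learning_rate,
                  tree_method = "hist", nthread = nthread, seed = seed),
    data = dtrain, nrounds = n_trees, verbose = 0
  )
}

#' Tune and train the boosted-tree head
#'
#' Fits one model per grid point on the training features, scores each
#' by validation UAR and keeps the best; ties are broken in favour of
#' fewer trees, then shallower depth. Deterministic given `seed`.
#'
#' @param train_features,val_features Feature matrices from
#'   [extract_features()] (column-compatible).
#' @param train_labels,val_labels Character labels aligned with the
#'   feature rows.
#' @param classes Ordered class labels (defines the integer encoding).
#' @param space An [xgb_search_space()].
#' @param seed Integer seed passed to xgboost.
#' @param nthread Threads for xgboost (1 keeps runs reproducible).
#' @return List with `model` (an `xgb.Booster`), `params` (one-row
#'   tibble of the chosen grid point and its validation UAR) and
#'   `search` (tibble of all grid points with validation UAR).
#' @export
tune_and_train_xgb <- function(train_features, train_labels,
                               val_features, val_labels, classes,
                               space = xgb_search_space(), seed = 1L,
                               nthread = 1L) {
  stopifnot(ncol(train_features) == ncol(val_features))
  k <- length(classes)
  ytr <- match(train_labels, classes) - 1L
  yva <- match(val_labels, classes) - 1L
  if (anyNA(ytr) || anyNA(yva)) abort("labels outside the class set")
  if (length(unique(ytr)) < 2) {
    abort("training labels are degenerate (single class)")
  }
  dval <- xgboost::xgb.DMatrix(val_features)
  best <- NULL
  search <- vector("list", nrow(space))
  for (i in seq_len(nrow(space))) {
    g <- space[i, ]
    fit <- fit_xgb(train_features, ytr, k, g$n_trees, g$max_depth,
                   g$learning_rate, seed, nthread)
    pred <- as.integer(predict(fit, dval))
    val_uar <- uar_int(yva + 1L, pred + 1L, k)
    search[[i]] <- dplyr::mutate(g, val_uar = val_uar)
    # strict improvement keeps the first (fewest trees, shallowest) of ties
    if (is.null(best) || val_uar > best$val_uar) {
      best <- list(model = fit, val_uar = val_uar, grid = g)
    }
  }
  list(model = best$model,
       params = dplyr::mutate(best$grid, val_uar = best$val_uar),
       search = dplyr::bind_rows(search))
}
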
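test_that("stratified split matches fractions per class and is deterministic", {
  one <- toy_windows(rep("W", 100))
  s <- stratified_split(one, seed = 1)
  expect_equal(vapply(s, nrow, integer(1)),
               c(train = 70L, validation = 15L, test = 15L))

  two <- toy_windows(rep(c("W", "FHF"), each = 20))
  s2 <- stratified_split(two, seed = 2)
  for (part in s2) {
    expect_equal(sum(part$label == "W"), sum(part$label == "FHF"))
  }
  expect_equal(nrow(s2$train) + nrow(s2$validation) + nrow(s2$test), 40L)
  # disjoint and exhaustive: every window value appears exactly once
  vals <- sort(unlist(lapply(s2, function(p) sapply(p$samples, function(m) m[1, 1]))))
  expect_equal(unname(vals), as.numeric(1:40))

  s2b <- stratified_split(two, seed = 2)
  expect_identical(s2, s2b)
  expect_error(stratified_split(toy_windows(c("W", "W", "FHF", "FHF")),
                                seed = 1),
               "FHF|W") # a class with fewer windows than splits is named
})

test_that("feature dimension follows the closed-form shape arithmetic", {
  expect_equal(cnn_feature_dim(cnn_config(), 600), 4544L) # 71 * 64
  # L = 40: per-layer lengths 38 -> 19 -> 17 -> 8 -> 6 -> 3 -> 1
  expect_equal(cnn_feature_dim(cnn_config(filters = 8), 40), 8L)
  expect_error(build_cnn(cnn_config(), 4, 6, c("A", "B")), "too small")
  m <- build_cnn(cnn_config(), 600, 6, letters[1:10])
  expect_equal(ncol(m$params$fc$W), 10L) # one logit per class
  expect_equal(nrow(m$params$fc$W), 4544L)
})

test_that("extracted features have the closed-form width and are deterministic", {
  w <- separable_windows(n_per_class = 3, L = 40)
  model <- build_cnn(cnn_config(filters = 8), 40, 6, c("A", "B"))
  f <- extract_features(model, w)
  expect_equal(ncol(f), cnn_feature_dim(cnn_config(filters = 8), 40))
  expect_equal(nrow(f), nrow(w))
  dup <- w[c(1, 1), ]
  fd <- extract_features(model, dup)
  # duplicate input, duplicate features (up to BLAS blocking order)
  expect_equal(fd[1, ], fd[2, ], tolerance = 1e-12)
  f0 <- extract_features(model, w[0, ])
  expect_equal(dim(f0), c(0L, ncol(f)))
  expect_error(extract_features(model, separable_windows(2, L = 60)),
               "length")
})

test_that("CNN training separates an easy two-class problem and stops early", {
  w <- separable_windows(n_per_class = 40, L = 40)
  s <- stratified_split(w, seed = 3)
  model <- build_cnn(cnn_config(filters = 8), 40, 6, c("A", "B"))
  fit <- train_cnn(model, s$train, s$validation,
                   train_config(max_epochs = 50, patience = 10, seed = 1))
  expect_equal(max(fit$history$val_uar), 100)
  expect_lte(nrow(fit$history), 50)
  expect_true(fit$model$trained)
  # best-epoch restore: the returned state scores the best recorded UAR
  expect_equal(max(fit$history$val_uar), 100)

  fit1 <- train_cnn(model, s$train, s$validation,
                    train_config(max_epochs = 50, patience = 0, seed = 1))
  expect_equal(nrow(fit1$history), 1L) # patience 0: exactly one epoch
})

test_that("head swap leaves the feature extractor untouched", {
  w <- separable_windows(n_per_class = 10, L = 40)
  s <- stratified_split(w, seed = 4)
  model <- build_cnn(cnn_config(filters = 8), 40, 6, c("A", "B"))
  fit <- train_cnn(model, s$train, s$validation,
                   train_config(max_epochs = 3, patience = 3, seed = 2))
  before <- extract_features(fit$model, s$test)
  headless <- fit$model
  headless$params$fc <- NULL # remove the softmax head
  after <- extract_features(headless, s$test)
  expect_identical(before, after)
})

test_that("boosted-tree tuning selects by validation UAR with stated tie-breaks", {
  # well-separated synthetic feature clouds, labels alternating A/B
  withr::with_seed(99, {
    lab <- rep(c("A", "B"), 30)
    f <- matrix(rnorm(60 * 8, mean = ifelse(lab == "B", 4, 0), sd = 0.5),
                60, 8)
  })
  w <- list(label = lab)
  idx_tr <- seq(1, 40)
  idx_va <- seq(41, 60)
  one <- xgb_search_space(50, 3, 0.3)
  r1 <- tune_and_train_xgb(f[idx_tr, ], w$label[idx_tr],
                           f[idx_va, ], w$label[idx_va],
                           c("A", "B"), one, seed = 1)
  expect_equal(r1$params$n_trees, 50L)
  expect_equal(r1$params$val_uar, 100) # separable features

  grid <- xgb_search_space(c(20, 50), c(2, 4), 0.3)
  r2 <- tune_and_train_xgb(f[idx_tr, ], w$label[idx_tr],
                           f[idx_va, ], w$label[idx_va],
                           c("A", "B"), grid, seed = 1)
  # all candidates reach 100 on separable data: ties resolve to the
  # fewest trees, then the shallowest depth
  expect_true(all(r2$search$val_uar == 100))
  expect_equal(r2$params$n_trees, 20L)
  expect_equal(r2$params$max_depth, 2L)

  r2b <- tune_and_train_xgb(f[idx_tr, ], w$label[idx_tr],
                            f[idx_va, ], w$label[idx_va],
                            c("A", "B"), grid, seed = 1)
  expect_equal(r2$params, r2b$params)

  expect_error(tune_and_train_xgb(f[1:10, ], rep("A", 10),
                                  f[idx_va, ], w$label[idx_va],
                                  c("A", "B"), one, seed = 1),
               "degenerate")
})

test_that("pipeline predictions are labels, aligned and permutation-equivariant", {
  w <- separable_windows(n_per_class = 25, L = 40)
  pipe <- train_fall_pipeline(
    w, scheme = structure(list(variant = "toy", mapping = character(),
                               class_set = c("A", "B")),
                          class = "label_scheme"),
    augmentation = augmentation_config(minority_classes = character()),
    cnn = cnn_config(filters = 8),
    training = train_config(max_epochs = 10, patience = 5),
    space = xgb_search_space(20, 3, 0.3), seed = 5)
  test <- pipe$splits$test
  pred <- predict(pipe, test)
  expect_equal(length(pred), nrow(test))
  expect_true(all(pred %in% c("A", "B")))
  perm <- sample(nrow(test))
  expect_identical(predict(pipe, test[perm, ]), pred[perm])
  g <- glance(pipe)
  expect_equal(g$feature_dim, pipe$cnn$feature_dim)
  expect_s3_class(tidy(pipe), "tbl_df")
})

test_that("a trained pipeline survives a save/load round-trip", {
  w <- separable_windows(n_per_class = 15, L = 40)
  pipe <- train_fall_pipeline(
    w, scheme = structure(list(variant = "toy", mapping = character(),
                               class_set = c("A", "B")),
                          class = "label_scheme"),
    augmentation = augmentation_config(minority_classes = character()),
    cnn = cnn_config(filters = 8),
    training = train_config(max_epochs = 5, patience = 5),
    space = xgb_search_space(20, 3, 0.3), seed = 6)
  dir <- withr::local_tempdir()
  save_pipeline(pipe, dir)
  expect_true(file.exists(file.path(dir, "pipeline.json")))
  back <- load_pipeline(dir)
  expect_identical(predict(back, pipe$splits$test),
                   predict(pipe, pipe$splits$test))
})
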
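#' CNN feature-extractor configuration
#'
#' The feature extractor is a small 1-D convolutional network applied
#' along time across the six IMU channels: four convolutional layers of
#' 64 filters each with kernels of length 3, each followed by batch
#' normalisation and a ReLU, with average pooling (length 2, stride 2)
#' condensing the output of the first three layers. Convolutions use no
#' padding and stride 1. For training, a fully connected softmax layer
#' is attached as a temporary head; after training the head is removed
#' and the flattened final feature map feeds the boosted-tree classifier.
#'
#' @param n_conv Number of conv layers (pooling follows all but the
#'   last).
#' @param filters Filters per conv layer.
#' @param kernel_len Temporal kernel length.
#' @param pool_len Average-pooling length and stride.
#'
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(n_conv = 4L, filters = 64L, kernel_len = 3L,
                       pool_len = 2L) {
  stopifnot(n_conv >= 1, filters >= 1, kernel_len >= 1, pool_len >= 1)
  structure(
    list(n_conv = as.integer(n_conv), filters = as.integer(filters),
         kernel_len = as.integer(kernel_len),
         pool_len = as.integer(pool_len)),
    class = "cnn_config"
  )
}

#' Training configuration for the CNN stage
#'
#' Plain stochastic gradient descent on the categorical cross-entropy,
#' learning rate 0.01, batch size 20. After every epoch the validation
#' unweighted average recall (UAR) is recorded; the returned parameter
#' state is the one with the highest validation UAR, and training stops
#' after `patience` epochs without improvement (early stopping) or at
#' `max_epochs`.
#'
#' @param learning_rate SGD learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Epochs without validation-UAR improvement tolerated
#'   before stopping (`0` = stop after the first epoch).
#' @param seed Integer seed (weight init and batch shuffling).
#'
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 20L,
                         max_epochs = 200L, patience = 20L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, patience >= 0,
            patience <= max_epochs, max_epochs >= 1)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# Temporal length after each layer; errors if the stack does not fit.
cnn_layer_lengths <- function(config, input_len) {
  len <- input_len
  lens <- integer(0)
  for (i in seq_len(config$n_conv)) {
    len <- len - (config$kernel_len - 1L)
    if (len < 1) {
      abort(sprintf(
        "input length %d too small for the conv stack (need >= %d)",
        input_len, cnn_min_input_len(config)))
    }
    lens <- c(lens, len)
    if (i < config$n_conv) {
      len <- len %/% config$pool_len
      if (len < 1) {
        abort(sprintf(
          "input length %d too small for the conv stack (need >= %d)",
          input_len, cnn_min_input_len(config)))
      }
      lens <- c(lens, len)
    }
  }
  lens
}

# Smallest input length for which every layer has positive output.
cnn_min_input_len <- function(config) {
  len <- 1L
  for (i in seq_len(config$n_conv)) {
    if (i < config$n_conv) len <- len * config$pool_len
    len <- len + (config$kernel_len - 1L)
  }
  len
}

#' Flattened feature dimension in closed form
#'
#' The number of columns of the feature matrix is a pure function of
#' the architecture and the window length: the temporal length after
#' the last conv layer times the filter count. With the defaults and
#' L = 600 the per-layer lengths are 598, 299, 297, 148, 146, 73, 71,
#' giving 71 * 64 = 4544 features.
#'
#' @param config A [cnn_config()].
#' @param input_len Window length L in samples.
#' @return Integer feature dimension.
#' @export
cnn_feature_dim <- function(config = cnn_config(), input_len) {
  lens <- cnn_layer_lengths(config, input_len)
  lens[length(lens)] * config$filters
}

#' Build the (untrained) CNN
#'
#' Layer sequence: `[Conv -> BatchNorm -> ReLU -> AvgPool] x 3 ->
#' Conv -> BatchNorm -> ReLU -> Flatten -> FC(k) -> softmax`. Weights
#' are He-initialised from the current RNG state; [train_cnn()]
#' re-initialises under its own seed.
#'
#' @param config A [cnn_config()].
#' @param input_len Window length L in samples.
#' @param n_channels Input channels (6 for accelerometer + gyroscope).
#' @param classes Ordered character vector of class labels (the softmax
#'   head has one logit per class).
#' @return An object of class `cnn_model`.
#' @export
build_cnn <- function(config = cnn_config(), input_len, n_channels = 6L,
                      classes) {
  stopifnot(length(classes) >= 2)
  lens <- cnn_layer_lengths(config, input_len) # validates input_len
  model <- structure(
    list(config = config, input_len = as.integer(input_len),
         n_channels = as.integer(n_channels), classes = classes,
         feature_dim = cnn_feature_dim(config, input_len),
         params = NULL, trained = FALSE),
    class = "cnn_model"
  )
  model$params <- cnn_init_params(model)
  model
}

cnn_init_params <- function(model) {
  cfg <- model$config
  k <- cfg$kernel_len
  conv <- vector("list", cfg$n_conv)
  bn <- vector("list", cfg$n_conv)
  c_in <- model$n_channels
  for (i in seq_len(cfg$n_conv)) {
    fan_in <- k * c_in
    conv[[i]] <- list(
      W = matrix(rnorm(fan_in * cfg$filters, 0, sqrt(2 / fan_in)),
                 fan_in, cfg$filters),
      b = numeric(cfg$filters)
    )
    bn[[i]] <- list(gamma = rep(1, cfg$filters),
                    beta = numeric(cfg$filters),
                    rmean = numeric(cfg$filters),
                    rvar = rep(1, cfg$filters))
    c_in <- cfg$filters
  }
  D <- model$feature_dim
  kcl <- length(model$classes)
  fc <- list(W = matrix(rnorm(D * kcl, 0, sqrt(1 / D)), D, kcl),
             b = numeric(kcl))
  list(conv = conv, bn = bn, fc = fc)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model: ", x$config$n_conv, " conv layers x ",
      x$config$filters, " filters, input ", x$input_len, " x ",
      x$n_channels, ", features ", x$feature_dim, ", ",
      length(x$classes), " classes, ",
      if (x$trained) "trained" else "untrained", ">\n", sep = "")
  invisible(x)
}

# ---- batched layer primitives ------------------------------------------
# Activations are stored as (B * T) x C matrices with rows grouped by
# window: row (b - 1) * T + t holds window b at time t.

# row indices selecting time t..t+k-1 for every window, one vector per
# kernel shift
conv_indices <- function(B, T_, k) {
  base <- as.vector(outer(seq_len(T_ - k + 1L), (seq_len(B) - 1L) * T_, "+"))
  lapply(seq_len(k) - 1L, function(s) base + s)
}

conv_fwd <- function(X, W, b, B, T_, k) {
  idx <- conv_indices(B, T_, k)
  Xc <- do.call(cbind, lapply(idx, function(i) X[i, , drop = FALSE]))
  Y <- sweep(Xc %*% W, 2, b, "+")
  list(Y = Y, Xc = Xc, idx = idx, Tout = T_ - k + 1L)
}

conv_bwd <- function(dY, cache, W, X_dim) {
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- tcrossprod(dY, W)
  C <- X_dim[2]
  dX <- matrix(0, X_dim[1], C)
  for (s in seq_along(cache$idx)) {
    cols <- ((s - 1L) * C + 1L):(s * C)
    i <- cache$idx[[s]]
    dX[i, ] <- dX[i, ] + dXc[, cols, drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

bn_fwd <- function(X, p, train, eps = 1e-5, momentum = 0.1) {
  if (train) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc^2)
    ivar <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, ivar, "*")
    p$rmean <- (1 - momentum) * p$rmean + momentum * mu
    p$rvar <- (1 - momentum) * p$rvar + momentum * v
    out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
    list(Y = out, xhat = xhat, xc = xc, ivar = ivar, p = p)
  } else {
    ivar <- 1 / sqrt(p$rvar + eps)
    xhat <- sweep(sweep(X, 2, p$rmean), 2, ivar, "*")
    list(Y = sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+"), p = p)
  }
}

bn_bwd <- function(dY, cache, gamma) {
  N <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  dvar <- colSums(dxhat * cache$xc) * (-0.5) * cache$ivar^3
  dmu <- -colSums(dxhat) * cache$ivar - 2 * dvar * colMeans(cache$xc)
  dX <- sweep(dxhat, 2, cache$ivar, "*") +
    sweep(cache$xc, 2, 2 * dvar / N, "*")
  sweep(dX, 2, dmu / N, "+")
  # dX returned with mean gradient folded in
}

bn_bwd_full <- function(dY, cache, gamma) {
  list(dX = bn_bwd(dY, cache, gamma),
       dgamma = colSums(dY * cache$xhat),
       dbeta = colSums(dY))
}

pool_fwd <- function(X, B, T_, pl) {
  Tout <- T_ %/% pl
  idx <- lapply(seq_len(pl) - 1L, function(s) {
    as.vector(outer((seq_len(Tout) - 1L) * pl + 1L + s,
                    (seq_len(B) - 1L) * T_, "+"))
  })
  Y <- Reduce(`+`, lapply(idx, function(i) X[i, , drop = FALSE])) / pl
  list(Y = Y, idx = idx, Tout = Tout)
}

pool_bwd <- function(dY, cache, X_dim, pl) {
  dX <- matrix(0, X_dim[1], X_dim[2])
  for (i in cache$idx) dX[i, ] <- dY / pl
  dX
}

flatten_rows <- function(X, B) matrix(t(X), nrow = B, byrow = TRUE)
unflatten_rows <- function(Fm, C) matrix(as.vector(t(Fm)), ncol = C,
                                         byrow = TRUE)

# Forward through the conv stack. Returns the flattened feature matrix
# and (in training mode) the caches needed for backprop.
cnn_forward_features <- function(model, X, B, train = FALSE) {
  cfg <- model$config
  p <- model$params
  T_ <- model$input_len
  caches <- list()
  for (i in seq_len(cfg$n_conv)) {
    cv <- conv_fwd(X, p$conv[[i]]$W, p$conv[[i]]$b, B, T_, cfg$kernel_len)
    bn <- bn_fwd(cv$Y, p$bn[[i]], train)
    p$bn[[i]] <- bn$p
    Y <- pmax(bn$Y, 0)
    if (train) {
      caches[[i]] <- list(conv = cv, bn = bn, relu_mask = bn$Y > 0,
                          X_dim = dim(X), T_in = T_)
    }
    T_ <- cv$Tout
    if (i < cfg$n_conv) {
      pool <- pool_fwd(Y, B, T_, cfg$pool_len)
      if (train) {
        caches[[i]]$pool <- pool
        caches[[i]]$prepool_dim <- dim(Y)
      }
      Y <- pool$Y
      T_ <- pool$Tout
    }
    X <- Y
  }
  list(features = flatten_rows(X, B), caches = caches, params = p,
       final_T = T_)
}

# One forward + backward pass over a batch; returns loss and gradients.
cnn_batch_grad <- function(model, X, y_int, B) {
  cfg <- model$config
  fwd <- cnn_forward_features(model, X, B, train = TRUE)
  Fm <- fwd$features
  fc <- model$params$fc
  logits <- sweep(Fm %*% fc$W, 2, fc$b, "+")
  zmax <- apply(logits, 1, max)
  ez <- exp(logits - zmax)
  prob <- ez / rowSums(ez)
  loss <- -mean(log(pmax(prob[cbind(seq_len(B), y_int)], 1e-12)))
  dZ <- prob
  dZ[cbind(seq_len(B), y_int)] <- dZ[cbind(seq_len(B), y_int)] - 1
  dZ <- dZ / B
  grads <- list(conv = vector("list", cfg$n_conv),
                bn = vector("list", cfg$n_conv),
                fc = list(W = crossprod(Fm, dZ), b = colSums(dZ)))
  dFm <- tcrossprod(dZ, fc$W)
  dX <- unflatten_rows(dFm, cfg$filters)
  for (i in rev(seq_len(cfg$n_conv))) {
    cache <- fwd$caches[[i]]
    if (i < cfg$n_conv) {
      dX <- pool_bwd(dX, cache$pool, cache$prepool_dim, cfg$pool_len)
    }
    dX <- dX * cache$relu_mask
    bnb <- bn_bwd_full(dX, cache$bn, model$params$bn[[i]]$gamma)
    grads$bn[[i]] <- list(dgamma = bnb$dgamma, dbeta = bnb$dbeta)
    cvb <- conv_bwd(bnb$dX, cache$conv, model$params$conv[[i]]$W,
                    cache$X_dim)
    grads$conv[[i]] <- list(dW = cvb$dW, db = cvb$db)
    dX <- cvb$dX
  }
  list(loss = loss, grads = grads, bn_params = fwd$params$bn)
}

cnn_sgd_step <- function(params, grads, lr) {
  for (i in seq_along(params$conv)) {
    params$conv[[i]]$W <- params$conv[[i]]$W - lr * grads$conv[[i]]$dW
    params$conv[[i]]$b <- params$conv[[i]]$b - lr * grads$conv[[i]]$db
    params$bn[[i]]$gamma <- params$bn[[i]]$gamma - lr * grads$bn[[i]]$dgamma
    params$bn[[i]]$beta <- params$bn[[i]]$beta - lr * grads$bn[[i]]$dbeta
  }
  params$fc$W <- params$fc$W - lr * grads$fc$W
  params$fc$b <- params$fc$b - lr * grads$fc$b
  params
}

# Stack a window tibble into one (N * L) x C matrix plus integer labels.
windows_to_matrix <- function(windows, classes) {
  X <- do.call(rbind, windows$samples)
  y <- match(windows$label, classes)
  if (anyNA(y)) {
    abort(paste0("labels outside the model's class set: ",
                 paste(unique(windows$label[is.na(y)]), collapse = ", ")))
  }
  list(X = X, y = y)
}

batch_rows <- function(idx, T_) {
  as.vector(vapply(idx, function(b) ((b - 1L) * T_ + 1L):(b * T_),
                   integer(T_)))
}

# Softmax-head predictions (integer class indices), eval mode, batched.
cnn_predict_int <- function(model, X, N, batch = 64L) {
  T_ <- model$input_len
  out <- integer(N)
  for (s in seq(1L, N, by = batch)) {
    e <- min(s + batch - 1L, N)
    idx <- s:e
    Xb <- X[batch_rows(idx, T_), , drop = FALSE]
    Fm <- cnn_forward_features(model, Xb, length(idx), train = FALSE)$features
    logits <- sweep(Fm %*% model$params$fc$W, 2, model$params$fc$b, "+")
    out[idx] <- max.col(logits, ties.method = "first")
  }
  out
}

# Unweighted average recall of integer predictions, as a percentage.
uar_int <- function(y_true, y_pred, k) {
  recalls <- vapply(seq_len(k), function(c) {
    n <- sum(y_true == c)
    if (n == 0) return(NA_real_)
    100 * sum(y_true == c & y_pred == c) / n
  }, numeric(1))
  mean(recalls, na.rm = TRUE)
}

#' Train the CNN with its temporary softmax head
#'
#' Minimises the categorical cross-entropy by plain SGD (learning rate
#' and batch size from `config`), recording the validation UAR after
#' every epoch. Returns the parameter state of the best validation
#' epoch; stops early after `config$patience` epochs without
#' improvement.
#'
#' @param model A [build_cnn()] model.
#' @param train,validation Window tibbles (training windows are
#'   typically augmented first; validation windows never are).
#' @param config A [train_config()].
#' @return List with `model` (trained `cnn_model`) and `history`
#'   (tibble: `epoch`, `train_loss`, `val_uar` in percent).
#' @export
train_cnn <- function(model, train, validation, config = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  if (nrow(train) == 0 || nrow(validation) == 0) {
    abort("train and validation splits must be non-empty")
  }
  k <- length(model$classes)
  tr <- windows_to_matrix(train, model$classes)
  va <- windows_to_matrix(validation, model$classes)
  n_tr <- nrow(train)
  n_va <- nrow(validation)
  T_ <- model$input_len

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  model$params <- cnn_init_params(model)

  best <- list(uar = -Inf, params = model$params, epoch = 0L)
  history <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n_tr)
    losses <- numeric(0)
    for (s in seq(1L, n_tr, by = config$batch_size)) {
      e <- min(s + config$batch_size - 1L, n_tr)
      bidx <- perm[s:e]
      Xb <- tr$X[batch_rows(bidx, T_), , drop = FALSE]
      res <- cnn_batch_grad(model, Xb, tr$y[bidx], length(bidx))
      model$params$bn <- res$bn_params # running stats
      model$params <- cnn_sgd_step(model$params, res$grads,
                                   config$learning_rate)
      losses <- c(losses, res$loss)
    }
    val_pred <- cnn_predict_int(model, va$X, n_va)
    val_uar <- uar_int(va$y, val_pred, k)
    history[[epoch]] <- tibble(epoch = epoch,
                               train_loss = mean(losses),
                               val_uar = val_uar)
    if (val_uar > best$uar) {
      best <- list(uar = val_uar, params = model$params, epoch = epoch)
    }
    if (epoch - best$epoch >= config$patience) break
  }
  model$params <- best$params
  model$trained <- TRUE
  list(model = model, history = dplyr::bind_rows(history))
}

#' Extract flattened convolutional features
#'
#' Forward pass through the conv stack only (inference mode: batch norm
#' uses its learned running statistics); the softmax head plays no part,
#' so the features are identical before and after the head swap.
#'
#' @param model A trained `cnn_model`.
#' @param windows Window tibble; rows of the result align with rows of
#'   `windows`.
#' @param batch Windows per forward batch.
#' @return Numeric matrix, `nrow(windows)` x `model$feature_dim`.
#' @export
extract_features <- function(model, windows, batch = 64L) {
  stopifnot(inherits(model, "cnn_model"))
  N <- nrow(windows)
  if (N == 0) return(matrix(numeric(0), 0, model$feature_dim))
  if (nrow(windows$samples[[1]]) != model$input_len) {
    abort(sprintf("window length %d does not match the model input length %d",
                  nrow(windows$samples[[1]]), model$input_len))
  }
  X <- do.call(rbind, windows$samples)
  T_ <- model$input_len
  out <- matrix(NA_real_, N, model$feature_dim)
  for (s in seq(1L, N, by = batch)) {
    e <- min(s + batch - 1L, N)
    idx <- s:e
    Xb <- X[batch_rows(idx, T_), , drop = FALSE]
    out[idx, ] <- cnn_forward_features(model, Xb, length(idx),
                                       train = FALSE)$features
  }
  out
}
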
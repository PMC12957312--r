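# Latent extraction and temporal-convolution classifiers.
#
# The latent step is a linear projection onto the top principal axes of
# the smoothed, trial-concatenated population activity; it keeps the
# M x dim x T contract that downstream decoding relies on. The classifier
# is a small two-layer temporal CNN (8 filters per layer, kernel 3,
# stride 1, zero padding 1, ReLU + max-pool(2) after each layer, dropout
# 0.5 before a softmax head), trained by minibatch gradient descent on
# cross-entropy. Evaluation with frozen parameters is a pure forward pass.

#' Extract low-dimensional latent trajectories
#'
#' Smooths single trials and projects them onto the top `dim` principal
#' axes of the trial-concatenated data. The fitted projection can be
#' reused for held-out tasks of the same session by passing it back via
#' `projection`.
#'
#' @param session a `session_data` object.
#' @param dim latent dimensionality (default 16; must not exceed units).
#' @param tasks tasks to include (default all).
#' @param sigma_ms smoothing kernel SD in ms.
#' @param projection optional projection (as returned in the result's
#'   `projection` field) to reuse instead of refitting.
#' @return an object of class `latent_tensor`: `values` (M x dim x T),
#'   `labels` (trial table rows carried through, in trial order),
#'   `projection` (rotation, center, sdev), `dim`.
#' @export
extract_latent <- function(session, dim = 16, tasks = NULL, sigma_ms = 50,
                           projection = NULL) {
  stopifnot(inherits(session, "session_data"))
  keep <- if (is.null(tasks)) {
    rep(TRUE, nrow(session$trials))
  } else {
    session$trials$task %in% tasks
  }
  if (!any(keep)) stop("no trials in the requested task subset")
  x <- smooth_rates(session$spike_counts[keep, , , drop = FALSE],
                    sigma_ms = sigma_ms, bin_ms = session$bin_ms)
  d <- dim(x)                                   # M x N x T
  if (!is.null(projection)) dim <- ncol(projection$rotation)
  if (dim > d[2]) {
    stop(sprintf("latent dim %d exceeds the %d available units", dim, d[2]))
  }
  mat <- matrix(aperm(x, c(1, 3, 2)), d[1] * d[3], d[2])  # (m,t) x units
  if (is.null(projection)) {
    center <- colMeans(mat)
    cmat <- sweep(mat, 2, center)
    cv <- crossprod(cmat) / (nrow(cmat) - 1)
    eg <- eigen(cv, symmetric = TRUE)
    projection <- list(rotation = eg$vectors[, seq_len(dim), drop = FALSE],
                       center = center,
                       sdev = sqrt(pmax(eg$values, 0)))
  } else {
    cmat <- sweep(mat, 2, projection$center)
  }
  scores <- cmat %*% projection$rotation        # (m,t) x dim
  values <- aperm(array(scores, c(d[1], d[3], dim)), c(1, 3, 2))
  structure(list(values = values,
                 labels = session$trials[keep, , drop = FALSE],
                 projection = projection, dim = dim),
            class = "latent_tensor")
}

# ---- CNN internals --------------------------------------------------------

cnn_init <- function(n_channels, n_bins, n_classes, n_filters = 8,
                     kernel = 3) {
  t2 <- floor(n_bins / 2)
  t4 <- floor(t2 / 2)
  if (t4 < 1) stop("time axis too short for two pooling stages")
  n_feat <- n_filters * t4
  list(
    W1 = matrix(rnorm(n_filters * n_channels * kernel,
                      sd = sqrt(2 / (n_channels * kernel))), n_filters),
    b1 = numeric(n_filters),
    W2 = matrix(rnorm(n_filters * n_filters * kernel,
                      sd = sqrt(2 / (n_filters * kernel))), n_filters),
    b2 = numeric(n_filters),
    Wfc = matrix(rnorm(n_classes * n_feat, sd = sqrt(2 / n_feat)),
                 n_classes),
    bfc = numeric(n_classes)
  )
}

cnn_im2col <- function(x, kernel) {
  # x: (C, T, B) -> (C*kernel, T*B) with zero padding (kernel-1)/2
  d <- dim(x)
  pad <- (kernel - 1) / 2
  xp <- array(0, c(d[1], d[2] + 2 * pad, d[3]))
  xp[, pad + seq_len(d[2]), ] <- x
  p <- array(0, c(d[1], kernel, d[2], d[3]))
  for (k in seq_len(kernel)) {
    p[, k, , ] <- xp[, k:(k + d[2] - 1), , drop = FALSE]
  }
  matrix(p, d[1] * kernel, d[2] * d[3])
}

cnn_col2im <- function(dp, n_channels, kernel, n_bins, n_batch) {
  pad <- (kernel - 1) / 2
  dp <- array(dp, c(n_channels, kernel, n_bins, n_batch))
  dxp <- array(0, c(n_channels, n_bins + 2 * pad, n_batch))
  for (k in seq_len(kernel)) {
    span <- k:(k + n_bins - 1)
    dxp[, span, ] <- array(dxp[, span, ], c(n_channels, n_bins, n_batch)) +
      array(dp[, k, , ], c(n_channels, n_bins, n_batch))
  }
  dxp[, pad + seq_len(n_bins), , drop = FALSE]
}

cnn_pool <- function(a) {
  # max-pool width 2 along time; a: (F, T, B)
  d <- dim(a)
  t2 <- floor(d[2] / 2)
  a1 <- a[, 2 * seq_len(t2) - 1, , drop = FALSE]
  a2 <- a[, 2 * seq_len(t2), , drop = FALSE]
  out <- a1
  sel2 <- a2 > a1
  out[sel2] <- a2[sel2]
  list(out = out, sel2 = sel2, t_in = d[2])
}

cnn_unpool <- function(dout, pool) {
  d <- dim(dout)
  da <- array(0, c(d[1], pool$t_in, d[3]))
  odd <- dout
  odd[pool$sel2] <- 0
  even <- dout
  even[!pool$sel2] <- 0
  da[, 2 * seq_len(d[2]) - 1, ] <- odd
  da[, 2 * seq_len(d[2]), ] <- even
  da
}

# Forward pass (and optionally gradients) for a batch.
# x: (C, T, B); y: integer class index per batch element or NULL.
# dropout_mask: NULL (evaluation / no dropout) or 0/1-over-keep matrix.
cnn_forward <- function(params, x, y = NULL, kernel = 3,
                        dropout_mask = NULL, want_grad = FALSE) {
  d <- dim(x)
  n_batch <- d[3]
  p1 <- cnn_im2col(x, kernel)
  z1 <- params$W1 %*% p1 + params$b1
  a1 <- pmax(z1, 0)
  f <- nrow(params$W1)
  pool1 <- cnn_pool(array(a1, c(f, d[2], n_batch)))
  t2 <- dim(pool1$out)[2]
  p2 <- cnn_im2col(pool1$out, kernel)
  z2 <- params$W2 %*% p2 + params$b2
  a2 <- pmax(z2, 0)
  pool2 <- cnn_pool(array(a2, c(f, t2, n_batch)))
  t4 <- dim(pool2$out)[2]
  feats <- matrix(pool2$out, f * t4, n_batch)
  if (!is.null(dropout_mask)) feats <- feats * dropout_mask
  logits <- params$Wfc %*% feats + params$bfc
  lmax <- apply(logits, 2, max)
  el <- exp(sweep(logits, 2, lmax))
  probs <- sweep(el, 2, colSums(el), "/")

  loss <- NULL
  if (!is.null(y)) {
    loss <- -mean(log(pmax(probs[cbind(y, seq_len(n_batch))], 1e-12)))
  }
  if (!want_grad) return(list(probs = probs, loss = loss))

  dlogits <- probs
  dlogits[cbind(y, seq_len(n_batch))] <-
    dlogits[cbind(y, seq_len(n_batch))] - 1
  dlogits <- dlogits / n_batch
  g <- list()
  g$Wfc <- dlogits %*% t(feats)
  g$bfc <- rowSums(dlogits)
  dfeats <- crossprod(params$Wfc, dlogits)
  if (!is.null(dropout_mask)) dfeats <- dfeats * dropout_mask
  da2p <- array(dfeats, c(f, t4, n_batch))
  da2 <- matrix(cnn_unpool(da2p, pool2), f, t2 * n_batch)
  dz2 <- da2 * (z2 > 0)
  g$W2 <- dz2 %*% t(p2)
  g$b2 <- rowSums(dz2)
  dp2 <- crossprod(params$W2, dz2)
  dpool1 <- cnn_col2im(dp2, f, kernel, t2, n_batch)
  da1 <- matrix(cnn_unpool(dpool1, pool1), f, d[2] * n_batch)
  dz1 <- da1 * (z1 > 0)
  g$W1 <- dz1 %*% t(p1)
  g$b1 <- rowSums(dz1)
  list(probs = probs, loss = loss, grads = g)
}

latent_values <- function(latents) {
  if (inherits(latents, "latent_tensor")) latents$values else latents
}

# trials x C x T array -> (C, T, B) batch for the selected trials
as_batch <- function(values, idx) {
  aperm(values[idx, , , drop = FALSE], c(2, 3, 1))
}

cnn_train <- function(values, y, n_classes, seed, n_filters = 8, kernel = 3,
                      dropout = 0.5, lr = 0.05, epochs = 200,
                      batch_size = 32, patience = 20, tol = 1e-4) {
  d <- dim(values)                              # M x C x T
  m <- d[1]
  with_seed(seed, {
    params <- cnn_init(d[2], d[3], n_classes, n_filters, kernel)
    t4 <- floor(floor(d[3] / 2) / 2)
    n_feat <- n_filters * t4
    best <- Inf
    stall <- 0
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(m)
      total <- 0
      for (start in seq(1, m, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, m)]
        xb <- as_batch(values, idx)
        mask <- if (dropout > 0) {
          matrix(rbinom(n_feat * length(idx), 1, 1 - dropout) /
                   (1 - dropout), n_feat)
        } else {
          NULL
        }
        fw <- cnn_forward(params, xb, y[idx], kernel, mask, want_grad = TRUE)
        for (nm in names(fw$grads)) {
          params[[nm]] <- params[[nm]] - lr * fw$grads[[nm]]
        }
        total <- total + fw$loss * length(idx)
      }
      avg <- total / m
      if (avg < best - tol) {
        best <- avg
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= patience) break
      }
    }
    params
  })
}

decoder_predict_idx <- function(model, values, idx = NULL) {
  idx <- idx %||% seq_len(dim(values)[1])
  xb <- as_batch(values, idx)
  fw <- cnn_forward(model$params, xb, kernel = model$kernel)
  max.col(t(fw$probs), ties.method = "first")
}

#' Train a temporal-convolution classifier on latent trajectories
#'
#' Splits the trials into a stratified train/holdout partition, trains the
#' two-layer temporal CNN by minibatch gradient descent on cross-entropy
#' (with early stopping when the training loss plateaus), and reports the
#' holdout accuracy. Dropout is active only during training; evaluation is
#' deterministic.
#'
#' @param latents a `latent_tensor` or an M x channels x bins array.
#' @param labels class label per trial (coerced to factor).
#' @param split fraction of trials used for training (default 0.8).
#' @param seed integer seed controlling split, initialization, dropout and
#'   batch order.
#' @param n_filters,kernel,dropout architecture settings (defaults 8, 3,
#'   0.5).
#' @param lr,epochs,batch_size,patience,tol optimizer settings.
#' @return an object of class `decoder_model` with the learned parameters,
#'   class set, `holdout_accuracy` and a `train_accuracy` snapshot.
#' @export
train_decoder <- function(latents, labels, split = 0.8, seed = 1,
                          n_filters = 8, kernel = 3, dropout = 0.5,
                          lr = 0.05, epochs = 200, batch_size = 32,
                          patience = 20, tol = 1e-4) {
  values <- latent_values(latents)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (length(labels) != dim(values)[1]) {
    stop("labels must have one entry per trial")
  }
  y <- as.integer(labels)
  split_idx <- with_seed(seed, {
    train <- integer(0)
    for (cl in seq_len(nlevels(labels))) {
      cls <- which(y == cl)
      if (length(cls) == 0) stop("class with zero trials")
      n_train <- max(1, round(split * length(cls)))
      train <- c(train, sample(cls, n_train))
    }
    sort(train)
  })
  if (any(tabulate(y[split_idx], nlevels(labels)) == 0)) {
    stop("a class has zero training trials")
  }
  params <- cnn_train(values[split_idx, , , drop = FALSE], y[split_idx],
                      nlevels(labels), seed = seed + 1,
                      n_filters = n_filters, kernel = kernel,
                      dropout = dropout, lr = lr, epochs = epochs,
                      batch_size = batch_size, patience = patience,
                      tol = tol)
  model <- structure(list(params = params, classes = levels(labels),
                          kernel = kernel, n_filters = n_filters,
                          dropout = dropout, seed = seed,
                          frozen = TRUE),
                     class = "decoder_model")
  pred_train <- decoder_predict_idx(model, values, split_idx)
  model$train_accuracy <- mean(pred_train == y[split_idx])
  holdout <- setdiff(seq_along(y), split_idx)
  model$holdout_accuracy <- if (length(holdout) > 0) {
    mean(decoder_predict_idx(model, values, holdout) == y[holdout])
  } else {
    NA_real_
  }
  model
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf(
    "<decoder_model> %d classes (%s); holdout accuracy %.3f\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    x$holdout_accuracy))
  invisible(x)
}

#' Evaluate a frozen decoder on new data
#'
#' Forward pass only: no parameter is updated, so a decoder trained on one
#' task can be tested on another task's trials.
#'
#' @param model a `decoder_model`.
#' @param latents a `latent_tensor` or M x channels x bins array. For
#'   meaningful results the latents must come from the same projection as
#'   the training data (see `projection` in [extract_latent()]).
#' @param labels true class label per trial; every label must belong to
#'   the model's class set.
#' @return classification accuracy (fraction correct).
#' @export
cross_task_eval <- function(model, latents, labels) {
  stopifnot(inherits(model, "decoder_model"))
  values <- latent_values(latents)
  labels <- as.character(labels)
  if (!all(labels %in% model$classes)) {
    stop(sprintf("unseen class label(s): %s",
                 paste(setdiff(unique(labels), model$classes),
                       collapse = ", ")))
  }
  pred <- model$classes[decoder_predict_idx(model, values)]
  mean(pred == labels)
}

#' Stratified k-fold cross-validated decoding accuracy
#'
#' @param latents a `latent_tensor` or M x channels x bins array.
#' @param labels class label per trial.
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment and per-fold training.
#' @param ... further arguments passed to the trainer (architecture and
#'   optimizer settings as in [train_decoder()]).
#' @return list with `mean`, `sd` and the per-fold `accuracies`.
#' @export
kfold_accuracy <- function(latents, labels, k = 10, seed = 1, ...) {
  k <- assert_count(k, "k")
  if (k < 2) stop("`k` must be at least 2")
  values <- latent_values(latents)
  labels <- factor(labels)
  y <- as.integer(labels)
  m <- length(y)
  folds <- with_seed(seed, {
    f <- integer(m)
    counter <- 0L
    for (cl in seq_len(nlevels(labels))) {
      cls <- sample(which(y == cl))
      # deal folds round-robin, continuing the cycle across classes so
      # that every fold is populated even when k exceeds a class size
      f[cls] <- (counter + seq_along(cls) - 1L) %% k + 1L
      counter <- counter + length(cls)
    }
    f
  })
  if (any(tabulate(folds, k) == 0)) {
    stop("some folds are empty; reduce k")
  }
  dots <- list(...)
  acc <- vapply(seq_len(k), function(fold) {
    test <- which(folds == fold)
    train <- which(folds != fold)
    if (any(tabulate(y[train], nlevels(labels)) == 0)) {
      stop("a class is absent from a training fold; reduce k")
    }
    args <- c(list(values = values[train, , , drop = FALSE],
                   y = y[train], n_classes = nlevels(labels),
                   seed = seed + fold), dots)
    params <- do.call(cnn_train, args)
    model <- structure(list(params = params, classes = levels(labels),
                            kernel = dots$kernel %||% 3),
                       class = "decoder_model")
    mean(decoder_predict_idx(model, values, test) == y[test])
  }, numeric(1))
  list(mean = mean(acc), sd = sd(acc), accuracies = acc)
}
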
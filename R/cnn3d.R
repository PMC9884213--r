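# The 17-layer 3D convolutional classifier.
#
# Feature-extraction block (13 layers): input + 4 stages of
# [3x3x3 convolution -> stride-2 max pool -> ReLU activation with batch
# normalization].  Classification block (4 layers): flatten, dense(512),
# dropout(0.60), dense+softmax(2).  The feature block is pretrained on a
# synthetic volumetric proxy task and frozen; only the classification block
# trains on the dental volumes.  All compute is double precision through
# BLAS (im2col + GEMM in C++), single-threaded and fully seeded, so runs
# are bit-reproducible.

#' Architecture configuration of the volumetric classifier
#'
#' @param input_shape cubic input edge(s); must be divisible by 2^4 = 16 so
#'   four stride-2 pools are valid.
#' @param filters convolution filter schedule for the four stages.
#' @param dense_width width of the dense layer in the classification block.
#' @param dropout dropout rate before the softmax layer.
#' @param classes number of output classes.
#' @return An `cnn_architecture` list.
#' @export
cnn_architecture <- function(input_shape = c(32L, 32L, 32L),
                             filters = c(64L, 128L, 256L, 256L),
                             dense_width = 512L, dropout = 0.60,
                             classes = 2L) {
  input_shape <- as.integer(rep(input_shape, length.out = 3))
  if (any(input_shape %% 16L != 0L))
    stop_crownforge("input shape must be divisible by 2^4 for four stride-2 pools",
                    "architecture_error")
  stopifnot(length(filters) == 4, dropout >= 0, dropout < 1, classes >= 2)
  structure(list(input_shape = input_shape, filters = as.integer(filters),
                 kernel = c(3L, 3L, 3L), pool_stride = 2L,
                 dense_width = as.integer(dense_width), dropout = dropout,
                 classes = as.integer(classes)),
            class = "cnn_architecture")
}

#' Layer accounting table
#'
#' Enumerates the 17 layers: the input layer plus four
#' convolution/pool/activation-normalization triples form the 13-layer
#' feature-extraction block; flatten, dense, dropout and softmax form the
#' 4-layer classification block.
#'
#' @param arch a [cnn_architecture()].
#' @return `data.frame` with columns `layer`, `block`, `type`.
#' @export
cnn_layer_table <- function(arch = cnn_architecture()) {
  rows <- list(data.frame(block = "feature", type = "input"))
  for (i in 1:4) {
    rows <- c(rows, list(data.frame(
      block = "feature",
      type = c(sprintf("conv3d_%d (3x3x3, %d filters)", i, arch$filters[i]),
               sprintf("maxpool3d_%d (stride 2)", i),
               sprintf("relu_bn_%d", i)))))
  }
  rows <- c(rows, list(data.frame(
    block = "classification",
    type = c("flatten", sprintf("dense (%d)", arch$dense_width),
             sprintf("dropout (%.2f)", arch$dropout),
             sprintf("dense_softmax (%d)", arch$classes)))))
  out <- do.call(rbind, rows)
  out$layer <- seq_len(nrow(out))
  out[, c("layer", "block", "type")]
}

# He-uniform initialization helper
he_init <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build the classifier with freshly initialized weights
#'
#' @param arch a [cnn_architecture()].
#' @param seed integer seed for weight initialization.
#' @return A `cnn_model` list of layers with weights, batch-norm running
#'   statistics and freeze flags.
#' @export
build_cnn <- function(arch = cnn_architecture(), seed = 1L) {
  stopifnot(inherits(arch, "cnn_architecture"))
  with_seed(derive_seed(seed, "init"), {
    layers <- list()
    c_in <- 1L
    side <- arch$input_shape
    for (i in 1:4) {
      f <- arch$filters[i]
      layers[[length(layers) + 1L]] <- list(
        type = "conv3d", name = sprintf("conv%d", i), block = "feature",
        w = he_init(f, 27L * c_in, 27L * c_in), b = numeric(f),
        frozen = FALSE)
      layers[[length(layers) + 1L]] <- list(
        type = "maxpool3d", name = sprintf("pool%d", i), block = "feature")
      layers[[length(layers) + 1L]] <- list(
        type = "relu_bn", name = sprintf("relu_bn%d", i), block = "feature",
        gamma = rep(1, f), beta = numeric(f),
        run_mean = numeric(f), run_var = rep(1, f), momentum = 0.9,
        frozen = FALSE)
      c_in <- f
      side <- side %/% 2L
    }
    n_flat <- prod(side) * c_in
    layers[[length(layers) + 1L]] <- list(
      type = "flatten", name = "flatten", block = "classification")
    layers[[length(layers) + 1L]] <- list(
      type = "dense", name = "dense1", block = "classification",
      w = he_init(arch$dense_width, n_flat, n_flat),
      b = numeric(arch$dense_width), activation = "relu", frozen = FALSE)
    layers[[length(layers) + 1L]] <- list(
      type = "dropout", name = "dropout", block = "classification",
      rate = arch$dropout)
    layers[[length(layers) + 1L]] <- list(
      type = "dense", name = "dense_softmax", block = "classification",
      w = he_init(arch$classes, arch$dense_width, arch$dense_width),
      b = numeric(arch$classes), activation = "softmax", frozen = FALSE)
    structure(list(arch = arch, layers = layers), class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  tab <- cnn_layer_table(x$arch)
  cat(sprintf("<cnn_model> %d layers (%d feature + %d classification), %s trainable parameters\n",
              nrow(tab), sum(tab$block == "feature"),
              sum(tab$block == "classification"),
              format(trainable_parameter_count(x), big.mark = ",")))
  invisible(x)
}

# parameter count of one layer
layer_param_count <- function(ly) {
  switch(ly$type,
         conv3d = length(ly$w) + length(ly$b),
         relu_bn = length(ly$gamma) + length(ly$beta),
         dense = length(ly$w) + length(ly$b),
         0L)
}

#' Count trainable (non-frozen) parameters
#' @param model a `cnn_model`.
#' @param total if `TRUE`, count all parameters regardless of freezing.
#' @return Integer parameter count.
#' @export
trainable_parameter_count <- function(model, total = FALSE) {
  sum(vapply(model$layers, function(ly) {
    if (!total && isTRUE(ly$frozen)) return(0L)
    as.integer(layer_param_count(ly))
  }, integer(1)))
}

#' Freeze or unfreeze the feature-extraction block
#'
#' Frozen layers (convolutions and batch-norm statistics of the feature
#' block) are excluded from gradient updates; the trainable parameter count
#' then equals the classification block alone.
#'
#' @param model a `cnn_model`.
#' @return The model with updated freeze flags.
#' @export
freeze_feature_block <- function(model) {
  model$layers <- lapply(model$layers, function(ly) {
    if (identical(ly$block, "feature") && !is.null(ly$frozen))
      ly$frozen <- TRUE
    ly
  })
  model
}

#' @rdname freeze_feature_block
#' @export
unfreeze_feature_block <- function(model) {
  model$layers <- lapply(model$layers, function(ly) {
    if (!is.null(ly$frozen)) ly$frozen <- FALSE
    ly
  })
  model
}

feature_block_frozen <- function(model) {
  all(vapply(model$layers, function(ly) {
    !identical(ly$block, "feature") || is.null(ly$frozen) || isTRUE(ly$frozen)
  }, logical(1)))
}

# ---- forward / backward ----------------------------------------------------

# x: numeric array dim (C, D, H, W, N)
as_batch <- function(volumes) {
  d <- dim(volumes[[1]])
  x <- array(0, c(1L, d, length(volumes)))
  for (i in seq_along(volumes)) x[1, , , , i] <- as.numeric(volumes[[i]])
  x
}

cnn_forward <- function(model, x, training = FALSE, keep_cache = FALSE,
                        start_layer = 1L) {
  caches <- vector("list", length(model$layers))
  layers <- model$layers
  for (li in seq_along(layers)) {
    if (li < start_layer) next
    ly <- layers[[li]]
    if (ly$type == "conv3d") {
      if (keep_cache) caches[[li]] <- list(x = x, xdim = dim(x))
      x <- cpp_conv3d_fwd(x, dim(x), ly$w, ly$b)
    } else if (ly$type == "maxpool3d") {
      res <- cpp_maxpool3d_fwd(x, dim(x))
      if (keep_cache) caches[[li]] <- list(idx = res$idx, xdim = dim(x))
      x <- res$y
    } else if (ly$type == "relu_bn") {
      d <- dim(x)
      xm <- matrix(x, nrow = d[1])
      relu_mask <- xm > 0
      xm <- xm * relu_mask
      if (training && !isTRUE(ly$frozen)) {
        mu <- rowMeans(xm)
        v <- rowMeans(xm^2) - mu^2
        model$layers[[li]]$run_mean <- ly$momentum * ly$run_mean +
          (1 - ly$momentum) * mu
        model$layers[[li]]$run_var <- ly$momentum * ly$run_var +
          (1 - ly$momentum) * v
      } else {
        mu <- ly$run_mean
        v <- ly$run_var
      }
      inv_sd <- 1 / sqrt(v + 1e-5)
      xhat <- (xm - mu) * inv_sd
      out <- xhat * ly$gamma + ly$beta
      if (keep_cache)
        caches[[li]] <- list(relu_mask = relu_mask, xhat = xhat,
                             inv_sd = inv_sd, dims = d)
      x <- array(out, d)
    } else if (ly$type == "flatten") {
      d <- dim(x)
      n <- d[length(d)]
      if (keep_cache) caches[[li]] <- list(xdim = d)
      x <- matrix(x, ncol = n)  # features x N
    } else if (ly$type == "dense") {
      if (keep_cache) caches[[li]] <- list(x = x)
      z <- ly$w %*% x + ly$b
      if (identical(ly$activation, "relu")) {
        mask <- z > 0
        if (keep_cache) caches[[li]]$mask <- mask
        x <- z * mask
      } else if (identical(ly$activation, "softmax")) {
        z <- sweep(z, 2, apply(z, 2, max))
        e <- exp(z)
        x <- sweep(e, 2, colSums(e), "/")
      } else x <- z
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- matrix(runif(length(x)) >= ly$rate, nrow(x)) / (1 - ly$rate)
        if (keep_cache) caches[[li]] <- list(mask = mask)
        x <- x * mask
      }
    }
  }
  list(out = x, caches = caches, model = model)
}

# backward pass from softmax + cross-entropy; y_onehot: classes x N.
# Returns list of gradients parallel to model$layers.
cnn_backward <- function(model, fwd, y_onehot, start_layer = 1L) {
  layers <- model$layers
  grads <- vector("list", length(layers))
  n <- ncol(y_onehot)
  delta <- (fwd$out - y_onehot) / n  # d loss / d logits of softmax layer
  for (li in rev(seq_along(layers))) {
    if (li < start_layer) break
    ly <- layers[[li]]
    cache <- fwd$caches[[li]]
    if (ly$type == "dense") {
      if (identical(ly$activation, "relu") && !is.null(cache$mask))
        delta <- delta * cache$mask  # gate through the layer's own ReLU
      grads[[li]] <- list(dw = delta %*% t(cache$x), db = rowSums(delta))
      delta <- t(ly$w) %*% delta
    } else if (ly$type == "dropout") {
      if (!is.null(cache)) delta <- delta * cache$mask
    } else if (ly$type == "flatten") {
      delta <- array(delta, cache$xdim)
    } else if (ly$type == "relu_bn") {
      d <- cache$dims
      dm <- matrix(delta, nrow = d[1])
      m <- ncol(dm)
      dgamma <- rowSums(dm * cache$xhat)
      dbeta <- rowSums(dm)
      grads[[li]] <- list(dgamma = dgamma, dbeta = dbeta)
      dxhat <- dm * ly$gamma
      dxm <- cache$inv_sd *
        (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
      dxm <- dxm * cache$relu_mask
      delta <- array(dxm, d)
    } else if (ly$type == "maxpool3d") {
      delta <- cpp_maxpool3d_bwd(delta, cache$idx, cache$xdim)
    } else if (ly$type == "conv3d") {
      need_dx <- li > start_layer
      res <- cpp_conv3d_bwd(cache$x, cache$xdim, ly$w, delta, need_dx)
      grads[[li]] <- list(dw = res$dw, db = res$db)
      if (need_dx) delta <- res$dx
    }
  }
  grads
}

# Adam optimizer state + step over all unfrozen parameter layers
adam_init <- function(model) {
  st <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type %in% c("conv3d", "dense")) {
      st[[li]] <- list(mw = ly$w * 0, vw = ly$w * 0,
                       mb = ly$b * 0, vb = ly$b * 0)
    } else if (ly$type == "relu_bn") {
      st[[li]] <- list(mg = ly$gamma * 0, vg = ly$gamma * 0,
                       mb = ly$beta * 0, vb = ly$beta * 0)
    }
  }
  st
}

adam_step <- function(model, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    g <- grads[[li]]
    if (is.null(g) || isTRUE(ly$frozen)) next
    if (ly$type %in% c("conv3d", "dense")) {
      r <- upd(ly$w, g$dw, state[[li]]$mw, state[[li]]$vw)
      model$layers[[li]]$w <- r$p; state[[li]]$mw <- r$m; state[[li]]$vw <- r$v
      r <- upd(ly$b, g$db, state[[li]]$mb, state[[li]]$vb)
      model$layers[[li]]$b <- r$p; state[[li]]$mb <- r$m; state[[li]]$vb <- r$v
    } else if (ly$type == "relu_bn") {
      r <- upd(ly$gamma, g$dgamma, state[[li]]$mg, state[[li]]$vg)
      model$layers[[li]]$gamma <- r$p
      state[[li]]$mg <- r$m; state[[li]]$vg <- r$v
      r <- upd(ly$beta, g$dbeta, state[[li]]$mb, state[[li]]$vb)
      model$layers[[li]]$beta <- r$p
      state[[li]]$mb <- r$m; state[[li]]$vb <- r$v
    }
  }
  list(model = model, state = state)
}

#' Cross-entropy loss (nats)
#'
#' Mean negative log predicted probability of the true class.  A uniform
#' two-class prediction scores `log(2) ~ 0.6931`.
#'
#' @param probs classes x n matrix of predicted probabilities.
#' @param labels integer class indices (1-based) or factor.
#' @return Mean cross-entropy in nats.
#' @export
cross_entropy <- function(probs, labels) {
  if (is.factor(labels)) labels <- as.integer(labels)
  p <- pmax(probs[cbind(labels, seq_along(labels))], 1e-12)
  mean(-log(p))
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' @param max_epochs maximum epochs (default 100).
#' @param patience early-stop patience on validation accuracy (default 15
#'   epochs without improvement).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling shuffling, dropout and (if the model
#'   is fresh) initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 100L, patience = 15L, lr = 1e-4,
                         batch_size = 4L, seed = 1L) {
  stopifnot(patience < max_epochs)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

label_onehot <- function(labels, classes) {
  if (is.factor(labels)) labels <- as.integer(labels)
  oh <- matrix(0, classes, length(labels))
  oh[cbind(labels, seq_along(labels))] <- 1
  oh
}

#' Train the classifier with early stopping
#'
#' Runs at most `config$max_epochs` epochs of Adam on the training set and
#' stops early once the best validation accuracy has not improved for
#' `config$patience` consecutive epochs.  When the feature block is frozen,
#' feature activations are precomputed once (batch-norm in inference mode)
#' and only the classification block is propagated, which is exact and much
#' faster.  Fully seeded and single-threaded: identical seeds give identical
#' histories.
#'
#' @param model a `cnn_model` (optionally with frozen features).
#' @param volumes list of input volumes (arrays of the architecture's input
#'   shape).
#' @param labels factor/integer labels (positive class = inlay = level 1).
#' @param split list with `train` and `validation` index vectors.
#' @param config a [train_config()].
#' @return A `train_result`: `history` (per-epoch data.frame), `best_epoch`,
#'   `stopping_reason`, `stopped_epoch`, `metrics` (validation
#'   [classification_metrics()] at the best epoch), `model` (weights at the
#'   best epoch), `frozen_layers`, `trainable_parameters`.
#' @export
train_cnn <- function(model, volumes, labels, split, config = train_config()) {
  stopifnot(inherits(model, "cnn_model"))
  labels <- if (is.factor(labels)) labels else
    factor(labels, levels = c("inlay", "onlay"))
  if (length(unique(labels[split$train])) < 2)
    stop_crownforge("training set contains a single class",
                    "degenerate_data_error")
  classes <- model$arch$classes
  frozen <- feature_block_frozen(model)
  first_class_layer <- which(vapply(model$layers, function(l)
    identical(l$block, "classification"), logical(1)))[1]
  x_all <- as_batch(volumes)
  # with frozen features, activations are precomputed once
  # (inference-mode batch norm) and only the head is propagated
  x_feat <- if (frozen) cnn_forward_features(model, x_all) else NULL
  tr_idx <- split$train
  va_idx <- split$validation
  y_tr <- label_onehot(labels[tr_idx], classes)
  history <- list()
  best <- list(acc = -Inf, epoch = 0L, model = model, loss = Inf)
  state <- adam_init(model)
  stopping <- "max_epochs"
  stopped_epoch <- config$max_epochs
  step_t <- 0
  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(seq_along(tr_idx))
      for (bs in base::split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        idx <- tr_idx[bs]
        if (frozen) {
          xb <- x_feat[, idx, drop = FALSE]
          fwd <- cnn_forward(model, xb, training = TRUE, keep_cache = TRUE,
                             start_layer = first_class_layer + 1L)
        } else {
          xb <- x_all[, , , , idx, drop = FALSE]
          fwd <- cnn_forward(model, xb, training = TRUE, keep_cache = TRUE)
          model <- fwd$model  # batch-norm running stats
        }
        grads <- cnn_backward(model, fwd, y_tr[, bs, drop = FALSE],
                              start_layer = if (frozen)
                                first_class_layer + 1L else 1L)
        step_t <- step_t + 1
        res <- adam_step(model, grads, state, config$lr, step_t)
        model <- res$model
        state <- res$state
      }
      ev_tr <- cnn_evaluate_probs(model, x_all, x_feat, tr_idx,
                                  first_class_layer, frozen)
      ev_va <- cnn_evaluate_probs(model, x_all, x_feat, va_idx,
                                  first_class_layer, frozen)
      acc_tr <- mean(apply(ev_tr, 2, which.max) == as.integer(labels[tr_idx]))
      acc_va <- mean(apply(ev_va, 2, which.max) == as.integer(labels[va_idx]))
      loss_tr <- cross_entropy(ev_tr, labels[tr_idx])
      loss_va <- cross_entropy(ev_va, labels[va_idx])
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = loss_tr,
                                     train_acc = acc_tr, val_loss = loss_va,
                                     val_acc = acc_va)
      if (acc_va > best$acc + 1e-12) {
        best <- list(acc = acc_va, epoch = epoch, model = model,
                     loss = loss_va)
      }
      if (epoch - best$epoch >= config$patience) {
        stopping <- "patience"
        stopped_epoch <- epoch
        break
      }
      stopped_epoch <- epoch
    }
  })
  history <- do.call(rbind, history)
  va_probs <- cnn_evaluate_probs(best$model, x_all, x_feat, va_idx,
                                 first_class_layer, frozen)
  preds <- factor(levels(labels)[apply(va_probs, 2, which.max)],
                  levels = levels(labels))
  metrics <- classification_metrics(preds, labels[va_idx])
  metrics$loss <- cross_entropy(va_probs, labels[va_idx])
  structure(list(history = history, best_epoch = best$epoch,
                 best_val_acc = max(history$val_acc),
                 best_val_loss = min(history$val_loss),
                 stopping_reason = stopping, stopped_epoch = stopped_epoch,
                 metrics = metrics, model = best$model,
                 frozen_layers = vapply(Filter(function(l) isTRUE(l$frozen),
                                               best$model$layers),
                                        `[[`, character(1), "name"),
                 trainable_parameters = trainable_parameter_count(model)),
            class = "train_result")
}

# forward through the feature block only, returning the flattened features
cnn_forward_features <- function(model, x) {
  layers <- model$layers
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (identical(ly$block, "classification")) break
    if (ly$type == "conv3d") {
      x <- cpp_conv3d_fwd(x, dim(x), ly$w, ly$b)
    } else if (ly$type == "maxpool3d") {
      x <- cpp_maxpool3d_fwd(x, dim(x))$y
    } else if (ly$type == "relu_bn") {
      d <- dim(x)
      xm <- matrix(x, nrow = d[1])
      xm <- xm * (xm > 0)
      xhat <- (xm - ly$run_mean) / sqrt(ly$run_var + 1e-5)
      x <- array(xhat * ly$gamma + ly$beta, d)
    }
  }
  matrix(x, ncol = dim(x)[length(dim(x))])  # flattened: features x N
}

cnn_evaluate_probs <- function(model, x_all, x_feat, idx, first_class_layer,
                               frozen) {
  if (frozen) {
    cnn_forward(model, x_feat[, idx, drop = FALSE], training = FALSE,
                start_layer = first_class_layer + 1L)$out
  } else {
    cnn_forward(model, x_all[, , , , idx, drop = FALSE],
                training = FALSE)$out
  }
}

#' Predict the prosthesis type for one volume
#'
#' @param model a trained `cnn_model`.
#' @param volume a logical/numeric array matching the architecture's input
#'   shape.
#' @return List with `label` ("inlay"/"onlay"; argmax with ties broken
#'   toward the first class) and `probabilities` (named, summing to 1).
#' @export
predict_cnn <- function(model, volume) {
  d <- dim(volume)
  if (!identical(as.integer(d), model$arch$input_shape))
    stop_crownforge(sprintf("volume shape %s does not match input shape %s",
                            paste(d, collapse = "x"),
                            paste(model$arch$input_shape, collapse = "x")),
                    "shape_error")
  x <- array(as.numeric(volume), c(1L, d, 1L))
  p <- as.numeric(cnn_forward(model, x, training = FALSE)$out)
  names(p) <- c("inlay", "onlay")[seq_along(p)]
  list(label = names(p)[which.max(p)], probabilities = p)
}

#' Confusion-matrix metrics with inlay as the positive class
#'
#' @param predicted,actual factors with levels `inlay`, `onlay`.
#' @return List: `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `precision` (NA with `precision_defined = FALSE` when no positive
#'   predictions exist).
#' @export
classification_metrics <- function(predicted, actual) {
  if (length(actual) == 0)
    stop_crownforge("no samples to evaluate", "degenerate_data_error")
  pos <- "inlay"
  tp <- sum(predicted == pos & actual == pos)
  fp <- sum(predicted == pos & actual != pos)
  tn <- sum(predicted != pos & actual != pos)
  fn <- sum(predicted != pos & actual == pos)
  prec_def <- (tp + fp) > 0
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(actual),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (prec_def) tp / (tp + fp) else NA_real_,
       precision_defined = prec_def)
}

#' Evaluate a trained model on labelled volumes
#'
#' @param model a `cnn_model`.
#' @param volumes list of input volumes.
#' @param labels factor labels.
#' @return [classification_metrics()] plus cross-entropy `loss`.
#' @export
evaluate_cnn <- function(model, volumes, labels) {
  if (length(volumes) == 0)
    stop_crownforge("no samples to evaluate", "degenerate_data_error")
  labels <- if (is.factor(labels)) labels else
    factor(labels, levels = c("inlay", "onlay"))
  x <- as_batch(volumes)
  probs <- cnn_forward(model, x, training = FALSE)$out
  preds <- factor(levels(labels)[apply(probs, 2, which.max)],
                  levels = levels(labels))
  m <- classification_metrics(preds, labels)
  m$loss <- cross_entropy(probs, labels)
  m
}

# ---- proxy pretraining -----------------------------------------------------

#' Configuration of the synthetic volumetric proxy pretraining task
#'
#' The feature block is pretrained to separate random blob volumes that
#' contain an ellipsoidal inclusion from those that do not — a stand-in
#' volumetric classification task that teaches generic 3D shape features
#' without any external corpus.  Pretraining runs at 16^3 by default:
#' convolutional feature weights are resolution-independent, so they
#' transfer unchanged to the 32^3 dental volumes.
#'
#' @param n_volumes total proxy volumes (split 2:1).
#' @param shape cubic edge of proxy volumes.
#' @param max_epochs,patience,lr,batch_size training hyperparameters.
#' @param target_acc validation accuracy at which pretraining may stop early.
#' @return A `proxy_config` list.
#' @export
proxy_config <- function(n_volumes = 192L, shape = 16L, max_epochs = 12L,
                         patience = 6L, lr = 1e-3, batch_size = 8L,
                         target_acc = 0.85) {
  structure(list(n_volumes = as.integer(n_volumes), shape = as.integer(shape),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 batch_size = as.integer(batch_size),
                 target_acc = target_acc),
            class = "proxy_config")
}

#' Generate the synthetic proxy volumes
#'
#' Both classes are random soft blobs (thresholded smoothed noise around a
#' central ellipsoid); the positive class carries an additional internal
#' ellipsoidal inclusion (a void).  A small fraction of voxels is flipped as
#' noise.
#'
#' @param n number of volumes.
#' @param shape cubic edge.
#' @param seed integer seed.
#' @return List with `volumes` and `labels` (factor `inclusion`/`plain`).
#' @export
generate_proxy_volumes <- function(n, shape = 16L, seed = 1L) {
  with_seed(derive_seed(seed, "proxy"), {
    ax <- seq(-1, 1, length.out = shape)
    gx <- array(rep(ax, times = shape^2), rep(shape, 3))
    gy <- aperm(gx, c(2, 1, 3))
    gz <- aperm(gx, c(3, 2, 1))
    volumes <- vector("list", n)
    labels <- character(n)
    for (i in seq_len(n)) {
      has_inc <- i %% 2 == 0
      r <- runif(3, 0.55, 0.85)
      c0 <- runif(3, -0.12, 0.12)
      blob <- ((gx - c0[1]) / r[1])^2 + ((gy - c0[2]) / r[2])^2 +
        ((gz - c0[3]) / r[3])^2 < 1
      if (has_inc) {
        ri <- runif(3, 0.18, 0.32)
        ci <- c0 + runif(3, -0.18, 0.18)
        inc <- ((gx - ci[1]) / ri[1])^2 + ((gy - ci[2]) / ri[2])^2 +
          ((gz - ci[3]) / ri[3])^2 < 1
        blob <- blob & !inc
      }
      flip <- runif(length(blob)) < 0.02
      blob[flip] <- !blob[flip]
      volumes[[i]] <- blob
      labels[i] <- if (has_inc) "inclusion" else "plain"
    }
    list(volumes = volumes, labels = factor(labels,
                                            levels = c("inclusion", "plain")))
  })
}

#' Pretrain the feature block on the synthetic proxy task
#'
#' Trains the full network (feature block + a temporary head at the proxy
#' resolution) on the inclusion-vs-plain task, then copies the learned
#' convolution and batch-norm parameters into `model`.  Errors if the proxy
#' task fails to exceed chance level.  An externally prepared volumetric
#' corpus can be substituted by passing its volumes/labels.
#'
#' @param model the target `cnn_model` (weights at the dental input shape).
#' @param config a [proxy_config()].
#' @param seed integer seed.
#' @param volumes,labels optional external pretraining data overriding the
#'   synthetic task.
#' @return List: `model` (feature weights replaced, not yet frozen),
#'   `history`, `val_acc` (best proxy validation accuracy).
#' @export
pretrain_proxy <- function(model, config = proxy_config(), seed = 1L,
                           volumes = NULL, labels = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.null(volumes)) {
    data <- generate_proxy_volumes(config$n_volumes, config$shape, seed)
    volumes <- data$volumes
    labels <- data$labels
  }
  labels <- factor(labels)
  proxy_arch <- cnn_architecture(input_shape = rep(config$shape, 3),
                                 filters = model$arch$filters,
                                 dense_width = model$arch$dense_width,
                                 dropout = model$arch$dropout,
                                 classes = nlevels(labels))
  proxy_model <- build_cnn(proxy_arch, seed = derive_seed(seed, "proxy-init"))
  split <- stratified_split(labels, c(2, 1), seed = derive_seed(seed, "proxy-split"))
  cfg <- train_config(max_epochs = config$max_epochs,
                      patience = config$patience, lr = config$lr,
                      batch_size = config$batch_size,
                      seed = derive_seed(seed, "proxy-train"))
  result <- train_cnn_proxy(proxy_model, volumes, labels, split, cfg,
                            config$target_acc)
  if (result$best_val_acc <= 0.55)
    stop_crownforge(sprintf(
      "proxy pretraining failed to exceed chance (val acc %.2f)",
      result$best_val_acc), "convergence_error")
  # transfer feature-block parameters into the dental-resolution model
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (!identical(ly$block, "feature")) next
    src <- result$model$layers[[li]]
    if (ly$type == "conv3d") {
      model$layers[[li]]$w <- src$w
      model$layers[[li]]$b <- src$b
    } else if (ly$type == "relu_bn") {
      model$layers[[li]]$gamma <- src$gamma
      model$layers[[li]]$beta <- src$beta
      model$layers[[li]]$run_mean <- src$run_mean
      model$layers[[li]]$run_var <- src$run_var
    }
  }
  list(model = model, history = result$history,
       val_acc = result$best_val_acc)
}

# proxy training: like train_cnn but with an accuracy-target stop
train_cnn_proxy <- function(model, volumes, labels, split, config,
                            target_acc) {
  labels <- factor(labels)
  classes <- model$arch$classes
  x_all <- as_batch(volumes)
  tr_idx <- split$train
  va_idx <- split$validation
  y_tr <- label_onehot(labels[tr_idx], classes)
  history <- list()
  best <- list(acc = -Inf, epoch = 0L, model = model)
  state <- adam_init(model)
  step_t <- 0
  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(seq_along(tr_idx))
      for (bs in base::split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        idx <- tr_idx[bs]
        xb <- x_all[, , , , idx, drop = FALSE]
        fwd <- cnn_forward(model, xb, training = TRUE, keep_cache = TRUE)
        model <- fwd$model
        grads <- cnn_backward(model, fwd, y_tr[, bs, drop = FALSE])
        step_t <- step_t + 1
        res <- adam_step(model, grads, state, config$lr, step_t)
        model <- res$model
        state <- res$state
      }
      pv <- cnn_forward(model, x_all[, , , , va_idx, drop = FALSE],
                        training = FALSE)$out
      acc_va <- mean(apply(pv, 2, which.max) == as.integer(labels[va_idx]))
      loss_va <- cross_entropy(pv, labels[va_idx])
      history[[epoch]] <- data.frame(epoch = epoch, val_loss = loss_va,
                                     val_acc = acc_va)
      if (acc_va > best$acc + 1e-12)
        best <- list(acc = acc_va, epoch = epoch, model = model)
      if (acc_va >= target_acc || epoch - best$epoch >= config$patience)
        break
    }
  })
  list(model = best$model, history = do.call(rbind, history),
       best_val_acc = best$acc)
}
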
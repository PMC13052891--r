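# A compact convolutional-network engine. Activations are 3D arrays
# channels x width x batch; the layer primitives (im2col convolution,
# batch norm, ReLU, max pooling) are compiled (src/layers.cpp) with the
# matrix products in BLAS, while the dense head, softmax, SGD loop and
# bookkeeping stay in R. The input's 4 base rows act as the input
# channels of the first convolution (a 4 x K kernel that collapses the
# base axis).

#' Configure the sequence classifier
#'
#' Architecture and optimization settings for the 3-class convolutional
#' expression classifier. The default network is
#' conv(4x9, 32) -> BN -> ReLU,
#' conv(1x9, 64) -> BN -> ReLU -> maxpool(2),
#' conv(1x9, 128) -> BN -> ReLU -> maxpool(2),
#' dense(128) -> ReLU -> dropout(0.5), dense(3) -> softmax.
#'
#' @param conv_blocks List of blocks, each `list(kernel =, channels =,
#'   pool =)`; `pool = 1` means no pooling.
#' @param dense Integer vector of hidden dense widths.
#' @param dropout Dropout rate on hidden dense layers.
#' @param learning_rate,momentum SGD-with-momentum settings.
#' @param clip_norm Global gradient-norm clipping threshold (set `Inf`
#'   to disable); keeps mini-batch SGD stable early in training.
#' @param weight_decay L2 penalty on conv/dense weights.
#' @param lr_decay,lr_patience The learning rate is multiplied by
#'   `lr_decay` whenever `lr_patience` epochs pass without a new best
#'   validation accuracy (reduce-on-plateau schedule).
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience, in epochs without a new best
#'   validation accuracy.
#' @param seed Integer seed for weight initialization, shuffling and
#'   dropout.
#' @return A `network_config` list.
#' @export
network_config <- function(conv_blocks = list(
                             list(kernel = 9L, channels = 32L, pool = 1L),
                             list(kernel = 9L, channels = 64L, pool = 2L),
                             list(kernel = 9L, channels = 128L, pool = 2L)),
                           dense = 128L,
                           dropout = 0.5,
                           learning_rate = 0.005,
                           momentum = 0.9,
                           clip_norm = 5,
                           weight_decay = 1e-4,
                           lr_decay = 0.5,
                           lr_patience = 2L,
                           batch_size = 64L,
                           max_epochs = 24L,
                           patience = 8L,
                           seed = 1L) {
  cfg <- list(conv_blocks = conv_blocks, dense = as.integer(dense),
              dropout = dropout, learning_rate = learning_rate,
              momentum = momentum, clip_norm = clip_norm,
              weight_decay = weight_decay, lr_decay = lr_decay,
              lr_patience = as.integer(lr_patience),
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), seed = as.integer(seed),
              n_classes = 3L)
  for (b in cfg$conv_blocks) {
    if (b$kernel < 1 || b$channels < 1 || !b$pool %in% c(1L, 2L)) {
      abort("conv block kernel and channels must be >= 1 and pool 1 or 2.")
    }
  }
  if (any(cfg$dense < 1) || cfg$dropout < 0 || cfg$dropout >= 1 ||
      cfg$batch_size < 1 || cfg$max_epochs < 1 || cfg$patience < 0) {
    abort("invalid network configuration.")
  }
  structure(cfg, class = "network_config")
}

#' Build an untrained sequence classifier
#'
#' Initializes weights (He-scaled Gaussians) for the configured network
#' at a given input length. The same `(config, L)` always produces the
#' same initial weights via `config$seed`.
#'
#' @param config A [network_config()].
#' @param L Input sequence length in bp.
#' @return A `seq_classifier` with untrained parameters.
#' @export
build_network <- function(config, L) {
  stopifnot(inherits(config, "network_config"))
  L <- as.integer(L)
  layers <- list()
  conv_relu_idx <- integer(0)
  width <- L
  ch <- 4L
  withr::with_seed(config$seed, {
    for (b in config$conv_blocks) {
      if (b$kernel > width) {
        abort(sprintf("kernel %d exceeds current width %d.", b$kernel, width))
      }
      W <- array(stats::rnorm(b$channels * ch * b$kernel,
                              sd = sqrt(2 / (ch * b$kernel))),
                 dim = c(b$channels, ch, b$kernel))
      layers <- c(layers, list(list(type = "conv", W = W,
                                    b = numeric(b$channels))))
      layers <- c(layers, list(list(type = "bn",
                                    gamma = rep(1, b$channels),
                                    beta = numeric(b$channels),
                                    rmean = numeric(b$channels),
                                    rvar = rep(1, b$channels))))
      layers <- c(layers, list(list(type = "relu")))
      conv_relu_idx <- c(conv_relu_idx, length(layers))
      width <- width - b$kernel + 1L
      ch <- b$channels
      if (b$pool > 1) {
        layers <- c(layers, list(list(type = "pool", size = as.integer(b$pool))))
        width <- width %/% b$pool
      }
    }
    layers <- c(layers, list(list(type = "flatten")))
    in_dim <- ch * width
    for (d in config$dense) {
      layers <- c(layers, list(list(type = "dense",
                                    W = matrix(stats::rnorm(d * in_dim,
                                                            sd = sqrt(2 / in_dim)),
                                               d, in_dim),
                                    b = numeric(d))))
      layers <- c(layers, list(list(type = "relu")))
      if (config$dropout > 0) {
        layers <- c(layers, list(list(type = "dropout", rate = config$dropout)))
      }
      in_dim <- d
    }
    layers <- c(layers, list(list(type = "dense",
                                  W = matrix(stats::rnorm(config$n_classes * in_dim,
                                                          sd = sqrt(2 / in_dim)),
                                             config$n_classes, in_dim),
                                  b = numeric(config$n_classes))))
  })
  structure(
    list(config = config, L = L, layers = layers,
         conv_relu_idx = conv_relu_idx,
         class_levels = CLASS_LEVELS, trained = FALSE, history = NULL),
    class = "seq_classifier")
}

#' @export
print.seq_classifier <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) {
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
  }, 0))
  cat(sprintf("<seq_classifier> input 4 x %d, %d layers, %s parameters, %s\n",
              x$L, length(x$layers), format(n_par, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  if (!is.null(x$history)) {
    best <- x$history[which.max(x$history$val_accuracy), ]
    cat(sprintf("  best epoch %d: val accuracy %.1f%%\n",
                best$epoch, 100 * best$val_accuracy))
  }
  invisible(x)
}

as_mat <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1], prod(d[-1]))
  a
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# ---- full network pass ------------------------------------------------------

# forward through layers from_idx+1 .. length(layers); input `A` is the
# activation emitted by layer from_idx (from_idx 0 = network input).
# Returns logits plus per-layer caches when keep_cache.
nn_forward <- function(net, A, training = FALSE, keep_cache = FALSE,
                       from_idx = 0L) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  x <- A
  for (i in seq_along(net$layers)) {
    if (i <= from_idx) next
    l <- net$layers[[i]]
    res <- switch(l$type,
      conv = {
        if (keep_cache) caches[[i]] <- list(X = x)
        cpp_conv_fwd(x, l$W, l$b)
      },
      bn = {
        r <- cpp_bn_fwd(x, l$gamma, l$beta, l$rmean, l$rvar, training, BN_EPS)
        if (keep_cache) {
          caches[[i]] <- list(X = x, mu = r$mu, v = r$v, invstd = r$invstd)
        }
        r$Y
      },
      relu = {
        y <- cpp_relu_fwd(x)
        if (keep_cache) caches[[i]] <- list(A = y)
        y
      },
      pool = {
        r <- cpp_pool2_fwd(x)
        if (keep_cache) caches[[i]] <- list(left = r$left, in_dim = r$in_dim)
        r$Y
      },
      flatten = {
        d <- dim(x)
        if (keep_cache) caches[[i]] <- list(in_dim = d)
        dim(x) <- c(d[1] * d[2], d[3])
        x
      },
      dense = {
        if (keep_cache) caches[[i]] <- list(X = x)
        l$W %*% x + l$b
      },
      dropout = {
        if (training) {
          mask <- matrix(stats::runif(length(x)) >= l$rate,
                         nrow(x), ncol(x)) / (1 - l$rate)
          if (keep_cache) caches[[i]] <- list(mask = mask)
          x * mask
        } else {
          if (keep_cache) caches[[i]] <- list(mask = NULL)
          x
        }
      },
      abort(sprintf("unknown layer type '%s'", l$type)))
    x <- res
  }
  list(logits = x, caches = caches)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# backward from dLogits down to (and excluding) layer stop_idx; collects
# parameter gradients when collect_grads. Returns the gradient arriving
# at the output of layer stop_idx.
nn_backward <- function(net, caches, dLogits, training = FALSE,
                        collect_grads = FALSE, stop_idx = 0L) {
  grads <- if (collect_grads) vector("list", length(net$layers)) else NULL
  dx <- dLogits
  for (i in rev(seq_along(net$layers))) {
    if (i <= stop_idx) break
    l <- net$layers[[i]]
    dx <- switch(l$type,
      conv = {
        r <- cpp_conv_bwd(l$W, caches[[i]]$X, dx)
        if (collect_grads) grads[[i]] <- list(dW = r$dW, db = r$db)
        r$dX
      },
      bn = {
        if (training) {
          r <- cpp_bn_bwd_train(dx, caches[[i]]$X, caches[[i]]$mu,
                                caches[[i]]$invstd, l$gamma)
          if (collect_grads) grads[[i]] <- list(dgamma = r$dgamma, dbeta = r$dbeta)
          r$dX
        } else {
          cpp_bn_bwd_infer(dx, caches[[i]]$invstd, l$gamma)
        }
      },
      relu = cpp_relu_bwd(dx, caches[[i]]$A),
      pool = cpp_pool2_bwd(dx, caches[[i]]$left, caches[[i]]$in_dim),
      flatten = {
        dim(dx) <- caches[[i]]$in_dim
        dx
      },
      dense = {
        if (collect_grads) {
          grads[[i]] <- list(dW = dx %*% t(caches[[i]]$X), db = rowSums(dx))
        }
        t(l$W) %*% dx
      },
      dropout = if (training && !is.null(caches[[i]]$mask)) dx * caches[[i]]$mask else dx)
  }
  list(dX = dx, grads = grads)
}

#' Cross-entropy loss of a single prediction
#'
#' Negative log-likelihood `-sum(y * log(p))` of a one-hot truth `y`
#' under a predicted probability vector `p` (probabilities clamped at
#' 1e-12 before the log). Zero exactly when the prediction is perfect.
#'
#' @param p Probability 3-vector.
#' @param y One-hot 3-vector.
#' @return Non-negative scalar loss.
#' @examples
#' cross_entropy(c(1, 0, 0), c(1, 0, 0))      # 0
#' cross_entropy(rep(1, 3) / 3, c(0, 1, 0))   # log(3)
#' @export
cross_entropy <- function(p, y) {
  if (length(p) != length(y) || abs(sum(p) - 1) > 1e-6 || any(p < -1e-12)) {
    abort("`p` must be a probability vector matching `y`.")
  }
  if (!all(y %in% c(0, 1)) || sum(y) != 1) {
    abort("`y` must be one-hot.")
  }
  -sum(y * log(pmax(p, 1e-12)))
}

# ---- training ---------------------------------------------------------------

get_params <- function(net) lapply(net$layers, function(l) {
  l[intersect(names(l), c("W", "b", "gamma", "beta"))]
})

set_params <- function(net, params) {
  for (i in seq_along(params)) {
    for (nm in names(params[[i]])) net$layers[[i]][[nm]] <- params[[i]][[nm]]
  }
  net
}

#' Train the sequence classifier
#'
#' Mini-batch stochastic gradient descent with momentum on the mean
#' cross-entropy of the training partition; after each epoch the
#' validation partition is scored, and the weights from the epoch with
#' the best validation accuracy are retained (early stopping once
#' `patience` epochs pass without improvement). Batch-norm running
#' statistics are accumulated during training and used at inference.
#' Fully deterministic given `config$seed`.
#'
#' @param classifier Untrained (or trained) `seq_classifier`.
#' @param dataset A `labeled_dataset` with train and validation
#'   partitions; all three classes must appear in the training partition.
#' @return The trained classifier, with a per-epoch `history` tibble
#'   (train loss/accuracy, validation loss/accuracy).
#' @export
train_classifier <- function(classifier, dataset) {
  stopifnot(inherits(classifier, "seq_classifier"),
            inherits(dataset, "labeled_dataset"))
  cfg <- classifier$config
  tr <- which(dataset$partition == "train")
  va <- which(dataset$partition == "validation")
  if (length(tr) == 0 || length(va) == 0) {
    abort("dataset must contain train and validation partitions.")
  }
  if (any(tabulate(dataset$labels[tr], 3) == 0)) {
    abort("all three classes must be present in the training partition.")
  }
  net <- classifier
  vel <- lapply(get_params(net), function(p) lapply(p, function(x) x * 0))
  Y_tr <- dataset$labels[tr]
  best <- list(acc = -Inf, params = NULL, epoch = 0L)
  history <- vector("list", cfg$max_epochs)
  lr <- cfg$learning_rate

  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(tr))
      starts <- seq(1, length(ord), by = cfg$batch_size)
      ep_loss <- 0; ep_correct <- 0
      for (s in starts) {
        bi <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
        Xb <- dataset$X[, , tr[bi], drop = FALSE]
        yb <- Y_tr[bi]
        fwd <- nn_forward(net, Xb, training = TRUE, keep_cache = TRUE)
        P <- softmax_cols(fwd$logits)
        Yh <- matrix(0, 3, length(bi))
        Yh[cbind(yb, seq_along(bi))] <- 1
        loss <- -mean(log(pmax(P[cbind(yb, seq_along(bi))], 1e-12)))
        if (!is.finite(loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d.", epoch))
        }
        ep_loss <- ep_loss + loss * length(bi)
        ep_correct <- ep_correct + sum(max.col(t(P), ties.method = "first") == yb)
        bwd <- nn_backward(net, fwd$caches, (P - Yh) / length(bi),
                           training = TRUE, collect_grads = TRUE)
        scale <- grad_clip_scale(bwd$grads, cfg$clip_norm)
        # SGD with momentum + batch-norm running-stat update
        for (i in seq_along(net$layers)) {
          g <- bwd$grads[[i]]
          l <- net$layers[[i]]
          if (l$type == "conv" || l$type == "dense") {
            vel[[i]]$W <- cfg$momentum * vel[[i]]$W -
              lr * (scale * g$dW + cfg$weight_decay * l$W)
            vel[[i]]$b <- cfg$momentum * vel[[i]]$b - lr * scale * g$db
            net$layers[[i]]$W <- l$W + vel[[i]]$W
            net$layers[[i]]$b <- l$b + vel[[i]]$b
          } else if (l$type == "bn") {
            vel[[i]]$gamma <- cfg$momentum * vel[[i]]$gamma - lr * scale * g$dgamma
            vel[[i]]$beta <- cfg$momentum * vel[[i]]$beta - lr * scale * g$dbeta
            net$layers[[i]]$gamma <- l$gamma + vel[[i]]$gamma
            net$layers[[i]]$beta <- l$beta + vel[[i]]$beta
            cc <- fwd$caches[[i]]
            net$layers[[i]]$rmean <- BN_MOMENTUM * l$rmean + (1 - BN_MOMENTUM) * cc$mu
            net$layers[[i]]$rvar <- BN_MOMENTUM * l$rvar + (1 - BN_MOMENTUM) * cc$v
          }
        }
      }
      val <- score_partition(net, dataset, va)
      history[[epoch]] <- tibble(
        epoch = epoch,
        train_loss = ep_loss / length(tr),
        train_accuracy = ep_correct / length(tr),
        val_loss = val$loss, val_accuracy = val$accuracy)
      if (val$accuracy > best$acc) {
        best <- list(acc = val$accuracy, params = get_params(net), epoch = epoch)
      } else {
        if (epoch - best$epoch >= cfg$patience) break
        if ((epoch - best$epoch) %% cfg$lr_patience == 0) lr <- lr * cfg$lr_decay
      }
    }
  })
  net <- set_params(net, best$params)
  net$trained <- TRUE
  net$best_epoch <- best$epoch
  net$history <- dplyr::bind_rows(history)
  net
}

# rescale factor bringing the global gradient norm under the clip threshold
grad_clip_scale <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(1)
  sq <- sum(vapply(grads, function(g) {
    if (is.null(g)) 0 else sum(vapply(g, function(x) sum(x^2), 0))
  }, 0))
  gn <- sqrt(sq)
  if (gn > clip_norm) clip_norm / gn else 1
}

score_partition <- function(net, dataset, idx, chunk = 512L) {
  loss <- 0; correct <- 0
  for (s in seq(1, length(idx), by = chunk)) {
    ii <- idx[s:min(s + chunk - 1L, length(idx))]
    P <- softmax_cols(nn_forward(net, dataset$X[, , ii, drop = FALSE])$logits)
    y <- dataset$labels[ii]
    loss <- loss + sum(-log(pmax(P[cbind(y, seq_along(ii))], 1e-12)))
    correct <- correct + sum(max.col(t(P), ties.method = "first") == y)
  }
  list(loss = loss / length(idx), accuracy = correct / length(idx))
}

#' Predict expression bins for one-hot inputs
#'
#' Deterministic inference (dropout off, batch-norm running statistics).
#' Argmax ties break toward the lower class index (zero < low < high).
#'
#' @param classifier A `seq_classifier`.
#' @param X A 4 x L matrix, or a 4 x L x n array of inputs.
#' @param chunk Inference batch size.
#' @return Tibble with `p_zero`, `p_low`, `p_high`, integer `label` and
#'   `bin`.
#' @export
predict_bins <- function(classifier, X, chunk = 512L) {
  if (is.matrix(X)) dim(X) <- c(dim(X), 1L)
  if (dim(X)[1] != 4 || dim(X)[2] != classifier$L) {
    abort(sprintf("inputs must be 4 x %d.", classifier$L))
  }
  n <- dim(X)[3]
  P <- matrix(0, 3, n)
  for (s in seq(1, n, by = chunk)) {
    ii <- s:min(s + chunk - 1L, n)
    P[, ii] <- softmax_cols(nn_forward(classifier, X[, , ii, drop = FALSE])$logits)
  }
  label <- max.col(t(P), ties.method = "first")
  tibble(p_zero = P[1, ], p_low = P[2, ], p_high = P[3, ],
         label = label, bin = CLASS_LEVELS[label])
}

#' Evaluate a trained classifier on a dataset partition
#'
#' @param classifier Trained `seq_classifier`.
#' @param dataset A `labeled_dataset`.
#' @param partition Which partition to score (default `"test"`).
#' @return A `classifier_evaluation`: `accuracy` (percent), 3 x 3
#'   `confusion` (rows = measured, columns = predicted), per-class `f1`,
#'   and `macro_f1` (unweighted mean over classes present in truth or
#'   prediction).
#' @export
evaluate_classifier <- function(classifier, dataset, partition = "test") {
  idx <- which(dataset$partition == partition)
  if (length(idx) == 0) abort(sprintf("no items in partition '%s'.", partition))
  pred <- predict_bins(classifier, dataset$X[, , idx, drop = FALSE])
  truth <- dataset$labels[idx]
  ev <- evaluation_from_labels(truth, pred$label)
  ev$partition <- partition
  ev
}

evaluation_from_labels <- function(truth, predicted) {
  cm <- matrix(0L, 3, 3, dimnames = list(measured = CLASS_LEVELS,
                                         predicted = CLASS_LEVELS))
  for (k in seq_along(truth)) {
    cm[truth[k], predicted[k]] <- cm[truth[k], predicted[k]] + 1L
  }
  f1 <- f1_scores(cm)
  present <- !is.na(f1)
  if (any(!present)) {
    warn(sprintf("class(es) %s absent from truth and prediction; excluded from macro F1.",
                 paste(CLASS_LEVELS[!present], collapse = ", ")))
  }
  structure(
    list(accuracy = 100 * sum(diag(cm)) / sum(cm),
         confusion = cm,
         f1 = f1,
         macro_f1 = mean(f1[present]),
         n = sum(cm)),
    class = "classifier_evaluation")
}

# per-class F1 = TP / (TP + (FP + FN) / 2); NA when the class appears in
# neither truth nor prediction
f1_scores <- function(cm) {
  vapply(1:3, function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    if (tp + fp + fn == 0) return(NA_real_)
    tp / (tp + 0.5 * (fp + fn))
  }, 0) |> stats::setNames(CLASS_LEVELS)
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("<classifier_evaluation> accuracy %.1f%% on %d items (macro F1 %.3f)\n",
              x$accuracy, x$n, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' @rdname evaluate_classifier
#' @param x A `classifier_evaluation`.
#' @param ... Unused.
#' @method tidy classifier_evaluation
#' @export
tidy.classifier_evaluation <- function(x, ...) {
  tibble(bin = CLASS_LEVELS, f1 = unname(x$f1),
         n_measured = unname(rowSums(x$confusion)),
         n_predicted = unname(colSums(x$confusion)))
}

#' @rdname evaluate_classifier
#' @method glance classifier_evaluation
#' @export
glance.classifier_evaluation <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1, n = x$n)
}

#' @rdname train_classifier
#' @param x A `seq_classifier`.
#' @param ... Unused.
#' @method tidy seq_classifier
#' @export
tidy.seq_classifier <- function(x, ...) {
  if (is.null(x$history)) abort("classifier has no training history yet.")
  x$history
}

#' @rdname train_classifier
#' @method glance seq_classifier
#' @export
glance.seq_classifier <- function(x, ...) {
  h <- x$history
  tibble(trained = x$trained,
         epochs_run = if (is.null(h)) 0L else nrow(h),
         best_epoch = x$best_epoch %||% NA_integer_,
         best_val_accuracy = if (is.null(h)) NA_real_ else max(h$val_accuracy))
}
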
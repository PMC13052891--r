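# Two gradient-attribution estimators over the conv engine:
#  * layer = "input": the map is the ReLU'd gradient of the target (loss
#    by default) with respect to each pixel of the one-hot input -- an
#    in-silico-mutagenesis-style footprint at base-pair resolution.
#  * layer = <conv block index>: classic Grad-CAM; channel weights are
#    the mean gradient of the class score over the layer's activation
#    pixels, and the map is the ReLU'd channel-weighted activation sum,
#    upsampled to the input grid and broadcast across the 4 base rows.

resolve_gradcam_layer <- function(classifier, layer, allow_input = FALSE,
                                  default_input = FALSE) {
  n_blocks <- length(classifier$conv_relu_idx)
  if (is.null(layer)) layer <- if (default_input) "input" else n_blocks
  if (identical(layer, "input")) {
    if (!allow_input) abort("`layer` must be a conv block index here.")
    return("input")
  }
  layer <- as.integer(layer)
  if (is.na(layer) || layer < 1 || layer > n_blocks) {
    abort(sprintf("`layer` must be \"input\" or a conv block index in 1..%d.",
                  n_blocks))
  }
  layer
}

# gradient of the target w.r.t. the post-ReLU activations of conv block
# `layer`, together with those activations; X is 4 x L x B, classes is an
# integer vector of length B
gradcam_backprop <- function(classifier, X, classes, layer, target) {
  relu_idx <- if (identical(layer, "input")) 0L else
    classifier$conv_relu_idx[layer]
  fwd <- nn_forward(classifier, X, training = FALSE, keep_cache = TRUE)
  B <- dim(X)[3]
  onehot <- matrix(0, 3, B)
  onehot[cbind(classes, seq_len(B))] <- 1
  dLogits <- switch(target,
    score = onehot,
    loss = softmax_cols(fwd$logits) - onehot,
    abort("`target` must be \"score\" or \"loss\"."))
  bwd <- nn_backward(classifier, fwd$caches, dLogits, training = FALSE,
                     stop_idx = relu_idx)
  A <- if (relu_idx == 0L) X else fwd$caches[[relu_idx]]$A
  list(dA = bwd$dX, A = A, P = softmax_cols(fwd$logits))
}

#' Grad-CAM channel weights for one input
#'
#' The weight of channel k is the mean over that channel's activation
#' pixels of the gradient of the class-c output with respect to the
#' activation. By default the output is the pre-softmax class score;
#' `target = "loss"` differentiates the cross-entropy loss at class c
#' instead.
#'
#' @param classifier Trained `seq_classifier`.
#' @param x One 4 x L one-hot matrix.
#' @param class Target class index in 1..3.
#' @param layer Conv block index (default: the last one).
#' @param target `"score"` (pre-softmax logit) or `"loss"`.
#' @return Numeric vector of per-channel weights.
#' @export
gradcam_channel_weights <- function(classifier, x, class, layer = NULL,
                                    target = c("score", "loss")) {
  target <- match.arg(target)
  layer <- resolve_gradcam_layer(classifier, layer)
  dim(x) <- c(dim(x), 1L)
  gb <- gradcam_backprop(classifier, x, as.integer(class), layer, target)
  rowMeans(as_mat(gb$dA))
}

#' Grad-CAM saliency map for one input
#'
#' ReLU of the channel-weight-averaged activations of the chosen conv
#' layer, upsampled (nearest neighbour) along the sequence to the input
#' length and broadcast across the four base rows.
#'
#' @inheritParams gradcam_channel_weights
#' @param layer Conv block index (default: the last one) or `"input"`
#'   for the input-pixel gradient map.
#' @return Non-negative 4 x L matrix.
#' @export
gradcam_map <- function(classifier, x, class, layer = NULL,
                        target = c("score", "loss")) {
  target <- match.arg(target)
  layer <- resolve_gradcam_layer(classifier, layer, allow_input = TRUE)
  dim(x) <- c(dim(x), 1L)
  gb <- gradcam_backprop(classifier, x, as.integer(class), layer, target)
  if (identical(layer, "input")) {
    m <- pmax(gauge_fix(gb$dA, x)[, , 1], 0)
    rownames(m) <- ONEHOT_ROWS
    return(m)
  }
  alpha <- rowMeans(as_mat(gb$dA))
  u <- pmax(colSums(alpha * as_mat(gb$A)), 0)
  upsample_broadcast(u, classifier$L)
}

# One-hot inputs live on a simplex: adding any constant to a column of
# the input gradient changes nothing on valid sequences, so the gradient
# is only defined up to a per-position offset. Referencing each column
# to the variant's own (present) base fixes the gauge and turns the map
# into the first-order effect of every point mutation.
gauge_fix <- function(g, X) {
  ref <- colSums(g * X)  # gradient at the present base, per (position, variant)
  sweep(g, 2:3, ref, "-")
}

upsample_broadcast <- function(u, L) {
  idx <- floor((seq_len(L) - 1) * length(u) / L) + 1L
  matrix(rep(u[idx], each = 4), nrow = 4,
         dimnames = list(ONEHOT_ROWS, NULL))
}

#' Mean saliency map over a set of variants
#'
#' Computes one attribution map per variant — by default targeting the
#' class the model predicts for that variant — and averages them into a
#' single 4 x L map. The default estimator (`layer = "input"`) is the
#' ReLU'd gradient of the loss with respect to each input pixel, taken
#' relative to the variant's present base at each position (the gradient
#' on the one-hot simplex is only defined up to a per-position offset) —
#' an in-silico-mutagenesis-style footprint whose entry (b, j) is the
#' first-order loss increase from mutating position j to base b. A conv
#' block index instead selects classic Grad-CAM on that layer's
#' activations.
#'
#' @param classifier Trained `seq_classifier`.
#' @param X 4 x L x n array of one-hot inputs (e.g. the test partition).
#' @param classes Optional integer vector of target classes per variant;
#'   default is each variant's predicted class.
#' @param layer `"input"` (default) or a conv block index.
#' @param target `"score"` (pre-softmax logit) or `"loss"`; defaults to
#'   `"loss"` for the input layer and `"score"` for conv layers.
#' @param chunk Batch size for the backward passes.
#' @return Non-negative 4 x L matrix with attribute
#'   `n_variants_averaged`.
#' @export
average_saliency <- function(classifier, X, classes = NULL, layer = NULL,
                             target = NULL, chunk = 256L) {
  layer <- resolve_gradcam_layer(classifier, layer, allow_input = TRUE,
                                 default_input = TRUE)
  input_mode <- identical(layer, "input")
  if (is.null(target)) target <- if (input_mode) "loss" else "score"
  target <- match.arg(target, c("score", "loss"))
  if (is.matrix(X)) dim(X) <- c(dim(X), 1L)
  n <- dim(X)[3]
  if (n < 1) abort("need at least one variant.")
  if (!is.null(classes) && length(classes) != n) {
    abort("`classes` must have one entry per variant.")
  }
  acc <- NULL
  for (s in seq(1, n, by = chunk)) {
    ii <- s:min(s + chunk - 1L, n)
    Xb <- X[, , ii, drop = FALSE]
    cls <- if (is.null(classes)) {
      P <- softmax_cols(nn_forward(classifier, Xb)$logits)
      max.col(t(P), ties.method = "first")
    } else as.integer(classes[ii])
    gb <- gradcam_backprop(classifier, Xb, cls, layer, target)
    if (input_mode) {
      if (is.null(acc)) acc <- matrix(0, 4, classifier$L)
      acc <- acc + rowSums(pmax(gauge_fix(gb$dA, Xb), 0), dims = 2)
    } else {
      W <- dim(gb$A)[2]
      if (is.null(acc)) acc <- numeric(W)
      for (b in seq_along(ii)) {
        alpha <- rowMeans(matrix(gb$dA[, , b], dim(gb$dA)[1]))
        acc <- acc + pmax(colSums(alpha * matrix(gb$A[, , b], dim(gb$A)[1])), 0)
      }
    }
  }
  out <- if (input_mode) {
    m <- acc / n
    rownames(m) <- ONEHOT_ROWS
    m
  } else {
    upsample_broadcast(acc / n, classifier$L)
  }
  attr(out, "n_variants_averaged") <- n
  out
}

#' Collapse a saliency map to a per-position vector
#'
#' Takes the maximum over the four base rows at each position, yielding
#' the length-L saliency vector that downstream site calling consumes.
#'
#' @param map 4 x L saliency matrix.
#' @return Numeric vector of length L; the `n_variants_averaged`
#'   attribute of `map`, if any, is carried over.
#' @export
collapse_to_vector <- function(map) {
  stopifnot(is.matrix(map), nrow(map) == 4)
  out <- apply(map, 2, max)
  attr(out, "n_variants_averaged") <- attr(map, "n_variants_averaged")
  out
}
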
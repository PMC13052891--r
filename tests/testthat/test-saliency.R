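# a small no-pool network so activations can be perturbed for finite
# differences without max-pool ties
fd_network <- function(seed = 21L) {
  cfg <- network_config(conv_blocks = list(
    list(kernel = 3L, channels = 3L, pool = 1L),
    list(kernel = 3L, channels = 4L, pool = 1L)),
    dense = 5L, dropout = 0, seed = seed)
  build_network(cfg, 14)
}

test_that("channel weights vanish when the head carries no signal", {
  net <- fd_network()
  k <- length(net$layers)
  net$layers[[k]]$W[] <- 0
  net$layers[[k]]$b[] <- 0
  x <- one_hot_encode(generate_wildtype(14, seed = 1))
  for (c in 1:3) {
    expect_equal(gradcam_channel_weights(net, x, class = c), rep(0, 4))
  }
})

test_that("channel weights match a finite-difference oracle on the activations", {
  net <- fd_network()
  x <- one_hot_encode(generate_wildtype(14, seed = 2))
  relu_idx <- net$conv_relu_idx[2]
  xin <- x; dim(xin) <- c(4, 14, 1)
  fwd <- mprafoot:::nn_forward(net, xin, keep_cache = TRUE)
  A <- fwd$caches[[relu_idx]]$A
  h <- 1e-5
  for (c in 1:3) {
    alpha <- gradcam_channel_weights(net, x, class = c, layer = 2)
    fd <- vapply(seq_len(dim(A)[1]), function(k) {
      grads <- vapply(seq_len(dim(A)[2]), function(j) {
        Ap <- A; Ap[k, j, 1] <- A[k, j, 1] + h
        Am <- A; Am[k, j, 1] <- A[k, j, 1] - h
        yp <- mprafoot:::nn_forward(net, Ap, from_idx = relu_idx)$logits[c, 1]
        ym <- mprafoot:::nn_forward(net, Am, from_idx = relu_idx)$logits[c, 1]
        (yp - ym) / (2 * h)
      }, 0)
      mean(grads)
    }, 0)
    expect_lt(max(abs(alpha - fd)) / max(abs(fd), 1e-8), 1e-3)
  }
})

test_that("channel weights are linear in the class score", {
  net <- fd_network()
  x <- one_hot_encode(generate_wildtype(14, seed = 3))
  a1 <- gradcam_channel_weights(net, x, class = 2)
  net2 <- net
  k <- length(net2$layers)
  net2$layers[[k]]$W[2, ] <- 2 * net2$layers[[k]]$W[2, ]
  net2$layers[[k]]$b[2] <- 2 * net2$layers[[k]]$b[2]
  a2 <- gradcam_channel_weights(net2, x, class = 2)
  expect_equal(a2, 2 * a1, tolerance = 1e-10)
})

test_that("Grad-CAM maps are ReLU'd channel-weighted activations", {
  # single-channel final conv: U must equal ReLU(alpha * A) exactly
  cfg <- network_config(conv_blocks = list(list(kernel = 3L, channels = 1L,
                                                pool = 1L)),
                        dense = 4L, dropout = 0, seed = 9L)
  net <- build_network(cfg, 10)
  x <- one_hot_encode(generate_wildtype(10, seed = 4))
  alpha <- gradcam_channel_weights(net, x, class = 1)
  xin <- x; dim(xin) <- c(4, 10, 1)
  A <- mprafoot:::nn_forward(net, xin,
                             keep_cache = TRUE)$caches[[net$conv_relu_idx[1]]]$A
  u <- pmax(alpha * A[1, , 1], 0)
  map <- gradcam_map(net, x, class = 1)
  expect_true(all(map >= 0))
  expect_equal(dim(map), c(4, 10))
  idx <- floor((seq_len(10) - 1) * length(u) / 10) + 1
  expect_equal(unname(map[1, ]), u[idx])
  expect_equal(map[1, ], map[4, ])  # broadcast across base rows

  # an all-negative weighted sum saturates the ReLU to zero
  expect_equal(unname(mprafoot:::upsample_broadcast(pmax(c(-1, -2), 0), 4)),
               matrix(0, 4, 4))
})

test_that("input-layer maps are ReLU'd present-base-relative gradients", {
  net <- fd_network()
  wt <- generate_wildtype(14, seed = 5)
  x <- one_hot_encode(wt)
  m <- gradcam_map(net, x, class = 2, layer = "input", target = "loss")
  expect_equal(dim(m), c(4, 14))
  expect_true(all(m >= 0))
  # the present base has zero relative gradient by construction
  present <- match(strsplit(wt, "")[[1]], rownames(m))
  expect_equal(unname(m[cbind(present, 1:14)]), rep(0, 14))

  # finite-difference oracle for the full loss gradient, then the same
  # present-base referencing
  xin <- x; dim(xin) <- c(4, 14, 1)
  h <- 1e-5
  fd <- matrix(0, 4, 14)
  for (i in 1:4) for (j in 1:14) {
    xp <- xin; xp[i, j, 1] <- xin[i, j, 1] + h
    xm <- xin; xm[i, j, 1] <- xin[i, j, 1] - h
    yp <- mprafoot:::softmax_cols(mprafoot:::nn_forward(net, xp)$logits)
    ym <- mprafoot:::softmax_cols(mprafoot:::nn_forward(net, xm)$logits)
    fd[i, j] <- (-log(yp[2, 1]) + log(ym[2, 1])) / (2 * h)
  }
  rel <- pmax(sweep(fd, 2, fd[cbind(present, 1:14)]), 0)
  expect_equal(unname(m), rel, tolerance = 1e-3)
})

test_that("saliency averaging is a plain mean over per-variant maps", {
  net <- fd_network()
  seqs <- mutagenize_library(generate_wildtype(14, seed = 7), 3, 0.3, seed = 8)
  X <- mprafoot:::encode_sequences(seqs)

  one <- average_saliency(net, X[, , 1, drop = FALSE], layer = 2)
  pred1 <- predict_bins(net, X[, , 1])$label
  expect_equal(unname(one), unname(gradcam_map(net, X[, , 1], pred1, layer = 2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(one, "n_variants_averaged"), 1L)

  # duplicating the variant list leaves the mean unchanged
  m1 <- average_saliency(net, X, layer = 2)
  m2 <- average_saliency(net, X[, , c(1:3, 1:3)], layer = 2)
  expect_equal(unname(m1), unname(m2), tolerance = 1e-12, ignore_attr = TRUE)

  # mean of two explicit maps
  preds <- predict_bins(net, X)$label
  maps <- lapply(1:2, function(i) gradcam_map(net, X[, , i], preds[i], layer = 2))
  m12 <- average_saliency(net, X[, , 1:2], layer = 2)
  expect_equal(unname(m12), unname((maps[[1]] + maps[[2]]) / 2),
               tolerance = 1e-12, ignore_attr = TRUE)

  # input-layer route obeys the same averaging contract
  mi <- average_saliency(net, X[, , c(1, 1)], layer = "input")
  mi1 <- average_saliency(net, X[, , 1, drop = FALSE], layer = "input")
  expect_equal(unname(mi), unname(mi1), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(average_saliency(net, X, classes = 1L), "per variant")
  expect_error(average_saliency(net, X, layer = 7), "conv block")
})

test_that("collapse takes column maxima and is monotone", {
  m <- matrix(c(0.1, 0.9, 0.2, 0.0,
                0.5, 0.1, 0.1, 0.1,
                0.0, 0.0, 0.3, 0.2,
                0.4, 0.4, 0.4, 0.4,
                0.7, 0.2, 0.1, 0.6), nrow = 4)
  expect_equal(unname(collapse_to_vector(m)), c(0.9, 0.5, 0.3, 0.4, 0.7))

  m2 <- m; m2[2, 3] <- m[2, 3] + 1
  expect_true(all(collapse_to_vector(m2) >= collapse_to_vector(m)))

  cm <- matrix(2, 4, 6)
  expect_equal(unname(collapse_to_vector(cm)), rep(2, 6))
})
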
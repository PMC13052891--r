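test_that("forward pass emits normalized probabilities with the right shapes", {
  cfg <- tiny_network_config()
  net <- build_network(cfg, 40)
  X <- mprafoot:::encode_sequences(mutagenize_library(
    generate_wildtype(40, seed = 1), 7, 0.2, seed = 2))
  pred <- predict_bins(net, X)
  expect_equal(nrow(pred), 7)
  p <- as.matrix(pred[, c("p_zero", "p_low", "p_high")])
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, 7), tolerance = 1e-6)

  one <- predict_bins(net, X[, , 1])
  expect_equal(nrow(one), 1)
  expect_equal(as.numeric(one[1, 1:3]), unname(as.numeric(pred[1, 1:3])),
               tolerance = 1e-12)
})

test_that("weight initialization and inference are deterministic", {
  cfg <- tiny_network_config(seed = 99)
  n1 <- build_network(cfg, 30)
  n2 <- build_network(cfg, 30)
  expect_identical(n1$layers, n2$layers)
  n3 <- build_network(tiny_network_config(seed = 100), 30)
  expect_false(identical(n1$layers[[1]]$W, n3$layers[[1]]$W))

  X <- mprafoot:::encode_sequences(rep(generate_wildtype(30, seed = 3), 4))
  pred <- predict_bins(n1, X)
  expect_equal(pred$p_zero, rep(pred$p_zero[1], 4))  # duplicated inputs agree
})

test_that("kernels longer than the input are rejected", {
  cfg <- tiny_network_config()
  expect_error(build_network(cfg, 4), "exceeds")
})

test_that("cross-entropy matches hand-computed values and validates inputs", {
  expect_equal(cross_entropy(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(cross_entropy(rep(1, 3) / 3, c(0, 0, 1)), log(3))
  expect_equal(cross_entropy(c(0.5, 0.25, 0.25), c(0, 1, 0)), -log(0.25))
  expect_error(cross_entropy(c(0.5, 0.25, 0.25), c(0, 2, 0)), "one-hot")
  expect_error(cross_entropy(c(0.5, 0.25, 0.25), c(1, 1, 0)), "one-hot")
})

test_that("softmax cross-entropy gradient matches central finite differences", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      z <- rnorm(3, sd = 2)
      y <- sample(3, 1)
      p <- mprafoot:::softmax_cols(matrix(z, 3, 1))[, 1]
      analytic <- p - replace(numeric(3), y, 1)
      h <- 1e-6
      fd <- vapply(1:3, function(i) {
        zp <- z; zp[i] <- z[i] + h
        zm <- z; zm[i] <- z[i] - h
        lp <- -log(mprafoot:::softmax_cols(matrix(zp, 3, 1))[y, 1])
        lm <- -log(mprafoot:::softmax_cols(matrix(zm, 3, 1))[y, 1])
        (lp - lm) / (2 * h)
      }, 0)
      expect_lt(max(abs(fd - analytic)) / max(abs(fd), 1e-8), 1e-4)
    }
  })
})

test_that("every layer's parameter gradient matches finite differences", {
  cfg <- network_config(conv_blocks = list(
    list(kernel = 3L, channels = 3L, pool = 1L),
    list(kernel = 3L, channels = 4L, pool = 2L)),
    dense = 6L, dropout = 0, seed = 5L)
  net <- build_network(cfg, 12)
  X <- mprafoot:::encode_sequences(c("ACGTACGTACGT", "TTGACCGGTAAC",
                                     "GGGTTTAAACCC"))
  y <- c(1L, 2L, 3L)
  fwd <- mprafoot:::nn_forward(net, X, training = TRUE, keep_cache = TRUE)
  P <- mprafoot:::softmax_cols(fwd$logits)
  Yh <- matrix(0, 3, 3); Yh[cbind(y, 1:3)] <- 1
  bwd <- mprafoot:::nn_backward(net, fwd$caches, (P - Yh) / 3,
                                training = TRUE, collect_grads = TRUE)
  h <- 1e-6
  withr::with_seed(8, {
    for (i in seq_along(net$layers)) {
      g <- bwd$grads[[i]]
      if (is.null(g)) next
      for (nm in names(g)) {
        pname <- c(dW = "W", db = "b", dgamma = "gamma", dbeta = "beta")[[nm]]
        par <- net$layers[[i]][[pname]]
        for (j in sample(length(par), min(4, length(par)))) {
          np <- net
          np$layers[[i]][[pname]][j] <- par[j] + h
          lp <- batch_loss(np, X, y)
          np$layers[[i]][[pname]][j] <- par[j] - h
          lm <- batch_loss(np, X, y)
          fd <- (lp - lm) / (2 * h)
          an <- g[[nm]][j]
          # conv biases feed straight into batch norm, so their true
          # gradient is 0; compare on an absolute scale there
          expect_lt(abs(fd - an), 1e-4 * max(abs(fd), abs(an), 0.01))
        }
      }
    }
  })
})

test_that("training reduces loss, early-stops and is seed-reproducible", {
  tbl <- small_table(n_variants = 250, seed = 31)
  ds <- build_dataset(tbl, seed = 32)
  cfg <- tiny_network_config(seed = 33, max_epochs = 6L, patience = 6L)
  clf1 <- train_classifier(build_network(cfg, 60), ds)
  expect_true(clf1$trained)
  h <- tidy(clf1)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_equal(clf1$best_epoch, which.max(h$val_accuracy))

  clf2 <- train_classifier(build_network(cfg, 60), ds)
  expect_identical(clf1$layers, clf2$layers)  # same seed, same weights
})

test_that("training errors on missing partitions or classes", {
  tbl <- small_table(n_variants = 250, seed = 31)
  ds <- build_dataset(tbl, seed = 32)
  cfg <- tiny_network_config()
  ds2 <- ds
  ds2$partition[ds2$partition == "validation"] <- "test"
  expect_error(train_classifier(build_network(cfg, 60), ds2), "validation")
  ds3 <- ds
  ds3$labels[ds3$partition == "train" & ds3$labels == 1L] <- 2L
  expect_error(train_classifier(build_network(cfg, 60), ds3), "classes")
})

test_that("argmax ties break toward the lower class index", {
  # force exactly tied logits: zero final dense layer
  cfg <- tiny_network_config()
  net <- build_network(cfg, 20)
  k <- length(net$layers)
  net$layers[[k]]$W[] <- 0
  net$layers[[k]]$b[] <- 0
  X <- mprafoot:::encode_sequences(generate_wildtype(20, seed = 2))
  pred <- predict_bins(net, X)
  expect_equal(pred$p_zero, 1 / 3, tolerance = 1e-12)
  expect_equal(pred$label, 1L)
  expect_equal(pred$bin, "zero")
})

test_that("evaluation computes accuracy, confusion structure and F1 per definition", {
  truth <- c(rep(1L, 50), rep(2L, 60), rep(3L, 40))
  pred <- truth
  ev <- mprafoot:::evaluation_from_labels(truth, pred)
  expect_equal(ev$accuracy, 100)
  expect_equal(unname(ev$f1), rep(1, 3))

  # one class with TP = 50, FP = 10, FN = 30 -> F1 = 50/70
  truth2 <- c(rep(1L, 80), rep(2L, 40))
  pred2 <- c(rep(1L, 50), rep(2L, 30), rep(1L, 10), rep(2L, 30))
  suppressWarnings(ev2 <- mprafoot:::evaluation_from_labels(truth2, pred2))
  expect_equal(unname(ev2$f1[1]), 50 / 70)
  # row sums = truth counts, column sums = prediction counts
  expect_equal(unname(rowSums(ev2$confusion)), c(80L, 40L, 0L))
  expect_equal(unname(colSums(ev2$confusion)), unname(table(factor(pred2, 1:3))),
               ignore_attr = TRUE)
  expect_equal(sum(ev2$confusion), 120)
  # class 3 absent from truth and prediction -> excluded from macro F1
  expect_true(is.na(ev2$f1[3]))
  expect_equal(ev2$macro_f1, mean(ev2$f1[1:2]))
  expect_warning(mprafoot:::evaluation_from_labels(truth2, pred2), "excluded")
})

test_that("F1 is 1 exactly when FP = FN = 0 with TP > 0", {
  cm <- matrix(c(10L, 0L, 0L, 0L, 5L, 2L, 0L, 1L, 7L), 3, 3, byrow = TRUE)
  f1 <- mprafoot:::f1_scores(cm)
  expect_equal(unname(f1[1]), 1)
  expect_true(all(f1[2:3] < 1))
  expect_true(all(f1 >= 0 & f1 <= 1, na.rm = TRUE))
})
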
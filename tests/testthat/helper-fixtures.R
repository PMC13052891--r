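# Small shared fixtures, all generated in code.

# a tiny network config that trains in seconds on short sequences
tiny_network_config <- function(seed = 7L, max_epochs = 5L, patience = 2L,
                                ...) {
  network_config(
    conv_blocks = list(list(kernel = 5L, channels = 6L, pool = 1L),
                       list(kernel = 5L, channels = 8L, pool = 2L)),
    dense = 16L, dropout = 0, batch_size = 32L,
    max_epochs = max_epochs, patience = patience, seed = seed, ...)
}

# small synthetic library: 60-bp wild type, activator/promoter/repressor
small_truth <- function(seed = 11L) {
  wt <- generate_wildtype(60, seed = seed)
  ground_truth(wt, dplyr::bind_rows(
    site_spec(5, 20, +2.0, "activator"),
    site_spec(25, 45, +2.0, "promoter"),
    site_spec(48, 60, -2.0, "repressor")))
}

small_table <- function(n_variants = 400, seed = 11L, noise_sd = NULL) {
  truth <- small_truth(seed)
  if (!is.null(noise_sd)) truth$noise_sd <- noise_sd
  lib <- mutagenize_library(truth$wildtype, n_variants, 0.1, seed = seed + 1L)
  simulate_expression(lib, truth, seed = seed + 2L, barcodes_per_variant = 2L)
}

# exhaustive oracle for the expression-binning threshold search: a
# threshold only acts through which sorted values land below it, so
# trying the midpoint between every pair of consecutive distinct values
# covers every labeling any threshold (e.g. a 1e5-point grid) can
# produce; each split is scored with stats::t.test, independent of the
# package's internals
exhaustive_binning_oracle <- function(normalized, min_bin_size = 5) {
  y <- log(normalized[normalized > 0])
  u <- sort(unique(y))
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- list(p = Inf, threshold = NA)
  for (t in cuts) {
    g1 <- y[y <= t]; g2 <- y[y > t]
    if (length(g1) < min_bin_size || length(g2) < min_bin_size) next
    p <- tryCatch(stats::t.test(g1, g2)$p.value, error = function(e) Inf)
    if (is.finite(p) && p < best$p) best <- list(p = p, threshold = t)
  }
  best
}

# numeric loss of a classifier on a fixed batch, for finite-difference
# checks of the full backward pass (BN in training mode, dropout 0)
batch_loss <- function(net, X, y, training = TRUE) {
  fwd <- mprafoot:::nn_forward(net, X, training = training)
  P <- mprafoot:::softmax_cols(fwd$logits)
  -mean(log(pmax(P[cbind(y, seq_along(y))], 1e-12)))
}

# build a sensitivity_profile tibble with fully controlled columns, for
# exercising the calling contracts independently of any model
manual_profile <- function(E_smooth, S_smooth, direction) {
  out <- tibble::tibble(
    position = seq_along(E_smooth) - 1L,
    B = E_smooth, S_star = S_smooth, S_smooth = S_smooth,
    E = E_smooth, E_smooth = E_smooth, direction = as.integer(direction))
  class(out) <- c("sensitivity_profile", class(out))
  out
}

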
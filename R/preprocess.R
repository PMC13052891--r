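ONEHOT_ROWS <- c("A", "T", "C", "G")  # fixed row order of the encoding
CLASS_LEVELS <- c("zero", "low", "high")

#' Normalize mRNA counts by plasmid copy number
#'
#' Adds a `normalized` column, `ct_RNA / ct_DNA`, correcting expression
#' for construct copy number. Rows with `ct_DNA == 0` cannot be
#' normalized and are dropped with a warning reporting how many.
#'
#' @param tbl MPRA count tibble (`seq`, `barcode`, `ct_RNA`, `ct_DNA`).
#' @return The tibble with a `normalized` column (attributes preserved).
#' @export
normalize_counts <- function(tbl) {
  stopifnot(all(c("seq", "ct_RNA", "ct_DNA") %in% names(tbl)))
  drop <- tbl$ct_DNA == 0
  if (any(drop)) {
    warn(sprintf("dropping %d record(s) with DNA count 0 (cannot normalize).",
                 sum(drop)))
  }
  out <- tbl[!drop, , drop = FALSE]
  if (nrow(out) == 0) abort("no records left after dropping DNA-count-0 rows.")
  out$normalized <- out$ct_RNA / out$ct_DNA
  for (a in c("wildtype", "locus_name", "truth")) {
    attr(out, a) <- attr(tbl, a)
  }
  out
}

#' Bin normalized expression into zero / low / high classes
#'
#' Records with normalized count 0 go to the zero bin (label 1). For the
#' rest, the low/high boundary on log(normalized count) is found by a
#' randomized search: `max_iteration` candidate thresholds are drawn
#' uniformly between the smallest and largest finite log value, each
#' splits the data in two, and the threshold whose Welch two-sample
#' t-test between the groups has the smallest p-value is kept.
#' Candidates leaving either group with fewer than `min_bin_size`
#' members are skipped. Ties at the threshold go to the low bin.
#'
#' @param normalized Numeric vector of normalized expression (>= 0).
#' @param max_iteration Number of random candidate thresholds (default
#'   10000).
#' @param min_bin_size Minimum group size for a candidate (default 5).
#' @param seed Integer seed for the threshold draws.
#' @return An `expression_binning` object: `labels` (integer 1/2/3 per
#'   record), `threshold` (log scale), `best_p_value`, `log_expr`
#'   (natural log, `-Inf` for zeros).
#' @export
bin_expression <- function(normalized, max_iteration = 10000L,
                           min_bin_size = 5L, seed) {
  if (any(normalized < 0, na.rm = TRUE) || anyNA(normalized)) {
    abort("`normalized` must be non-negative and complete.")
  }
  log_expr <- ifelse(normalized > 0, log(normalized), -Inf)
  pos <- which(is.finite(log_expr))
  if (length(pos) < 2L * min_bin_size) {
    abort(sprintf("binning infeasible: %d positive records but 2 * min_bin_size = %d required.",
                  length(pos), 2L * min_bin_size))
  }
  y <- log_expr[pos]
  lo <- min(y); hi <- max(y)
  if (hi - lo <= 0) {
    abort("binning infeasible: all positive normalized counts identical (degenerate t-test).")
  }

  # a threshold only acts through the split index it induces on sorted y,
  # so p-values are precomputed once per split from cumulative sums
  ys <- sort(y)
  n <- length(ys)
  cs <- cumsum(ys); css <- cumsum(ys^2)
  split_p <- rep(NA_real_, n - 1)  # split i: group1 = ys[1:i]
  i <- seq_len(n - 1)
  ok <- i >= min_bin_size & (n - i) >= min_bin_size
  n1 <- i[ok]; n2 <- n - n1
  m1 <- cs[n1] / n1
  m2 <- (cs[n] - cs[n1]) / n2
  v1 <- pmax((css[n1] - n1 * m1^2) / (n1 - 1), 0)
  v2 <- pmax((css[n] - css[n1] - n2 * m2^2) / (n2 - 1), 0)
  se2 <- v1 / n1 + v2 / n2
  tt <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), NA_real_)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  split_p[i[ok]] <- 2 * stats::pt(-abs(tt), df)

  thresholds <- withr::with_seed(as.integer(seed),
                                 stats::runif(as.integer(max_iteration), lo, hi))
  idx <- findInterval(thresholds, ys)  # values <= threshold -> low bin
  pvals <- rep(Inf, length(thresholds))
  valid <- idx >= 1 & idx <= n - 1
  pv <- split_p[idx[valid]]
  pvals[valid] <- ifelse(is.na(pv), Inf, pv)
  if (all(!is.finite(pvals))) {
    abort("binning infeasible: no candidate threshold produced a valid t-test.")
  }
  best <- which.min(pvals)
  threshold <- thresholds[best]

  labels <- integer(length(normalized))
  labels[!is.finite(log_expr)] <- 1L
  labels[is.finite(log_expr) & log_expr <= threshold] <- 2L
  labels[is.finite(log_expr) & log_expr > threshold] <- 3L
  structure(
    list(labels = labels, threshold = threshold,
         best_p_value = pvals[best], log_expr = log_expr),
    class = "expression_binning")
}

#' @export
print.expression_binning <- function(x, ...) {
  ct <- tabulate(x$labels, 3)
  cat(sprintf("<expression_binning> threshold %.4f (log scale), best p = %.3g\n",
              x$threshold, x$best_p_value))
  cat(sprintf("  zero %d | low %d | high %d\n", ct[1], ct[2], ct[3]))
  invisible(x)
}

#' @rdname bin_expression
#' @param x An `expression_binning` object.
#' @param ... Unused.
#' @method tidy expression_binning
#' @export
tidy.expression_binning <- function(x, ...) {
  tibble(record = seq_along(x$labels),
         log_expr = x$log_expr,
         label = x$labels,
         bin = CLASS_LEVELS[x$labels])
}

#' @rdname bin_expression
#' @method glance expression_binning
#' @export
glance.expression_binning <- function(x, ...) {
  ct <- tabulate(x$labels, 3)
  tibble(threshold = x$threshold, best_p_value = x$best_p_value,
         n_zero = ct[1], n_low = ct[2], n_high = ct[3])
}

#' One-hot encode a nucleotide sequence
#'
#' Converts a sequence to a 4 x L binary matrix with row order A, T, C,
#' G: column j has a single 1 in the row of nucleotide j.
#'
#' @param sequence Nucleotide string over `{A,C,G,T}`.
#' @return 4 x L binary matrix with rownames `A`, `T`, `C`, `G`.
#' @examples
#' one_hot_encode("ATCG")  # the 4x4 identity matrix
#' @export
one_hot_encode <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  rows <- match(chars, ONEHOT_ROWS)
  if (anyNA(rows)) {
    abort(sprintf("invalid character '%s' at position %d.",
                  chars[which(is.na(rows))[1]], which(is.na(rows))[1]))
  }
  L <- length(rows)
  m <- matrix(0, nrow = 4, ncol = L, dimnames = list(ONEHOT_ROWS, NULL))
  m[cbind(rows, seq_len(L))] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' @param mat 4 x L one-hot matrix (row order A, T, C, G).
#' @return Nucleotide string.
#' @export
one_hot_decode <- function(mat) {
  stopifnot(nrow(mat) == 4)
  paste(ONEHOT_ROWS[apply(mat, 2, which.max)], collapse = "")
}

# all sequences at once -> 4 x L x n array
encode_sequences <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  rows <- match(unlist(strsplit(seqs, ""), use.names = FALSE), ONEHOT_ROWS)
  if (anyNA(rows)) abort("sequences contain characters outside {A,C,G,T}.")
  x <- array(0, dim = c(4, L, n))
  pos <- rep(seq_len(L), times = n)
  item <- rep(seq_len(n), each = L)
  x[cbind(rows, pos, item)] <- 1
  x
}

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  need <- n - sum(base)
  if (need > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(need)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Partition records into train / validation / test
#'
#' Stratified by label: within each label, items are allocated to
#' partitions by largest-remainder rounding, then reconciled so the
#' partition totals exactly match largest-remainder rounding of the
#' overall counts. Assignment is reproducible by seed.
#'
#' @param labels Integer or factor label per item (>= 10 items).
#' @param fractions Length-3 numeric summing to 1 (train, validation,
#'   test); default `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed.
#' @return Character vector in `{"train","validation","test"}`.
#' @export
split_dataset <- function(labels, fractions = c(0.70, 0.15, 0.15), seed) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be 3 values summing to 1.")
  }
  n <- length(labels)
  if (n < 10) abort("need at least 10 items to split.")
  parts <- c("train", "validation", "test")
  target <- largest_remainder(n, fractions)

  labs <- as.character(labels)
  groups <- split(seq_len(n), labs)
  alloc <- t(vapply(groups, function(g) largest_remainder(length(g), fractions),
                    integer(3)))
  # reconcile column sums with the global largest-remainder totals by
  # moving single items between partitions within a label
  repeat {
    delta <- colSums(alloc) - target
    if (all(delta == 0)) break
    p_over <- which.max(delta); p_under <- which.min(delta)
    cand <- which(alloc[, p_over] > 0)
    frac_deficit <- vapply(cand, function(l) {
      length(groups[[l]]) * fractions[p_under] - alloc[l, p_under]
    }, 0)
    l <- cand[which.max(frac_deficit)]
    alloc[l, p_over] <- alloc[l, p_over] - 1L
    alloc[l, p_under] <- alloc[l, p_under] + 1L
  }

  out <- character(n)
  withr::with_seed(as.integer(seed), {
    for (l in seq_along(groups)) {
      g <- sample(groups[[l]])
      out[g] <- rep(parts, times = alloc[l, ])
    }
  })
  out
}

#' Rebalance class counts by joint under/over-sampling
#'
#' Equalizes the three expression-bin counts at the median of the input
#' counts: classes above the target are sampled without replacement,
#' classes below it with replacement. Intended for the training
#' partition only, so validation and test stay honest.
#'
#' @param labels Integer labels in `{1,2,3}`; all three must be present.
#' @param seed Integer seed.
#' @return Integer vector of (resampled) item indices, shuffled.
#' @export
rebalance <- function(labels, seed) {
  counts <- tabulate(labels, 3)
  if (any(counts == 0)) {
    abort(paste("all three expression bins must be present to rebalance;",
                "inspect the binning threshold."))
  }
  target <- as.integer(stats::median(counts))
  withr::with_seed(as.integer(seed), {
    idx <- unlist(lapply(1:3, function(k) {
      members <- which(labels == k)
      if (length(members) >= target) sample(members, target)
      else c(members, sample(members, target - length(members), replace = TRUE))
    }), use.names = FALSE)
    sample(idx)
  })
}

#' Build a labeled, partitioned, one-hot dataset from an MPRA table
#'
#' Runs the full preprocessing chain: count normalization, expression
#' binning, 70/15/15 stratified split, training-partition rebalancing,
#' and one-hot encoding. Splitting happens before rebalancing, so no
#' resampled duplicate ever crosses partitions.
#'
#' @param tbl MPRA count tibble.
#' @param fractions Train/validation/test fractions.
#' @param max_iteration,min_bin_size Passed to [bin_expression()].
#' @param balance Rebalance the training partition (default TRUE).
#' @param seed Integer seed driving binning, split and rebalance.
#' @return A `labeled_dataset`: one-hot array `X` (4 x L x n), integer
#'   `labels`, `partition` tags, `provenance` (original record row of
#'   each item), the `expression_binning`, and locus metadata.
#' @export
build_dataset <- function(tbl, fractions = c(0.70, 0.15, 0.15),
                          max_iteration = 10000L, min_bin_size = 5L,
                          balance = TRUE, seed) {
  seed <- as.integer(seed)
  tbl <- normalize_counts(tbl)
  binning <- bin_expression(tbl$normalized, max_iteration = max_iteration,
                            min_bin_size = min_bin_size, seed = seed + 1L)
  labels <- binning$labels
  partition <- split_dataset(labels, fractions, seed = seed + 2L)

  if (balance) {
    tr <- which(partition == "train")
    oth <- which(partition != "train")
    rb <- rebalance(labels[tr], seed = seed + 3L)
    prov <- c(tr[rb], oth)
    part_out <- c(rep("train", length(rb)), partition[oth])
  } else {
    prov <- seq_len(nrow(tbl))
    part_out <- partition
  }

  structure(
    list(X = encode_sequences(tbl$seq[prov]),
         labels = labels[prov],
         partition = part_out,
         provenance = prov,
         binning = binning,
         wildtype = attr(tbl, "wildtype"),
         locus_name = attr(tbl, "locus_name") %||% "locus",
         class_levels = CLASS_LEVELS),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<labeled_dataset> %d items of 4 x %d\n", d[3], d[2]))
  print(table(partition = x$partition, bin = CLASS_LEVELS[x$labels]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
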
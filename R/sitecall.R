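# From saliency vector to binding-site calls: z-score normalization,
# exponentiated absolute sensitivity, 5-bp smoothing, peak detection at
# mean + 1 sd, expansion of each peak to its sign-contiguous region of
# the smoothed normalized saliency, a >= 10 bp length filter, and
# same-direction merging.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Z-score a saliency vector
#'
#' Raw saliency scales are not interpretable; only relative changes are.
#' The vector is therefore centred on its mean and divided by its
#' (population) standard deviation.
#'
#' @param B Numeric saliency vector, length >= 2.
#' @return Normalized vector `S*` with mean 0 and population sd 1.
#' @export
normalize_saliency <- function(B) {
  if (length(B) < 2) abort("`B` must have length >= 2.")
  s <- pop_sd(B)
  if (s == 0) {
    abort("degenerate saliency profile: constant vector carries no signal.")
  }
  (B - mean(B)) / s
}

#' Exponentiated mutation sensitivity
#'
#' `E_j = exp(|S*_j|)`: both strongly negative (activator-like) and
#' strongly positive (repressor-like) normalized saliency contribute,
#' so `E_j >= 1` everywhere.
#'
#' @param S_star Normalized saliency vector.
#' @return Sensitivity vector `E`.
#' @export
sensitivity <- function(S_star) exp(abs(S_star))

#' Centred moving average with truncated ends
#'
#' @param x Numeric vector.
#' @param window Odd window size (default 5 bp); at the vector ends the
#'   window truncates to the available positions.
#' @return Smoothed vector, same length.
#' @export
smooth_profile <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0) abort("`window` must be a positive odd integer.")
  h <- window %/% 2
  L <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Per-position mutation direction from the data
#'
#' For every position j, compares the mean log normalized expression of
#' variants mutated at j against variants wild-type at j (finite
#' expression only). Mutations that raise expression (`delta > 0`) mark
#' repressor-like positions (+1); mutations that lower it mark
#' activator-like positions (-1); positions with no mutated (or no
#' wild-type) finite-expression variants get 0.
#'
#' @param tbl Normalized MPRA tibble (see [normalize_counts()]).
#' @param binning The [bin_expression()] result for `tbl$normalized`.
#' @param wildtype Wild-type string; defaults to the table's `wildtype`
#'   attribute, else the per-column majority consensus of the library.
#' @return Integer vector of length L in `{-1, 0, +1}`, with attribute
#'   `delta` (the underlying expression shifts).
#' @export
assign_direction <- function(tbl, binning, wildtype = NULL) {
  stopifnot(inherits(binning, "expression_binning"))
  if (length(binning$labels) != nrow(tbl)) {
    abort("`binning` does not align with `tbl` (row counts differ).")
  }
  mism <- mismatch_matrix(tbl$seq, wildtype %||% attr(tbl, "wildtype"))
  le <- binning$log_expr
  fin <- is.finite(le)
  n_mut <- colSums(mism[fin, , drop = FALSE])
  n_wt <- sum(fin) - n_mut
  sum_mut <- colSums(mism[fin, , drop = FALSE] * le[fin])
  delta <- ifelse(n_mut > 0 & n_wt > 0,
                  sum_mut / n_mut - (sum(le[fin]) - sum_mut) / n_wt,
                  NA_real_)
  dir <- as.integer(ifelse(is.na(delta), 0, sign(delta)))
  structure(dir, delta = delta)
}

# n x L logical matrix of positions differing from the wild type; if no
# wild type is supplied, the per-column majority base stands in for it
mismatch_matrix <- function(seqs, wildtype = NULL) {
  L <- nchar(seqs[1])
  vmat <- matrix(match(unlist(strsplit(seqs, ""), use.names = FALSE), DNA_BASES),
                 ncol = L, byrow = TRUE)
  if (is.null(wildtype)) {
    wt <- apply(vmat, 2, function(col) which.max(tabulate(col, 4)))
  } else {
    if (nchar(wildtype) != L) abort("wildtype length does not match sequences.")
    wt <- match(strsplit(wildtype, "")[[1]], DNA_BASES)
  }
  sweep(vmat, 2, wt, "!=")
}

#' Build a per-position sensitivity profile
#'
#' Chains the saliency-to-sensitivity transformations: z-scoring of the
#' saliency vector, exponentiation of its absolute value, and 5-bp
#' smoothing, aligned with the per-position mutation direction.
#'
#' @param B Raw saliency vector (length L).
#' @param direction Integer direction vector from [assign_direction()]
#'   (or `sign(S*)` if the saliency-sign convention is preferred).
#' @param window Smoothing window (odd, default 5).
#' @return A `sensitivity_profile` tibble: `position` (0-based), `B`,
#'   `S_star`, `S_smooth` (smoothed `S_star`, whose sign drives the
#'   contiguity check in [call_sites()]), `E`, `E_smooth`, `direction`.
#' @export
sensitivity_profile <- function(B, direction, window = 5L) {
  B <- as.numeric(B)
  if (length(direction) != length(B)) {
    abort("`direction` must align with `B`.")
  }
  S_star <- normalize_saliency(B)
  E <- sensitivity(S_star)
  out <- tibble(position = seq_along(B) - 1L, B = B, S_star = S_star,
                S_smooth = smooth_profile(S_star, window),
                E = E, E_smooth = smooth_profile(E, window),
                direction = as.integer(direction))
  class(out) <- c("sensitivity_profile", class(out))
  out
}

#' Call binding sites from a sensitivity profile
#'
#' Positions whose smoothed sensitivity exceeds its mean plus one
#' (population) standard deviation are peaks. Each peak is expanded to
#' the maximal surrounding region over which the smoothed normalized
#' saliency (`S_smooth`) keeps one constant nonzero sign — the region
#' that is contiguous in a single regulatory sense — and a region is
#' called a site when it spans at least `min_site_length` bp. Calls are
#' labelled from the data-driven expression shift: `activator` when
#' mutations in the span lower expression (direction sum < 0),
#' `repressor` when they raise it; a span with no direction information
#' defaults to `activator`, the convention for sites not previously
#' mapped as promoters.
#'
#' @param profile A [sensitivity_profile()].
#' @param min_site_length Minimum site span in bp (default 10).
#' @return Tibble of calls (`start`, `end` 0-based half-open,
#'   `direction`, `mean_sensitivity`, `max_sensitivity`) with attributes
#'   `F` (the filtered sensitivity vector: `E_smooth` inside retained
#'   sites, 0 elsewhere) and `threshold`.
#' @export
call_sites <- function(profile, min_site_length = 10L) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  e <- profile$E_smooth
  thr <- mean(e) + pop_sd(e)
  peaks <- which(e > thr)
  sgn <- sign(profile$S_smooth)
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- findInterval(peaks, starts)
  keep <- sort(unique(seg[r$values[seg] != 0 & r$lengths[seg] >= min_site_length]))
  Fvec <- numeric(length(e))
  calls <- list()
  for (i in keep) {
    run <- starts[i]:ends[i]
    Fvec[run] <- e[run]
    dir_sum <- sum(profile$direction[run])
    calls[[length(calls) + 1]] <- tibble(
      start = run[1] - 1L, end = run[length(run)],
      direction = if (dir_sum > 0) "repressor" else "activator",
      mean_sensitivity = mean(e[run]), max_sensitivity = max(e[run]))
  }
  out <- if (length(calls)) dplyr::bind_rows(calls) else
    tibble(start = integer(), end = integer(), direction = character(),
           mean_sensitivity = double(), max_sensitivity = double())
  attr(out, "F") <- Fvec
  attr(out, "threshold") <- thr
  out
}

#' Merge nearby same-direction site calls
#'
#' Calls with the same direction separated by at most `max_gap` bp are
#' reported as a single spanning site (a conservative count of distinct
#' sites). Mean and max sensitivity are recomputed over the spanning
#' interval when `profile` is supplied, otherwise length-weighted over
#' the merged parts.
#'
#' @param calls Call tibble from [call_sites()].
#' @param max_gap Largest gap (bp) that still merges (default 6).
#' @param profile Optional [sensitivity_profile()] for recomputing
#'   sensitivities over merged spans.
#' @return Merged call tibble, sorted by `start`.
#' @export
merge_sites <- function(calls, max_gap = 6L, profile = NULL) {
  if (nrow(calls) < 2) return(calls)
  calls <- dplyr::arrange(calls, .data$start)
  merged <- list()
  cur <- calls[1, ]
  parts <- list(calls[1, ])
  flush <- function(cur, parts) {
    if (!is.null(profile)) {
      span <- (cur$start + 1L):cur$end
      cur$mean_sensitivity <- mean(profile$E_smooth[span])
      cur$max_sensitivity <- max(profile$E_smooth[span])
    } else {
      p <- dplyr::bind_rows(parts)
      w <- p$end - p$start
      cur$mean_sensitivity <- sum(p$mean_sensitivity * w) / sum(w)
      cur$max_sensitivity <- max(p$max_sensitivity)
    }
    cur
  }
  for (i in seq_len(nrow(calls))[-1]) {
    nxt <- calls[i, ]
    if (nxt$direction == cur$direction && nxt$start - cur$end <= max_gap) {
      cur$end <- max(cur$end, nxt$end)
      parts[[length(parts) + 1]] <- nxt
    } else {
      merged[[length(merged) + 1]] <- flush(cur, parts)
      cur <- nxt
      parts <- list(nxt)
    }
  }
  merged[[length(merged) + 1]] <- flush(cur, parts)
  dplyr::bind_rows(merged)
}

#' Benchmark site calls against known annotations
#'
#' A known site counts as captured if at least one called site overlaps
#' it by >= 1 bp; calls overlapping no known site are novel.
#'
#' @param calls Call tibble (`start`, `end`).
#' @param known Annotation tibble from [read_annotations()] (or any
#'   tibble with `start`, `end`, `label`).
#' @return A `benchmark_report`: counts (`n_called`, `n_known`,
#'   `n_captured`, `n_novel`, `n_missed`), `captured_fraction` (percent,
#'   `NA` when there are no known sites), and a per-known-site `overlap`
#'   tibble.
#' @export
benchmark_sites <- function(calls, known) {
  overlap_bp <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))
  n_known <- nrow(known)
  n_called <- nrow(calls)
  per_known <- if (n_known > 0) {
    purrr::map_dfr(seq_len(n_known), function(i) {
      ov <- if (n_called > 0) {
        overlap_bp(calls$start, calls$end, known$start[i], known$end[i])
      } else integer(0)
      tibble(start = known$start[i], end = known$end[i],
             label = known$label[i],
             captured = any(ov > 0),
             best_overlap = if (length(ov)) max(ov) else 0L)
    })
  } else {
    tibble(start = integer(), end = integer(), label = character(),
           captured = logical(), best_overlap = integer())
  }
  novel <- if (n_called > 0 && n_known > 0) {
    vapply(seq_len(n_called), function(i) {
      all(overlap_bp(known$start, known$end, calls$start[i], calls$end[i]) == 0)
    }, TRUE)
  } else rep(n_known == 0, n_called)
  n_captured <- sum(per_known$captured)
  structure(
    list(n_called = n_called, n_known = n_known, n_captured = n_captured,
         n_missed = n_known - n_captured, n_novel = sum(novel),
         captured_fraction = if (n_known > 0) 100 * n_captured / n_known else NA_real_,
         overlap = per_known, novel_calls = calls[novel, , drop = FALSE]),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d called / %d known: %d captured (%s%%), %d novel, %d missed\n",
              x$n_called, x$n_known, x$n_captured,
              ifelse(is.na(x$captured_fraction), "NA",
                     sprintf("%.1f", x$captured_fraction)),
              x$n_novel, x$n_missed))
  invisible(x)
}

#' @rdname benchmark_sites
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, ...) x$overlap

#' @rdname benchmark_sites
#' @method glance benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  tibble(n_called = x$n_called, n_known = x$n_known,
         n_captured = x$n_captured, n_novel = x$n_novel,
         n_missed = x$n_missed, captured_fraction = x$captured_fraction)
}

#' Per-position mutual-information footprint
#'
#' The classical MPRA footprinting statistic: at each position, the
#' mutual information (bits) between the mutated-vs-wild-type indicator
#' and the expression bin, estimated from empirical joint frequencies
#' and smoothed with the same 5-bp window as the sensitivity profile.
#'
#' @param tbl Normalized MPRA tibble.
#' @param binning [bin_expression()] result aligned to `tbl`.
#' @param wildtype Optional wild-type string (defaults as in
#'   [assign_direction()]).
#' @param window Smoothing window.
#' @return Tibble `position` (0-based), `mi`, `mi_smooth`.
#' @export
mi_footprint <- function(tbl, binning, wildtype = NULL, window = 5L) {
  stopifnot(inherits(binning, "expression_binning"))
  if (length(binning$labels) != nrow(tbl)) {
    abort("`binning` does not align with `tbl` (row counts differ).")
  }
  mism <- mismatch_matrix(tbl$seq, wildtype %||% attr(tbl, "wildtype"))
  n <- nrow(mism); L <- ncol(mism)
  labels <- binning$labels
  mi <- numeric(L)
  n_b <- tabulate(labels, 3)
  mut_b <- vapply(1:3, function(b) colSums(mism[labels == b, , drop = FALSE]),
                  numeric(L))  # L x 3 counts of mutated records per bin
  for (b in 1:3) {
    for (m in 0:1) {
      joint <- if (m == 1) mut_b[, b] else n_b[b] - mut_b[, b]
      p_joint <- joint / n
      p_m <- if (m == 1) colSums(t(mut_b)) / n else 1 - colSums(t(mut_b)) / n
      p_b <- n_b[b] / n
      term <- p_joint * log2(p_joint / (p_m * p_b))
      term[!is.finite(term) | p_joint == 0] <- 0
      mi <- mi + term
    }
  }
  tibble(position = seq_len(L) - 1L, mi = mi,
         mi_smooth = smooth_profile(mi, window))
}
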
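#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random wild-type regulatory sequence
#'
#' Draws a uniform-random nucleotide string, the stand-in for the fixed
#' 160-bp window upstream of a transcription start site that an MPRA
#' library mutagenizes.
#'
#' @param length Sequence length in bp (default 160).
#' @param seed Integer seed; the same `(length, seed)` pair always yields
#'   the same sequence.
#' @return A single character string over `A`, `C`, `G`, `T`.
#' @examples
#' generate_wildtype(20, seed = 1)
#' @export
generate_wildtype <- function(length = 160L, seed) {
  if (!is.numeric(length) || length(length) != 1 || length < 1) {
    abort("`length` must be a single integer >= 1.")
  }
  withr::with_seed(as.integer(seed), {
    paste(sample(DNA_BASES, as.integer(length), replace = TRUE),
          collapse = "")
  })
}

#' Mutagenize a wild-type sequence into a variant library
#'
#' Emulates random mutagenesis of a regulatory window: every position of
#' every variant is independently mutated with probability `rate`, and a
#' mutated base is replaced by one of its three alternatives chosen
#' uniformly. Variants are not deduplicated, matching how a mutagenized
#' plasmid library is actually drawn.
#'
#' @param wildtype Wild-type nucleotide string.
#' @param n_variants Number of variants to draw (>= 1).
#' @param rate Per-base mutation probability in `[0, 1]` (default 0.1, the
#'   usual Reg-Seq design rate).
#' @param seed Integer seed.
#' @return Character vector of `n_variants` sequences, each the length of
#'   `wildtype`.
#' @examples
#' wt <- generate_wildtype(30, seed = 1)
#' mutagenize_library(wt, 5, rate = 0.1, seed = 2)
#' @export
mutagenize_library <- function(wildtype, n_variants, rate = 0.1, seed) {
  check_sequence(wildtype, what = "wildtype")
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1) {
    abort("`rate` must be a single probability in [0, 1].")
  }
  if (!is.numeric(n_variants) || n_variants < 1) {
    abort("`n_variants` must be >= 1.")
  }
  n <- as.integer(n_variants)
  wt <- match(strsplit(wildtype, "")[[1]], DNA_BASES)
  L <- length(wt)
  withr::with_seed(as.integer(seed), {
    idx <- matrix(rep(wt, each = n), nrow = n)
    hit <- matrix(stats::runif(n * L) < rate, nrow = n)
    k <- sum(hit)
    if (k > 0) {
      # jump 1..3 steps around the 4-letter alphabet: uniform over the
      # three non-wild-type bases
      idx[hit] <- (idx[hit] - 1L + sample.int(3L, k, replace = TRUE)) %% 4L + 1L
    }
    seq_mat_to_strings(idx)
  })
}

seq_mat_to_strings <- function(idx) {
  chars <- matrix(DNA_BASES[idx], nrow = nrow(idx))
  apply(chars, 1, paste, collapse = "")
}

check_sequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1 || is.na(x) || nchar(x) < 1) {
    abort(sprintf("`%s` must be a single non-empty string.", what))
  }
  bad <- gsub("[ACGT]", "", x)
  if (nchar(bad) > 0) {
    abort(sprintf("`%s` contains characters outside {A,C,G,T}: %s",
                  what, substr(bad, 1, 10)))
  }
  invisible(x)
}

#' Specify a planted regulatory site
#'
#' One row of a ground-truth architecture: a half-open, 0-based interval
#' with a signed per-unit-damage effect on log expression. A positive
#' effect is activator-like (damage lowers expression); a negative effect
#' is repressor-like (damage raises expression).
#'
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param effect Signed shift in log expression per unit damage fraction.
#' @param label One of `"promoter"`, `"activator"`, `"repressor"`.
#' @return A one-row tibble with columns `start`, `end`, `effect`, `label`.
#' @export
site_spec <- function(start, end, effect, label) {
  label <- match.arg(label, c("promoter", "activator", "repressor"))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0 || start >= end) {
    abort("site must satisfy 0 <= start < end (0-based half-open).")
  }
  tibble(start = start, end = end, effect = as.numeric(effect), label = label)
}

#' Assemble a synthetic ground truth
#'
#' Bundles a wild-type sequence with a planted architecture and the
#' parameters of the generative expression model (see
#' [simulate_expression()]).
#'
#' @param wildtype Wild-type nucleotide string.
#' @param sites Tibble of sites as produced by [site_spec()] rows bound
#'   together (may be empty).
#' @param baseline_log_expr Log expression of the undamaged sequence.
#' @param noise_sd Standard deviation of multiplicative log-normal
#'   expression noise (>= 0).
#' @param promoter_kill_fraction Promoter damage fraction at and above
#'   which expression is set to exactly zero.
#' @param dna_copy_mean Mean of the plasmid copy-number distribution
#'   (copies are `1 + Poisson(dna_copy_mean)` so normalization never
#'   divides by zero).
#' @return A `ground_truth` object (a list).
#' @export
ground_truth <- function(wildtype, sites,
                         baseline_log_expr = log(50),
                         noise_sd = 0.3,
                         promoter_kill_fraction = 0.125,
                         dna_copy_mean = 20) {
  check_sequence(wildtype, "wildtype")
  sites <- as_tibble(sites)
  L <- nchar(wildtype)
  if (nrow(sites) > 0) {
    stopifnot(all(c("start", "end", "effect", "label") %in% names(sites)))
    if (any(sites$start < 0 | sites$start >= sites$end | sites$end > L)) {
      abort("every site must satisfy 0 <= start < end <= nchar(wildtype).")
    }
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (promoter_kill_fraction < 0 || promoter_kill_fraction > 1) {
    abort("`promoter_kill_fraction` must be in [0, 1].")
  }
  if (dna_copy_mean <= 0) abort("`dna_copy_mean` must be > 0.")
  structure(
    list(wildtype = wildtype, sites = sites,
         baseline_log_expr = baseline_log_expr, noise_sd = noise_sd,
         promoter_kill_fraction = promoter_kill_fraction,
         dna_copy_mean = dna_copy_mean),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d bp wild type, %d planted site(s)\n",
              nchar(x$wildtype), nrow(x$sites)))
  cat(sprintf("  baseline log expr %.3f, noise sd %.2f, kill fraction %.3f, mean DNA copy %.1f\n",
              x$baseline_log_expr, x$noise_sd, x$promoter_kill_fraction,
              x$dna_copy_mean))
  if (nrow(x$sites) > 0) print(x$sites)
  invisible(x)
}

#' Default synthetic regulatory architecture
#'
#' A 160-bp wild type carrying one promoter (60-95, effect +2), one
#' activator (20-35, effect +2) and one repressor (120-138, effect -2).
#' These are the library conditions used throughout the package's tests
#' and documentation.
#'
#' @param seed Integer seed for the wild-type draw.
#' @param length Sequence length (default 160).
#' @return A `ground_truth` object.
#' @export
default_ground_truth <- function(seed, length = 160L) {
  wt <- generate_wildtype(length, seed = seed)
  sites <- dplyr::bind_rows(
    site_spec(20, 35, +2.0, "activator"),
    site_spec(60, 95, +2.0, "promoter"),
    site_spec(120, 138, -2.0, "repressor"))
  ground_truth(wt, sites)
}

#' Simulate MPRA counts for a variant library
#'
#' The generative model is additive in log space in per-site damage: for
#' variant v with damage fraction d_k in site k,
#' `log mu_v = baseline - sum_k effect_k * d_k`. If promoter damage
#' reaches `promoter_kill_fraction`, `mu_v = 0` (promoter knockout, the
#' source of the zero-expression bin). Each barcode row then draws a DNA
#' copy number `c ~ 1 + Poisson(dna_copy_mean)` and an mRNA count
#' `Poisson(c * mu_v * exp(eps))` with `eps ~ Normal(0, noise_sd)`.
#'
#' @param variants Character vector of variant sequences, all the length
#'   of `truth$wildtype`.
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed.
#' @param barcodes_per_variant Barcode rows per variant (default 4).
#' @param locus_name Name recorded with the table.
#' @return A tibble with columns `seq`, `barcode`, `ct_RNA`, `ct_DNA` and
#'   attributes `wildtype`, `locus_name`, `truth` and `mu` (the noise-free
#'   expected expression per variant).
#' @export
simulate_expression <- function(variants, truth, seed,
                                barcodes_per_variant = 4L,
                                locus_name = "synthetic_locus") {
  stopifnot(inherits(truth, "ground_truth"))
  L <- nchar(truth$wildtype)
  if (any(nchar(variants) != L)) {
    abort("all variants must have the same length as the wild type.")
  }
  n <- length(variants)
  m <- as.integer(barcodes_per_variant)
  wt <- match(strsplit(truth$wildtype, "")[[1]], DNA_BASES)
  vmat <- t(vapply(strsplit(variants, ""),
                   function(s) match(s, DNA_BASES), integer(L)))
  if (anyNA(vmat)) abort("variants contain characters outside {A,C,G,T}.")
  mism <- sweep(vmat, 2, wt, "!=")

  log_mu <- rep(truth$baseline_log_expr, n)
  killed <- rep(FALSE, n)
  if (nrow(truth$sites) > 0) {
    for (k in seq_len(nrow(truth$sites))) {
      s <- truth$sites[k, ]
      dmg <- rowMeans(mism[, (s$start + 1):s$end, drop = FALSE])
      log_mu <- log_mu - s$effect * dmg
      if (s$label == "promoter") {
        killed <- killed | dmg >= truth$promoter_kill_fraction
      }
    }
  }
  mu <- exp(log_mu)
  mu[killed] <- 0

  withr::with_seed(as.integer(seed), {
    rows_mu <- rep(mu, each = m)
    dna <- 1L + stats::rpois(n * m, truth$dna_copy_mean)
    eps <- if (truth$noise_sd > 0) stats::rnorm(n * m, 0, truth$noise_sd) else 0
    rna <- stats::rpois(n * m, dna * rows_mu * exp(eps))
    barcode <- unique_barcodes(n * m)
    out <- tibble(
      seq = rep(variants, each = m),
      barcode = barcode,
      ct_RNA = as.integer(rna),
      ct_DNA = as.integer(dna))
    attr(out, "wildtype") <- truth$wildtype
    attr(out, "locus_name") <- locus_name
    attr(out, "truth") <- truth
    attr(out, "mu") <- mu  # expected expression per variant, before noise
    out
  })
}

# random 16-mers, re-drawn until unique (collisions are ~never at the
# library sizes used here)
unique_barcodes <- function(n, width = 16L) {
  draw <- function(k) {
    m <- matrix(sample(DNA_BASES, k * width, replace = TRUE), nrow = k)
    apply(m, 1, paste, collapse = "")
  }
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

#' One-call synthetic MPRA library under the default architecture
#'
#' Convenience wrapper: default ground truth, mutagenized library,
#' simulated counts. Defaults are the package's standard study
#' conditions: 2000 variants of a 160-bp wild type at 10% per-base
#' mutagenesis with 4 barcodes per variant.
#'
#' @param n_variants Number of variants (default 2000).
#' @param rate Per-base mutation rate (default 0.1).
#' @param seed Integer seed driving the whole simulation.
#' @param truth Optional [ground_truth()]; default [default_ground_truth()].
#' @param barcodes_per_variant Barcode rows per variant.
#' @param locus_name Locus label.
#' @return An MPRA count tibble (see [simulate_expression()]).
#' @export
simulate_mpra <- function(n_variants = 2000L, rate = 0.1, seed,
                          truth = NULL, barcodes_per_variant = 4L,
                          locus_name = "synthetic_locus") {
  seed <- as.integer(seed)
  if (is.null(truth)) truth <- default_ground_truth(seed = seed)
  variants <- mutagenize_library(truth$wildtype, n_variants, rate,
                                 seed = seed + 1L)
  simulate_expression(variants, truth, seed = seed + 2L,
                      barcodes_per_variant = barcodes_per_variant,
                      locus_name = locus_name)
}

#' Write a ground-truth architecture as BED
#'
#' Serializes planted sites as BED6 (0-based half-open): name = site
#' label, score = signed effect, strand = ".".
#'
#' @param truth A [ground_truth()] object.
#' @param path Output file path.
#' @param locus_name Value for the chrom column.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, locus_name = "synthetic_locus") {
  stopifnot(inherits(truth, "ground_truth"))
  df <- truth$sites
  lines <- character(0)
  if (nrow(df) > 0) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.", locus_name, df$start, df$end,
                     df$label, format(df$effect, trim = TRUE))
  }
  writeLines(lines, path)
  invisible(path)
}
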
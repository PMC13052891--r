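test_that("saliency normalization is an exact population z-score", {
  s <- normalize_saliency(c(1, 2, 3))
  expect_equal(s, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(s[2], 0)

  withr::with_seed(11, b <- rnorm(160, 5, 2))
  z <- normalize_saliency(b)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)

  expect_error(normalize_saliency(rep(2, 10)), "degenerate")
  expect_error(normalize_saliency(3), "length")
})

test_that("sensitivity exponentiates the absolute z-score", {
  expect_equal(sensitivity(0), 1)
  expect_equal(sensitivity(-2), sensitivity(2))
  expect_equal(sensitivity(2), exp(2))
  withr::with_seed(12, z <- rnorm(50))
  expect_true(all(sensitivity(z) >= 1))
})

test_that("smoothing is a truncated centred moving average", {
  expect_equal(smooth_profile(c(1, 1, 10, 1, 1), 5),
               c(4, 13 / 4, 14 / 5, 13 / 4, 4))
  x <- 1:10
  expect_equal(smooth_profile(x, 5)[3:8], vapply(3:8, function(j) mean(x[(j - 2):(j + 2)]), 0))
  expect_error(smooth_profile(1:5, 4), "odd")
})

test_that("length and sign-contiguity filters act as specified", {
  # an 8-bp and a 12-bp run above mean + 1 sd: only the 12-bp run calls
  E <- rep(1, 80)
  E[11:18] <- 8    # 8 bp
  E[41:52] <- 8    # 12 bp
  S <- rep(-0.5, 80); S[11:18] <- 1; S[41:52] <- 1
  prof <- manual_profile(E, S, rep(-1L, 80))
  calls <- call_sites(prof)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 40L)
  expect_equal(calls$end, 52L)
  expect_equal(calls$direction, "activator")
  expect_true(all(calls$end - calls$start >= 10))
  # F copies the smoothed sensitivity inside the retained run only
  Fv <- attr(calls, "F")
  expect_equal(Fv[41:52], E[41:52])
  expect_true(all(Fv[-(41:52)] == 0))

  # a 14-bp peak block whose smoothed saliency sign flips mid-block is
  # rejected: each same-sign region around the peaks spans only 7 bp
  E2 <- rep(1, 80); E2[31:44] <- 8
  S2 <- rep_len(c(rep(-0.3, 3), rep(0.3, 3)), 80)
  S2[28:30] <- -0.3; S2[31:37] <- 1; S2[38:44] <- -1; S2[45:47] <- 0.3
  expect_equal(nrow(call_sites(manual_profile(E2, S2, rep(-1L, 80)))), 0)

  # data-driven direction labels the call
  calls_rep <- call_sites(manual_profile(E, S, rep(1L, 80)))
  expect_equal(calls_rep$direction, "repressor")
  # no direction information defaults to activator
  calls_na <- call_sites(manual_profile(E, S, rep(0L, 80)))
  expect_equal(calls_na$direction, "activator")
})

test_that("a flat profile with a tiny short-period ripple produces no calls", {
  # sign regions of the ripple are 3 bp, far below the site length floor
  B <- 1 + 1e-3 * sin(2 * pi * seq_len(160) / 6)
  prof <- sensitivity_profile(B, rep(-1L, 160))
  expect_equal(nrow(call_sites(prof)), 0)
})

test_that("site calling is invariant to affine rescaling of the saliency vector", {
  withr::with_seed(14, {
    B <- exp(rnorm(160)) + rep(c(0, 4, 0), c(60, 20, 80))
  })
  dir <- rep(c(1L, -1L), 80)
  c1 <- call_sites(sensitivity_profile(B, dir))
  c2 <- call_sites(sensitivity_profile(3 * B + 7, dir))
  expect_equal(as.data.frame(c1), as.data.frame(c2))
})

test_that("nearby same-direction calls merge; gaps and directions separate", {
  calls <- tibble::tibble(
    start = c(10L, 26L), end = c(22L, 40L),
    direction = c("activator", "activator"),
    mean_sensitivity = c(2, 4), max_sensitivity = c(3, 5))
  m <- merge_sites(calls, max_gap = 6)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 10L)
  expect_equal(m$end, 40L)
  # length-weighted mean over the merged parts when no profile is given
  expect_equal(m$mean_sensitivity, (2 * 12 + 4 * 14) / 26)
  expect_equal(m$max_sensitivity, 5)

  far <- calls; far$start[2] <- 29L  # gap 7 > 6
  expect_equal(nrow(merge_sites(far, max_gap = 6)), 2)

  opp <- calls; opp$direction[2] <- "repressor"; opp$start[2] <- 24L
  expect_equal(nrow(merge_sites(opp, max_gap = 6)), 2)

  # with a profile, sensitivities are recomputed over the merged span
  E <- rep(1, 60); E[11:40] <- 2
  prof <- manual_profile(E, rep(1, 60), rep(-1L, 60))
  mp <- merge_sites(calls, max_gap = 6, profile = prof)
  expect_equal(mp$mean_sensitivity, mean(E[11:40]))
})

test_that("benchmarking counts captured, novel and missed sites by >=1 bp overlap", {
  known <- tibble::tibble(start = c(20L, 60L), end = c(35L, 95L),
                          label = c("activator", "promoter"),
                          source = "db")
  calls <- tibble::tibble(start = c(20L, 60L), end = c(35L, 95L),
                          direction = c("activator", "activator"),
                          mean_sensitivity = 1, max_sensitivity = 1)
  b <- benchmark_sites(calls, known)
  expect_equal(b$captured_fraction, 100)
  expect_equal(b$n_novel, 0)
  expect_equal(b$n_captured + b$n_missed, b$n_known)

  b0 <- benchmark_sites(calls[0, ], known)
  expect_equal(b0$n_missed, 2)
  expect_equal(b0$captured_fraction, 0)

  # one call overlapping one known site by 3 bp, plus one disjoint call
  partial <- tibble::tibble(start = c(32L, 120L), end = c(45L, 140L),
                            direction = "activator",
                            mean_sensitivity = 1, max_sensitivity = 1)
  bp <- benchmark_sites(partial, known)
  expect_equal(bp$captured_fraction, 50)
  expect_equal(bp$n_novel, 1)
  expect_equal(bp$n_missed, 1)
  expect_equal(tidy(bp)$best_overlap, c(3L, 0L))

  bn <- benchmark_sites(partial, known[0, ])
  expect_true(is.na(bn$captured_fraction))
  expect_equal(bn$n_novel, 2)
})

test_that("direction assignment recovers planted signs and flags unmutated positions", {
  wt <- generate_wildtype(40, seed = 15)
  truth <- ground_truth(wt, site_spec(5, 20, +2, "activator"),
                        noise_sd = 0, promoter_kill_fraction = 1)
  # mutate positions 2..40 only, never position 1
  chars <- strsplit(wt, "")[[1]]
  variants <- vapply(2:40, function(j) {
    v <- chars
    v[j] <- chartr("ACGT", "CATG", v[j])
    paste(v, collapse = "")
  }, "")
  variants <- rep(c(variants, wt), each = 6)
  tbl <- simulate_expression(variants, truth, seed = 16, barcodes_per_variant = 1L)
  tbl_n <- normalize_counts(tbl)
  binning <- bin_expression(tbl_n$normalized, seed = 17)
  dir <- assign_direction(tbl_n, binning)
  expect_equal(dir[1], 0L)                     # never mutated
  expect_true(all(dir[6:20] == -1L))           # activator: damage lowers expr
  delta <- attr(dir, "delta")
  expect_lt(mean(abs(delta[21:40])), mean(abs(delta[6:20])))
})

test_that("mutual information footprint matches the closed form on a deterministic fixture", {
  wt <- strrep("A", 12)
  mut <- wt
  substr(mut, 4, 4) <- "G"
  seqs <- rep(c(wt, mut), each = 15)
  tbl <- tibble::tibble(seq = seqs, barcode = paste0("b", seq_along(seqs)),
                        ct_RNA = 1L, ct_DNA = 1L)
  withr::with_seed(18, {
    tbl$normalized <- c(exp(rnorm(15, 0, 0.1)), exp(rnorm(15, log(100), 0.1)))
  })
  binning <- bin_expression(tbl$normalized, seed = 18)
  mi <- mi_footprint(tbl, binning, wildtype = wt)
  # bin is a deterministic function of mutated-at-position-4, both at 50%:
  # MI there equals the bin entropy, 1 bit; everywhere else 0
  expect_equal(mi$mi[4], 1)
  expect_equal(mi$mi[-4], rep(0, 11))
  expect_equal(mi$mi_smooth, smooth_profile(mi$mi, 5))
})

test_that("mutual information is near zero when mutations are independent of bins", {
  tbl <- small_table(n_variants = 400, seed = 19, noise_sd = 0.3)
  truth0 <- small_truth(19)
  truth0$sites$effect <- 0
  truth0$promoter_kill_fraction <- 1
  lib <- mutagenize_library(truth0$wildtype, 400, 0.1, seed = 20)
  tblnull <- simulate_expression(lib, truth0, seed = 21, barcodes_per_variant = 2L)
  tbl_n <- normalize_counts(tblnull)
  binning <- bin_expression(tbl_n$normalized, seed = 22)
  mi <- mi_footprint(tbl_n, binning)
  expect_lt(max(mi$mi), 0.05)
})
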
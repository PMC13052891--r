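#' Read an MPRA count table
#'
#' Reads the tab-separated dialect used throughout the package: one row
#' per (variant sequence, barcode) with mRNA and plasmid DNA read counts.
#' Validation is strict — malformed rows are rejected with row-numbered
#' diagnostics rather than silently coerced.
#'
#' @param path Path to a TSV file.
#' @param expected_length If given, every sequence must have this length;
#'   otherwise all sequences must share the length of the first row.
#' @param col_map Named character vector mapping the canonical column
#'   roles `seq`, `barcode`, `ct_RNA`, `ct_DNA` to the column names found
#'   in the file.
#' @return A tibble with columns `seq`, `barcode`, `ct_RNA`, `ct_DNA` and
#'   a `locus_name` attribute taken from the file name.
#' @examples
#' path <- system.file("extdata", "example_mpra.tsv", package = "mprafoot")
#' read_mpra_table(path)
#' @export
read_mpra_table <- function(path, expected_length = NULL,
                            col_map = c(seq = "seq", barcode = "barcode",
                                        ct_RNA = "ct_RNA", ct_DNA = "ct_DNA")) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(unname(col_map), names(df))
  if (length(missing) > 0) {
    abort(sprintf("MPRA table %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  out <- tibble(
    seq = toupper(df[[col_map[["seq"]]]]),
    barcode = df[[col_map[["barcode"]]]],
    ct_RNA = suppressWarnings(as.integer(df[[col_map[["ct_RNA"]]]])),
    ct_DNA = suppressWarnings(as.integer(df[[col_map[["ct_DNA"]]]])))
  validate_mpra_table(out, expected_length = expected_length, path = path)
  attr(out, "locus_name") <- sub("\\.[^.]*$", "", basename(path))
  out
}

validate_mpra_table <- function(tbl, expected_length = NULL, path = "table") {
  if (nrow(tbl) < 1) abort(sprintf("%s: MPRA table has no rows.", path))
  bad_seq <- which(is.na(tbl$seq) | grepl("[^ACGT]", tbl$seq))
  if (length(bad_seq) > 0) {
    abort(sprintf("%s: sequence outside {A,C,G,T} at row(s) %s",
                  path, row_list(bad_seq)))
  }
  L <- if (is.null(expected_length)) nchar(tbl$seq[1]) else as.integer(expected_length)
  bad_len <- which(nchar(tbl$seq) != L)
  if (length(bad_len) > 0) {
    abort(sprintf("%s: sequence length != %d at row(s) %s",
                  path, L, row_list(bad_len)))
  }
  bad_ct <- which(is.na(tbl$ct_RNA) | is.na(tbl$ct_DNA) |
                    tbl$ct_RNA < 0 | tbl$ct_DNA < 0)
  if (length(bad_ct) > 0) {
    abort(sprintf("%s: missing or negative count at row(s) %s",
                  path, row_list(bad_ct)))
  }
  dup <- which(duplicated(tbl$barcode))
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicated barcode at row(s) %s", path, row_list(dup)))
  }
  invisible(tbl)
}

row_list <- function(idx, max = 5) {
  shown <- paste(utils::head(idx, max), collapse = ", ")
  if (length(idx) > max) shown <- paste0(shown, sprintf(" (+%d more)", length(idx) - max))
  shown
}

#' Write an MPRA count table
#'
#' @param tbl Tibble with columns `seq`, `barcode`, `ct_RNA`, `ct_DNA`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mpra_table <- function(tbl, path) {
  readr::write_tsv(tbl[, c("seq", "barcode", "ct_RNA", "ct_DNA")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read interval annotations (BED-like)
#'
#' Reads known binding-site annotations as 0-based half-open intervals.
#' The BED name field is parsed into a site label; anything other than
#' promoter/activator/repressor becomes `"unknown"`.
#'
#' @param path BED(-like) file: at least chrom, start, end; optionally
#'   name, score, strand.
#' @param source Source tag stored with each interval (defaults to the
#'   file name).
#' @return Tibble with columns `start`, `end`, `label`, `source`.
#' @examples
#' bed <- system.file("extdata", "example_sites.bed", package = "mprafoot")
#' read_annotations(bed)
#' @export
read_annotations <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(start = integer(), end = integer(),
                  label = character(), source = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_f <- lengths(fields)
  if (any(n_f < 3)) {
    abort(sprintf("%s: fewer than 3 BED fields at line(s) %s",
                  path, row_list(which(n_f < 3))))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid interval (need 0 <= start < end) at line(s) %s",
                  path, row_list(bad)))
  }
  name <- vapply(seq_along(fields), function(i) {
    if (n_f[i] >= 4) fields[[i]][4] else "unknown"
  }, "")
  label <- ifelse(name %in% c("promoter", "activator", "repressor"),
                  name, "unknown")
  tibble(start = start, end = end, label = label, source = source)
}

#' Write binding-site calls as BED6
#'
#' Serializes site calls with chrom = `locus_name`, 0-based half-open
#' coordinates, name = direction label, score = mean sensitivity scaled
#' linearly to `[0, 1000]` across the calls (and clamped), strand `"."`.
#'
#' @param calls Tibble of calls (see [call_sites()]), columns `start`,
#'   `end`, `direction`, `mean_sensitivity`.
#' @param locus_name Chrom field value.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(calls, locus_name, path) {
  if (nrow(calls) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ms <- calls$mean_sensitivity
  hi <- max(ms)
  score <- if (hi > 0) round(1000 * ms / hi) else rep(0, length(ms))
  score <- pmin(pmax(score, 0), 1000)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", locus_name,
                     calls$start, calls$end, calls$direction, score), path)
  invisible(path)
}

#' Read a wild-type sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return Uppercased nucleotide string.
#' @export
read_wildtype_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package.")
  }
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1) abort(sprintf("%s: no FASTA records.", path))
  wt <- toupper(as.character(ss[[1]]))
  check_sequence(wt, "wildtype")
  wt
}

#' Write a wild-type sequence to FASTA
#'
#' @param wildtype Nucleotide string.
#' @param path Output path.
#' @param name Record name.
#' @return `path`, invisibly.
#' @export
write_wildtype_fasta <- function(wildtype, path, name = "wildtype") {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("writing FASTA requires the Biostrings package.")
  }
  check_sequence(wildtype, "wildtype")
  ss <- Biostrings::DNAStringSet(stats::setNames(wildtype, name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
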
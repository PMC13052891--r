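#' Assemble and validate a pipeline run configuration
#'
#' Either build the configuration programmatically or load it from a
#' YAML file with the same keys. Validation reports every problem at
#' once rather than stopping at the first.
#'
#' @param table Path to an MPRA count TSV (omit when `simulate` is
#'   given).
#' @param out Output directory for run artifacts.
#' @param seed Global integer seed; every stage derives its own seed
#'   from it deterministically.
#' @param simulate Optional list for the synthetic stage:
#'   `n_variants`, `rate`, `barcodes_per_variant`.
#' @param wildtype Optional wild-type FASTA path.
#' @param annotations Optional BED of known sites for benchmarking.
#' @param preprocess Optional list: `fractions`, `max_iteration`,
#'   `min_bin_size`.
#' @param network Optional list of [network_config()] overrides.
#' @param saliency Optional list: `layer`, `target`.
#' @param sitecall Optional list: `min_site_length`, `max_gap`, `window`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(table = NULL, out, seed, simulate = NULL,
                       wildtype = NULL, annotations = NULL,
                       preprocess = list(), network = list(),
                       saliency = list(), sitecall = list()) {
  cfg <- list(table = table, out = out, seed = seed, simulate = simulate,
              wildtype = wildtype, annotations = annotations,
              preprocess = preprocess, network = network,
              saliency = saliency, sitecall = sitecall)
  problems <- character(0)
  if (is.null(cfg$out) || !is.character(cfg$out)) {
    problems <- c(problems, "`out`: output directory is required.")
  }
  if (is.null(cfg$seed) || !is.numeric(cfg$seed)) {
    problems <- c(problems, "`seed`: an integer seed is required.")
  }
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$table)) {
      problems <- c(problems, "`table`: a count-table path is required unless `simulate` is given.")
    } else if (!file.exists(cfg$table)) {
      problems <- c(problems, sprintf("`table`: file not found: %s", cfg$table))
    }
  }
  for (key in c("wildtype", "annotations")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      problems <- c(problems, sprintf("`%s`: file not found: %s", key, cfg[[key]]))
    }
  }
  fr <- cfg$preprocess$fractions
  if (!is.null(fr) && (length(fr) != 3 || abs(sum(fr) - 1) > 1e-9)) {
    problems <- c(problems, "`preprocess$fractions`: must be 3 values summing to 1.")
  }
  if (length(problems) > 0) {
    abort(paste(c("invalid run configuration:", problems), collapse = "\n  "))
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the configuration keys above.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes (optional) simulation, preprocessing, training, evaluation,
#' saliency mapping and site calling, writing all artifacts into the
#' output directory: the count table and ground truth (when simulated),
#' `metrics.json`, `confusion.tsv`, `history.tsv`, `sensitivity.tsv`
#' (position, B, S*, E, smoothed E, direction, filtered F and the MI
#' footprint), `sites.bed` (merged calls), `benchmark.json` (when known
#' sites are available) and `manifest.json`. Identical configurations
#' and seeds produce identical artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the trained classifier, evaluation,
#'   profile, calls and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  paths <- list()
  truth <- NULL

  tbl <- run_stage("simulate", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      truth <- default_ground_truth(seed = seed)
      t0 <- simulate_mpra(n_variants = sim$n_variants %||% 2000L,
                          rate = sim$rate %||% 0.1, seed = seed,
                          truth = truth,
                          barcodes_per_variant = sim$barcodes_per_variant %||% 4L)
      paths$table <- file.path(out, "mpra_table.tsv")
      write_mpra_table(t0, paths$table)
      paths$ground_truth <- file.path(out, "ground_truth.bed")
      write_ground_truth(truth, paths$ground_truth)
      t0
    } else {
      read_mpra_table(config$table)
    }
  })

  dataset <- run_stage("preprocess", {
    pp <- config$preprocess
    build_dataset(tbl,
                  fractions = pp$fractions %||% c(0.70, 0.15, 0.15),
                  max_iteration = pp$max_iteration %||% 10000L,
                  min_bin_size = pp$min_bin_size %||% 5L,
                  seed = seed + 10L)
  })

  clf <- run_stage("train", {
    net_cfg <- do.call(network_config,
                       c(config$network, list(seed = seed + 20L)))
    train_classifier(build_network(net_cfg, dim(dataset$X)[2]), dataset)
  })

  ev <- run_stage("evaluate", {
    ev <- evaluate_classifier(clf, dataset, "test")
    paths$metrics <- file.path(out, "metrics.json")
    jsonlite::write_json(list(accuracy = ev$accuracy, f1 = as.list(ev$f1),
                              macro_f1 = ev$macro_f1, n_test = ev$n),
                         paths$metrics, auto_unbox = TRUE, digits = NA)
    paths$confusion <- file.path(out, "confusion.tsv")
    readr::write_tsv(as_tibble(as.data.frame.table(ev$confusion)),
                     paths$confusion, progress = FALSE)
    paths$history <- file.path(out, "history.tsv")
    readr::write_tsv(clf$history, paths$history, progress = FALSE)
    ev
  })

  profile <- run_stage("saliency", {
    te <- which(dataset$partition == "test")
    sal <- config$saliency
    map <- average_saliency(clf, dataset$X[, , te, drop = FALSE],
                            layer = sal$layer, target = sal$target)
    B <- collapse_to_vector(map)
    tbl_n <- normalize_counts(tbl)
    dir <- if (identical(config$sitecall$direction, "saliency-sign")) {
      as.integer(sign(normalize_saliency(B)))
    } else {
      assign_direction(tbl_n, dataset$binning)
    }
    sensitivity_profile(B, dir, window = config$sitecall$window %||% 5L)
  })

  res <- run_stage("callsites", {
    sc <- config$sitecall
    calls <- call_sites(profile, min_site_length = sc$min_site_length %||% 10L)
    merged <- merge_sites(calls, max_gap = sc$max_gap %||% 6L,
                          profile = profile)
    tbl_n <- normalize_counts(tbl)
    mi <- mi_footprint(tbl_n, dataset$binning)
    paths$sensitivity <- file.path(out, "sensitivity.tsv")
    sens_out <- dplyr::mutate(profile, F = attr(calls, "F"))
    sens_out$mi <- mi$mi
    sens_out$mi_smooth <- mi$mi_smooth
    readr::write_tsv(sens_out, paths$sensitivity, progress = FALSE)
    paths$sites <- file.path(out, "sites.bed")
    write_sites_bed(merged, dataset$locus_name, paths$sites)

    known <- if (!is.null(config$annotations)) {
      read_annotations(config$annotations)
    } else if (!is.null(truth) && nrow(truth$sites) > 0) {
      dplyr::mutate(truth$sites, source = "ground_truth")
    }
    bench <- NULL
    if (!is.null(known)) {
      bench <- benchmark_sites(merged, known)
      paths$benchmark <- file.path(out, "benchmark.json")
      jsonlite::write_json(glance(bench), paths$benchmark,
                           auto_unbox = TRUE, digits = NA)
    }
    list(calls = calls, merged = merged, benchmark = bench)
  })

  paths$manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(
    list(package = "mprafoot",
         version = as.character(utils::packageVersion("mprafoot")),
         r_version = R.version.string,
         seed = seed,
         config = config[setdiff(names(config), "out")],
         artifacts = paths),
    paths$manifest, auto_unbox = TRUE, digits = NA, null = "null",
    force = TRUE)

  invisible(list(classifier = clf, evaluation = ev, dataset = dataset,
                 profile = profile, calls = res$calls, merged = res$merged,
                 benchmark = res$benchmark, paths = paths))
}
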
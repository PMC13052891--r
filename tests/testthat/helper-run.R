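# One full run of the pipeline on the default synthetic library (2000
# variants of a 160-bp wild type at 10% mutagenesis, 4 barcodes per
# variant, planted activator/promoter/repressor), shared by the tests
# that exercise end-to-end behaviour. Built lazily, once per session.
default_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tbl <- simulate_mpra(seed = 101)
    ds <- build_dataset(tbl, seed = 102)
    clf <- train_classifier(build_network(network_config(seed = 103), 160), ds)
    te <- which(ds$partition == "test")
    map <- average_saliency(clf, ds$X[, , te, drop = FALSE])
    B <- collapse_to_vector(map)
    tbl_n <- normalize_counts(tbl)
    profile <- sensitivity_profile(B, assign_direction(tbl_n, ds$binning))
    calls <- call_sites(profile)
    merged <- merge_sites(calls, profile = profile)
    cache <<- list(
      tbl = tbl, tbl_n = tbl_n, truth = attr(tbl, "truth"), dataset = ds,
      classifier = clf, evaluation = evaluate_classifier(clf, ds),
      map = map, profile = profile, calls = calls, merged = merged)
    cache
  }
})
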
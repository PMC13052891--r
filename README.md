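# mprafoot

Binding-site footprinting from massively parallel reporter assays
(MPRAs) with convolutional sequence classifiers and gradient saliency.

## The problem

Reg-Seq-style MPRAs mutagenize a fixed regulatory window (typically 160
bp around a bacterial transcription start site) at ~10% per base, couple
each variant to barcodes, and read out expression as the ratio of mRNA
to plasmid-DNA sequencing counts. The analysis question is inverse:
*which positions in the window are transcription-factor binding sites,
and do they activate or repress?* mprafoot answers it in two stages:

1. **Sequence → expression.** Normalized counts are discretized into
   three bins — zero, low and high — with the low/high boundary chosen by
   a randomized threshold search minimizing the Welch t-test p-value
   between bins. A per-locus convolutional network (input: the 4 × L
   one-hot image with row order A,T,C,G; loss: cross-entropy
   `-Σ yᵢ log pᵢ`; optimizer: mini-batch SGD with momentum) is trained
   to predict the bin from the raw sequence, with a 70/15/15
   train/validation/test split and class rebalancing of the training
   partition only.
2. **Model → sites.** The trained network is differentiated: by default
   the map is the ReLU'd gradient of the loss with respect to each input
   pixel, referenced to the variant's present base (a first-order
   in-silico-mutagenesis estimate); classic Grad-CAM on a chosen conv
   layer (channel weights `α_k = mean_j ∂y_c/∂A_kj`, map
   `ReLU(Σ_k α_k A_k)`) is also provided. Maps are averaged over the
   test variants and collapsed to a per-position saliency vector **B**
   (column maxima), which is z-scored (**S\***), exponentiated
   (`E = exp|S*|`), smoothed over 5 bp, and thresholded at mean + 1 sd.
   Peaks expand to sign-contiguous regions of the smoothed **S\***;
   regions of ≥ 10 bp become site calls, labelled activator or
   repressor by the expression shift of variants mutated in the span,
   and calls within 6 bp of each other (same direction) are merged.

A synthetic Reg-Seq simulator with a planted
activator/promoter/repressor architecture, a per-position
mutual-information footprint baseline, and benchmarking of calls
against known annotations complete the toolkit. Audience: people
analysing bacterial MPRA/Reg-Seq libraries, and people who want a fully
inspectable, dependency-light reference implementation of the
CNN-plus-saliency footprinting idea.

## Worked example

A complete run on the default synthetic library (2000 variants of a
160-bp wild type at 10% per-base mutagenesis, 4 barcodes per variant;
planted activator at 20–35, promoter at 60–95, repressor at 120–138,
effects ±2 on log expression):

```r
library(mprafoot)
library(dplyr)

tbl <- simulate_mpra(seed = 101)                 # counts + ground truth
ds  <- build_dataset(tbl, seed = 102)            # bin, split, rebalance, encode
clf <- train_classifier(build_network(network_config(seed = 103), 160), ds)
clf
#> <seq_classifier> input 4 x 160, 16 layers, 619,011 parameters, trained
#>   best epoch 14: val accuracy 76.6%

evaluate_classifier(clf, ds)
#> <classifier_evaluation> accuracy 76.9% on 1200 items (macro F1 0.775)
#>         predicted
#> measured zero  low high
#>     zero  342    0    0
#>     low     1  376   88
#>     high    1  187  205

te <- which(ds$partition == "test")
B  <- collapse_to_vector(average_saliency(clf, ds$X[, , te]))
profile <- sensitivity_profile(B, assign_direction(normalize_counts(tbl),
                                                   ds$binning))
sites <- merge_sites(call_sites(profile), profile = profile)
sites
#> # A tibble: 2 × 5
#>   start   end direction mean_sensitivity max_sensitivity
#>   <int>   <int> <chr>              <dbl>           <dbl>
#> 1    58    95 activator             2.88            5.23
#> 2   118   139 repressor             6.01           15.5

benchmark_sites(sites, mutate(attr(tbl, "truth")$sites, source = "truth"))
#> <benchmark_report> 2 called / 3 known: 2 captured (66.7%), 0 novel, 1 missed
```

Reading the output: the classifier separates the zero bin almost
perfectly (F1 1.00 — it has learned the promoter-knockout rule) and the
low/high bins imperfectly (they differ only through noisy graded
effects). The two calls recover the planted promoter (58–95, labelled
`activator` because mutations there lower expression — de novo calls are
never labelled `promoter`) and the repressor (118–139) at near-exact
boundaries with no spurious call; the weaker flanking activator is
missed in this run. `autoplot(profile, calls = sites)` draws the
sensitivity profile with the calls shaded; the run takes ~10 minutes on
one CPU core.

The same pipeline runs from the shell:

```sh
exec/mprafoot run --out runs/demo --seed 101          # simulate + analyse
exec/mprafoot run --table counts.tsv --annotations known.bed \
    --out runs/real --seed 1                          # your own table
```

writing `metrics.json`, `sensitivity.tsv`, `sites.bed`,
`benchmark.json` and a reproducibility manifest into the run directory.

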
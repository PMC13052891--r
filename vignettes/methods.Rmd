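---
title: "From MPRA counts to binding-site calls: the models behind mprafoot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From MPRA counts to binding-site calls: the models behind mprafoot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mprafoot analyses massively parallel reporter assay (MPRA) libraries of
the Reg-Seq type: a fixed regulatory window (160 bp by default) is
randomly mutagenized at roughly 10% per base, each variant is coupled to
one or more barcodes, and expression is read out as the ratio of mRNA to
plasmid DNA sequencing counts. The package trains a per-locus
convolutional network to predict discretized expression from the raw
sequence and then interrogates the trained network with gradient
attribution to locate activator and repressor binding sites at
base-pair resolution. This vignette explains each model, the tunable
parameters, the numerical choices, and what the synthetic benchmark
does and does not establish.

## The synthetic library generator

Real Reg-Seq data ships as sequencing counts with unknown ground truth,
so the package carries a simulator whose planted architecture makes
every downstream stage testable. The generative model is deliberately
minimal:

* a wild type of length $L$ (default 160 bp) is drawn uniformly over
  `{A,C,G,T}`;
* each variant mutates every position independently with probability
  `rate` (default 0.1), choosing uniformly among the three alternative
  bases — the Reg-Seq design;
* each planted site $k$ spanning interval $[s_k, e_k)$ has a signed
  per-unit-damage effect $\beta_k$, and a variant's expected expression
  is additive in log space in its damage fractions $d_k$ (the fraction
  of site positions mutated): $\log \mu = \log \mu_0 - \sum_k \beta_k
  d_k$. Positive $\beta$ is activator-like (damage lowers expression),
  negative $\beta$ repressor-like;
* the promoter site carries a knockout switch: damage at or above
  `promoter_kill_fraction` sets $\mu = 0$, which is what creates the
  overrepresented zero-expression class seen in real libraries;
* each barcode row draws a plasmid copy number $c \sim 1 +
  \mathrm{Pois}(\texttt{dna\_copy\_mean})$ (the offset keeps
  normalization finite) and an mRNA count $\mathrm{Pois}(c\,\mu\,
  e^{\varepsilon})$ with $\varepsilon \sim N(0, \texttt{noise\_sd})$.

The default architecture plants one activator (positions 20–35, effect
+2), one promoter (60–95, effect +2 plus the knockout switch) and one
repressor (120–138, effect −2) in a 2000-variant library with 4
barcodes per variant — library sizes in the range reported for real
Reg-Seq operons.

Two defaults deserve justification. `promoter_kill_fraction` is 0.125:
with a 35-bp promoter mutagenized at 10% per base, promoter damage is
$\mathrm{Binom}(35, 0.1)/35$, so a 0.125 threshold fires with
probability $P(X \ge 5) \approx 0.27$ and produces a zero class near a
quarter of the library; thresholds much higher than that essentially
never fire (at 0.3 the probability is $4 \times 10^{-4}$), leaving the
zero class empty and a three-class model untrainable. And the promoter
is given a graded effect (+2) in addition to its knockout switch so
that sub-threshold promoter damage also shifts expression, as promoter
mutations do in real libraries.

What the simulator does **not** emulate: PCR and sequencing errors,
barcode misassignment, growth-condition effects, position-specific
mutation biases, and epistasis between sites (effects are strictly
additive in log space). Tests passing on synthetic data therefore
establish that the pipeline's statistical machinery works when its
assumptions hold; they say nothing about, for example, robustness to
barcode collisions in real sequencing runs.

## Normalization and expression binning

Expression is `ct_RNA / ct_DNA` per barcode row; rows with zero DNA
count cannot be normalized and are dropped with a warning. Records with
normalized count 0 form the zero bin (label 1). The low/high boundary
on $\log$(normalized count) is found by a randomized search: 10,000
candidate thresholds drawn uniformly between the smallest and largest
finite log value, each scored by a Welch two-sample t-test between the
two groups it induces, keeping the threshold with the smallest
p-value. Natural log is used (any base gives the same ordering of
candidate splits), Welch rather than pooled-variance because the two
bins have no reason to share a variance, and candidates leaving a group
below `min_bin_size = 5` are skipped so the t-test stays defined. Ties
at the threshold go to the low bin. Because a threshold acts only
through the split it induces on the sorted values, the implementation
precomputes one p-value per split from cumulative sums and the
randomized search just indexes into them; the test suite checks it
against a literal split-enumeration oracle built on `stats::t.test`.

## Dataset assembly

Sequences are one-hot encoded as 4 × L binary images with row order
A, T, C, G. The data are split 70/15/15 into train/validation/test,
stratified by label with largest-remainder rounding so partition sizes
are exact. The zero bin typically dominates, so the training partition
is rebalanced to the median class count — the majority class sampled
without replacement, minority classes with replacement. Splitting
happens **before** rebalancing so that no resampled duplicate can leak
across partitions; validation and test are never rebalanced. (Whether
rebalancing precedes or follows splitting is genuinely open in the
pipeline this package re-implements; leakage prevention decides it
here.)

## The classifier

The default network is a three-block convolutional stack: conv(4×9, 32)
→ batch-norm → ReLU, conv(1×9, 64) → BN → ReLU → max-pool(2),
conv(1×9, 128) → BN → ReLU → max-pool(2), then dense(128) → ReLU →
dropout(0.5) → dense(3) → softmax. The first kernel spans all four base
rows, collapsing the base axis; all later layers are 1-D along the
sequence. Every piece of the engine — the im2col convolution, batch
norm, pooling, backpropagation — is implemented in the package (compiled
kernels over BLAS matrix products), and each layer's analytic gradient
is checked against central finite differences in the test suite.

Training is mini-batch SGD with momentum 0.9 on the mean cross-entropy
$-\sum_i y_i \log p_i$ (probabilities clamped at $10^{-12}$), batch 64.
Defaults that required tuning for stability, all overridable through
`network_config()`:

* learning rate 0.005 — 0.01 diverged reproducibly on the default
  synthetic library (validation loss exploding in epoch 2 followed by
  collapse to the uniform prediction);
* global gradient-norm clipping at 5, the standard remedy for the rare
  exploding mini-batch;
* weight decay $10^{-4}$ on conv/dense weights;
* a reduce-on-plateau schedule (halve the rate after 2 epochs without a
  new best validation accuracy);
* at most 24 epochs with early stopping at patience 8, keeping the
  weights of the best-validation-accuracy epoch. Twelve epochs already
  pass the accuracy level the package's acceptance tests demand, but
  the saliency maps of an under-trained model are visibly noisier, so
  the default budget leaves room for the maps to stabilize while a full
  default-scale run stays near ten minutes on one CPU core.

Evaluation reports accuracy, the 3 × 3 confusion matrix (rows =
measured, columns = predicted), per-class F1 = TP / (TP + (FP+FN)/2)
and the unweighted macro-F1; classes absent from both truth and
prediction are excluded from the macro average with a warning.

## Saliency

Two gradient-attribution estimators are implemented, sharing all
downstream processing.

**Input-pixel gradients (default).** For each test variant, the
gradient of the cross-entropy loss at the variant's predicted class is
taken with respect to every pixel of the one-hot input. One subtlety
matters: on the one-hot simplex the input gradient is only defined up
to a per-position additive constant (adding a constant to all four
bases of a column never changes a valid input), and that gauge freedom
is not harmless — the raw ReLU'd gradient showed consistent spurious
structure at the sequence ends. The map therefore references each
column's gradients to the variant's own present base, making entry
$(b, j)$ the first-order loss change of the point mutation $j \to b$ —
an in-silico-mutagenesis estimate. Negative parts are removed (ReLU)
and maps are averaged over the test set.

**Grad-CAM (`layer = k`).** The classic formulation: channel weights
are the mean gradient of the class score over a conv layer's activation
pixels, the map is the ReLU of the channel-weighted activation sum,
upsampled to input resolution and broadcast across the base rows. It is
exposed and tested (including a finite-difference oracle for the
channel weights), but on desk-scale synthetic data its channel-global
weights produce nearly flat maps — position-specific information lives
in the dense head, which global channel averaging cannot see — so it is
not the pipeline default.

Either way, the averaged 4 × L map is collapsed to a per-position
vector B by taking the column maximum over the four bases.

## Site calling

B is z-scored (population sd; a constant profile is an error since it
carries no signal), exponentiated as $E_j = \exp(|S^*_j|)$ — absolute
value because strong negative and strong positive normalized saliency
both flag functional positions — and smoothed with a centred 5-bp
moving average (truncated at the ends). Positions where smoothed E
exceeds its mean plus one standard deviation are peaks. Each peak is
expanded to the maximal surrounding region over which the smoothed
normalized saliency keeps one constant nonzero sign — contiguity in a
single regulatory sense — and regions of at least `min_site_length`
(default 10 bp, the minimum bacterial operator length) become calls.
Requiring instead that every position of a site stay above the peak
threshold proved brittle: real site profiles routinely dip below
mean + 1 sd inside a genuine site, and a single sub-threshold
position vetoes the whole call.

Call direction is taken from the data rather than from the saliency
sign: for each position, the mean log expression of variants mutated
there is compared with variants that are wild type there, and a call is
labelled activator when mutations in its span lower expression,
repressor when they raise it (spans with no information default to
activator, the convention for sites not previously mapped as
promoters). Saliency sign alone encodes above/below-average saliency,
which cannot distinguish activation from repression.

Calls with the same direction separated by at most 6 bp are merged for
a conservative site count, with sensitivities recomputed over the
merged span. Benchmarking against known annotations counts a known site
as captured when any call overlaps it by at least 1 bp; calls
overlapping no known site are novel.

A per-position mutual-information footprint — MI in bits between the
mutated-at-j indicator and the expression bin, smoothed with the same
5-bp window — is provided as the classical baseline statistic for the
same task.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout (BED convention).
* Population (1/L) standard deviations throughout the saliency chain.
* Sequences are uppercased on read; any character outside `{A,C,G,T}`
  is an error, since the 4-row encoding defines nothing else.
* Argmax ties in prediction break toward the lower class index.
* Max-pool ties route the gradient to the left element.
* All randomness is seeded through explicit arguments; no function
  touches the global RNG state except through `withr::with_seed`.

## Problem sizes

The shared end-to-end test run uses the full default conditions: 2000
variants × 4 barcodes (8000 records), 160 bp, the default network, and
the full randomized binning search. Unit tests use smaller fixtures
(60-bp wild types, a few hundred variants, narrow networks) chosen so
each one isolates a single contract.

## Known limitations

* The expression model is additive and site-local; cooperative or
  epistatic regulation is outside the simulator and untested.
* Attribution at the two sequence extremes is less reliable — edge
  positions participate in fewer convolution windows — although the
  present-base gauge fix removes the systematic component we observed.
* The mean + 1 sd peak threshold is scale-free but not a significance
  test; on pure-noise profiles the caller can emit occasional spurious
  regions, mirrored in real analyses as "novel" sites that need
  orthogonal evidence.
* Early stopping keeps the weights of the best validation-*accuracy*
  epoch. Accuracy can plateau several epochs before the saliency maps
  stabilize, so a run that converges unusually fast may stop with maps
  that recover fewer of the weaker sites; accuracy itself is unaffected.
* A single pooled multi-locus model is deliberately out of scope; one
  network is trained per locus.
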
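---
title: "Predicting CpG methylation from flanking-sequence k-mers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CpG methylation from flanking-sequence k-mers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

DNA methylation at CpG dinucleotides is a central epigenetic mark; in
promoter regions, hypermethylation can silence a gene, which is why
methylation prediction is of direct interest in cancer biology. The premise
of this package is that the methylation propensity of a CG site is partly
encoded in the local sequence: the k-mer composition of a 500 bp window
centred on the site carries enough signal for a classifier to call the
site methylated or unmethylated.

The pipeline is:

1. **Curation.** Each CG site with a percent-methylation call (a beta
   value, reads methylated / total reads) is binarized at
   `beta >= 50%` — the boundary is inclusive, so exactly 50% is
   *methylated*. A window of `flank` bases on each side of the CG
   (`2*flank + 2` bp; 500 bp at the default `flank = 249`) is extracted
   and the occurrence frequency of every motif in a fixed vocabulary is
   counted with overlapping matches.
2. **Vocabulary.** All k-mers for k = 1..4 (4 + 16 + 64 + 256 = 340)
   plus a configurable set of nine hexamers: 349 motifs at the defaults.
   Exhaustive hexamer enumeration (4096 motifs) would mostly add noise;
   a short curated list keeps the dimensionality down. The packaged
   default list (`default_hexamers()`) exists so the full pipeline runs
   out of the box; it is a synthetic stand-in (nine CpG-containing
   6-mers), and any real analysis should configure its own list.
3. **Reduction.** A univariate K-best filter keeps the 100 highest-scoring
   motifs.
4. **Feature analysis (optional).** One of three learned stages:
   autoencoder compression, GAN augmentation, or multi-head attention
   re-weighting.
5. **Classification.** A 1D-adapted UNet (or one of three baselines)
   with a sigmoid head, trained on a stratified 70:30 split with binary
   cross-entropy.
6. **Evaluation.** Threshold metrics (ACC, SE, SP, MCC, precision, F1),
   ROC/PR curves with areas, and — for external validation lists —
   the chi-square independence test and Cohen's kappa between observed
   and predicted labels.

## Window geometry

A "500 bp window with ±249 bp of flank" is only self-consistent if the
window is counted as flank + CG + flank: 249 + 2 + 249 = 500. The window
is therefore the half-open, 0-based interval `[p - flank, p + 2 + flank)`
where `p` is the C's position. Minus-strand calls get the reverse
complement of that interval so the context reads 5'→3' on the called
strand; CG is palindromic, so the central dinucleotide is unchanged. This
behaviour is configurable off (`reverse_complement_minus = FALSE`) because
public tracks differ in whether minus-strand calls are merged with their
plus-strand partners.

Windows containing `N` are kept by default: `N` matches no motif, so such
windows simply count fewer k-mers. `drop_n_windows = TRUE` removes them;
the curation report records how many.

## The K-best filter

No univariate score is canonical for count features against a binary
label, so two are offered: the one-way ANOVA F statistic (default) and a
chi-square score comparing per-class feature totals with the totals
expected from the class priors. Ties break toward the lower column index
so selection is deterministic. A feature that separates the classes with
zero within-class variance has an infinite F statistic and ranks first;
only flat features (no variance at all) score zero.

## The three feature-analysis stages

Each stage is fitted on the training split only and applied frozen
everywhere — fitting on all rows would leak held-out information into the
classifier's input representation.

* **Autoencoder.** Minimizes the mean squared reconstruction error
  `min 1/n * sum ||x_i - g(f(x_i))||^2` with a `p -> 64 -> latent`
  rectifier encoder and a mirrored decoder on z-scored columns. When this
  mode is chosen the classifier consumes the **latent matrix** — the
  compressed representation is the point of the stage.
* **GAN.** One small generator/discriminator pair per class plays the
  usual minimax game; generated profiles are clipped to the per-feature
  `[min, max]` of the training class so synthetic rows never leave the
  empirical support. The classifier consumes the **original features over
  the augmented row set**: this stage is data augmentation, not a
  re-representation. Synthetic rows join the training split only;
  held-out rows are never synthetic. A class with fewer than 10 rows is
  refused (with a warning) — a generator fitted to fewer rows is noise.
* **Multi-head attention.** Every feature is one token: its value scales
  a learned embedding vector, summed with a sinusoidal positional
  encoding. Scaled dot-product attention
  `A = softmax(Q K' / sqrt(d_k)) V` runs per head; head outputs are
  concatenated and projected. With labels, a mean-pooled linear head
  trained with binary cross-entropy drives all parameters. The stage's
  output re-weights each original feature column by its **attention
  mass** — the average attention its token receives, scaled so uniform
  attention gives weight 1 — which preserves the input width for the
  classifier. Attention is quadratic in the number of tokens, so fitting
  is capped at `max_fit_rows = 1024` stratified rows by default; the
  learned weight vector then applies to any number of rows at no cost.

## The UNet classifier

The architecture, at its published defaults: batch-normalized input, a
weight-normalized dense layer with 16,384 units reshaped to a
32 x 32 x 16 tensor, a 12-filter kernel-4 "same" convolution with swish
activation, 2 x 2 max pooling, two further batch-norm + weight-normalized
convolution blocks, an element-wise **multiplicative** skip connection
with the tensor saved before them, a second pool, a two-iteration decoder
(batch-norm, weight-normalized convolution, 2x nearest-neighbour
upsampling), and a dense head of 512/1024/512 rectifier blocks into one
sigmoid unit.

Two readings had to be fixed where the description is under-determined:

* **Pooling.** With "same" convolutions, the element-wise multiplication
  of the skip tensor only type-checks if each 2 x 2 pool uses stride 1
  and "valid" padding, shrinking height and width by exactly one. That is
  the only geometry under which the saved tensor and the post-convolution
  tensor agree, so it is the default (`build_unet(100)$shapes` walks the
  full chain: 32x32x16 → 31x31x12 → 30x30x12 → 120x120x12 → 172,800
  flattened).
* **Output.** The head is a single sigmoid unit (binary labels), not a
  softmax pair.

`unet_config_small()` is the same topology at desk scale (dense 256 →
8 x 8 x 4, 6 filters, kernel 3, head 32/64/32) and is what
`run_pipeline()` trains by default: the full-size head alone holds ~90M
parameters, which buys nothing on a 100-feature input but costs hours on
a CPU. The full-size configuration remains the `build_unet()` default and
is what the shape tests pin.

## Baselines

* **CNN** — features zero-padded to a square map, two convolution +
  pool blocks, dense head.
* **FFNN-KNN** — a one-hidden-layer feed-forward network; its hidden
  activations define the feature space for a K-nearest-neighbour
  majority vote (Euclidean distance, odd K, default 5). The predicted
  probability is the fraction of methylated neighbours, so the KNN stage
  is the decision maker, not a decoration; `stage = "ffnn"` exposes the
  network head alone for comparison.
* **Residual network** — a stack of dense residual blocks, each
  computing `H(x) = F(x) + x`. This is deliberately built from scratch:
  pretrained 2D-image weights have no meaning for tabular k-mer counts,
  so a "transfer learning" baseline on this input reduces to its
  architectural idea, the residual mapping.

All classifiers share one training contract: stratified seeded 70:30
split, binary cross-entropy on the sigmoid output, adaptive-moment
gradient descent (learning rate 1e-3, batch 64, 50 epochs by default),
per-epoch train/held-out loss and accuracy history, and bit-for-bit
reproducibility from the seed. The training engine is a small reverse-mode
implementation written for this package (dense, conv2d, batch norm,
weight norm, max pool, upsampling, residual blocks, attention); every
layer's analytic gradient is checked against central finite differences
in the test suite.

## Evaluation statistics

The threshold metrics follow their standard definitions; MCC uses the
square root in the denominator (the scale-invariant form — the name fixes
the intent). A metric with a zero denominator is reported as 0 and
flagged rather than thrown, because degenerate confusion matrices are
routine in small experiments. AUROC uses the pairwise convention (ties
count one half), which the exported curve integrates exactly; AUPRC is
the step-curve area. The chi-square test uses expected cells from the
marginals, df = 1, no continuity correction; for any 2x2 table the
identity `chi2 = N * MCC^2` holds and is property-tested. Cohen's kappa
is `(Po - Pe) / (1 - Pe)` with `Pe` from the marginal proportions; a
table with `Pe = 1` leaves kappa undefined (flagged `NA`).

## The synthetic study

`generate_study()` builds one contig of `n_sites` windows (each with a
CG planted at its centre) separated by spacers, so every window is fully
in-bounds and curation keeps exactly `n_sites` rows. Percent methylation
follows a logistic model of planted motif counts:
`percent = 100 * logistic(b0 + sum_m w_m * count_m + eps)`,
`eps ~ N(0, sigma^2)`. Planting effects on the logit scale keeps the
analytic truth (counts, logits, labels) available for every site, which
is what makes end-to-end signal-recovery tests possible.

The fixed study conditions used by the shipped checks:

* `strong_effect_config()` — 4,000 sites, five tetramer effects
  (`ACGT +1.2, GATC +0.9, CCGG +0.8, AATT -0.9, TGCA -0.8`), intercept
  −2.3 (centres the class balance near 50:50 given the expected counts),
  noise sd 0.5. A logistic fit on the true planted counts reaches
  AUROC ≈ 0.99, so the features carry the signal and a competent
  classifier should recover most of it.
* `zero_effect_config()` — no effects, noise sd 1: percent methylation
  is pure noise and any classifier's held-out AUROC should sit at
  chance.

What the generator emulates: per-site beta values with coverage, window
composition driving methylation, balanced or unbalanced classes via the
intercept. What it does not emulate: CpG-island spatial clustering,
bisulfite read-level error, coverage-dependent beta noise, strand
asymmetry, or correlated neighbouring sites. Passing the recovery checks
therefore shows the pipeline can find sequence-composition signal of the
planted form; it says nothing about how much such signal real RRBS data
contains.

## Problem sizes, budgets and numerical choices

The shipped end-to-end checks train the desk-scale UNet for 30 epochs on
the 4,000-site strong-effect study (held-out AUROC ≥ 0.85 with the
attention stage) and 8 epochs on three 800-site null studies (AUROC
0.5 ± 0.07); these sizes keep a full run in minutes on one CPU while
leaving the signal-recovery margins wide. Attention fitting uses 15
epochs on at most 1,024 stratified rows. Smaller unit tests use toy
topologies of the same layer types.

Other fixed choices: feature z-scoring uses training-split statistics
(constant columns get unit scale); parameter initialization is fan-in
scaled; batch norm uses momentum 0.9 running statistics for inference;
classification thresholds are boundary-inclusive (`p >= 0.5 -> 1`,
mirroring the beta rule); all RNG flows from a single user-supplied seed
through R's default generator, so runs are bit-reproducible on the same
platform.

## Known limitations

* The hexamer vocabulary is a required configuration in any real
  analysis; the packaged list is synthetic.
* "K-best" is implemented as a univariate filter; descriptions of
  K-best as a tree search with path metrics do not define a concrete
  supervised filter on count data, and the univariate reading is the one
  every standard toolkit uses.
* Validation lists are taken as given. An optional inter-quartile-range
  coverage filter (`iqr_coverage_filter = TRUE`) is available for lists
  that carry coverage, but no outlier removal happens silently.
* The pure-R training engine favours auditability over speed; it is not
  a platform for genome-scale training runs.
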
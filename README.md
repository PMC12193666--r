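# methylkmer

Predicting the binary methylation status of CpG sites from the k-mer
composition of their flanking genomic sequence.

DNA methylation at CG dinucleotides regulates gene expression; in promoter
regions, hypermethylation can silence a gene, which makes per-site
methylation calls a biomarker of direct interest in cancer biology.
Measuring methylation (bisulfite sequencing) is expensive; the local
sequence context is free. `methylkmer` is for computational biologists who
want a tested, fully reproducible pipeline that goes from a FASTA genome
plus a bedMethyl-style percent-methylation track to a trained sequence-based
classifier and a complete evaluation report — and a synthetic
planted-effect simulator so every stage can be exercised and unit-tested
without any download.

## The method

For each CG site with a percent-methylation call (beta value), the site is
labeled methylated iff beta ≥ 50% (boundary inclusive), and the
2·249 + 2 = 500 bp window centred on the CG is featurized by counting a
349-motif vocabulary with overlapping matches: all k-mers for k = 1..4
(340) plus nine configurable hexamers. A univariate K-best filter
(ANOVA F or chi-square score) keeps the top 100 motifs. Optionally one of
three learned feature-analysis stages runs next, each fitted on the
training split only:

- **autoencoder** — minimizes the reconstruction error
  `min 1/n Σᵢ ‖xᵢ − g(f(xᵢ))‖²` and hands the classifier the latent code;
- **GAN** — per-class generators play the minimax game
  `min_G max_D E[log D(x)] + E[log(1 − D(G(z)))]` and augment the
  training rows with synthetic profiles clipped to the class's empirical
  support;
- **multi-head attention** — each feature is a token (value embedding +
  sinusoidal positional encoding); per head,
  `Attention(Q, K, V) = softmax(QKᵀ/√d_k)V`, heads are concatenated and
  projected, and each feature column is re-weighted by its learned
  attention mass.

The classifier is a 1D-adapted UNet — weight-normalized dense 16,384 →
reshape 32×32×16 → 12-filter kernel-4 swish convolutions → 2×2 stride-1
max-pool → a multiplicative skip connection → a two-step upsampling
decoder → a 512/1024/512 rectifier head → sigmoid — or one of three
baselines (CNN; FFNN whose hidden layer feeds a Euclidean K-nearest-
neighbour vote; a from-scratch residual network of `H(x) = F(x) + x`
blocks). Training is stratified 70:30, binary cross-entropy, Adam,
bit-reproducible from one seed. Evaluation covers ACC/SE/SP/MCC/
precision/F1, ROC and PR curves with areas, and — for external site
lists — the chi-square independence test (`χ² = Σ(O−E)²/E`, df = 1, no
continuity correction) and Cohen's kappa (`κ = (P_o − P_e)/(1 − P_e)`)
between observed and predicted labels. For any 2×2 table `χ² = N·MCC²`,
an identity the test suite checks by property.

All learned components run on a small pure-R reverse-mode engine written
for this package; every layer's gradient is verified against finite
differences in the tests.

## Worked example

Simulate a study in which three tetramer effects drive methylation through
a logistic model, then run the full pipeline with attention preprocessing
and the (desk-scale) UNet:

```r
library(methylkmer)

study <- generate_study(synthetic_config(
  n_sites = 1000, planted_effects = c(ACGT = 1.2, GATC = 0.9, AATT = -0.9),
  intercept = -1.6, noise_sd = 0.5, seed = 7))

cfg <- run_config(genome = study$genome, track = study$calls,
                  preproc = "mhan", model = "unet", epochs = 25, seed = 42)
report <- run_pipeline(cfg)
report
#> Pipeline run: unet + mhan preprocessing
#> Held-out: accuracy 0.707, AUROC 0.770, kappa 0.378

report$metrics
#> # A tibble: 1 × 8
#>   accuracy sensitivity specificity   mcc precision    f1 auroc auprc
#>      <dbl>       <dbl>       <dbl> <dbl>     <dbl> <dbl> <dbl> <dbl>
#> 1    0.707       0.808       0.561 0.382     0.726 0.765 0.770 0.803

report$agreement
#> # A tibble: 1 × 6
#>    chi2    df  p_value kappa    po    pe
#>   <dbl> <int>    <dbl> <dbl> <dbl> <dbl>
#> 1  43.8     1 3.64e-11 0.378 0.707 0.528
```

The held-out AUROC of 0.77 says the classifier recovered most of the
planted sequence signal at this small size (at 4,000 sites it reaches
≈ 0.94); the chi-square p-value of 4 × 10⁻¹¹ says the association between
observed and predicted labels is far beyond chance, and κ = 0.38 is the
chance-corrected agreement. `autoplot(report$roc)`, `autoplot(report$model)`
and `tidy(report$model)` expose the curves and learning history;
`validate_sites()` applies a trained model to an external CG-site list and
reports the same statistics.

A thin CLI over the same functions ships in `inst/exec/methylkmer`
(subcommands `simulate`, `curate`, `run`, `validate`).

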
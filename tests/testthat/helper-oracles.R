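# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive (loops, O(n^2) scans) and share no code with
# the functions they verify.

# brute-force overlapping motif counter: slide a window of each motif's
# width one base at a time and compare substrings literally
naive_count_motifs <- function(sequences, motifs) {
  out <- matrix(0L, length(sequences), length(motifs),
                dimnames = list(NULL, motifs))
  for (s in seq_along(sequences)) {
    seqc <- sequences[s]
    L <- nchar(seqc)
    for (m in seq_along(motifs)) {
      k <- nchar(motifs[m])
      if (k > L) next
      cnt <- 0L
      for (i in seq_len(L - k + 1)) {
        if (substr(seqc, i, i + k - 1) == motifs[m]) cnt <- cnt + 1L
      }
      out[s, m] <- cnt
    }
  }
  out
}

# pairwise AUROC: fraction of positive-negative pairs ranked correctly,
# ties counted one half
pairwise_auroc <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# threshold-enumeration average precision: walk every distinct score as a
# cutoff (descending) and accumulate precision times recall increment
threshold_auprc <- function(truth, scores) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(truth == 1)
  prev_recall <- 0
  area <- 0
  for (ct in cuts) {
    called <- scores >= ct
    tp <- sum(truth == 1 & called)
    prec <- tp / sum(called)
    rec <- tp / n_pos
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

# direct arithmetic on the four cells, written independently of
# compute_metrics / cohens_kappa
arithmetic_metrics <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  list(
    acc = po,
    se = tp / (tp + fn),
    sp = tn / (tn + fp),
    precision = tp / (tp + fp),
    f1 = tp / (tp + 0.5 * (fp + fn)),
    mcc = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
    kappa = (po - pe) / (1 - pe),
    chi2_direct = {
      obs <- matrix(c(tp, fn, fp, tn), 2, 2)
      expd <- outer(rowSums(obs), colSums(obs)) / n
      sum((obs - expd)^2 / expd)
    }
  )
}

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
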
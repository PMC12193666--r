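#' Configuration for the synthetic planted-effect study
#'
#' Defines a simulated genome + methylation track with known structure: one
#' contig built by concatenating `n_sites` windows of length `2*flank + 2`,
#' each with a CG dinucleotide planted at its centre and separated by
#' `spacer` bp of background sequence (spacers also pad both ends, so every
#' window is fully in-bounds and curation keeps exactly `n_sites` rows).
#' Each site's percent methylation follows a logistic model of the planted
#' motif counts in its own window:
#' \deqn{percent = 100 \cdot logistic(b_0 + \sum_m w_m \, count_m(window)
#'   + \epsilon), \quad \epsilon \sim N(0, \sigma^2)}
#' so the analytic truth (counts, logits) is available for every site.
#'
#' @param n_sites Number of CG sites (windows).
#' @param flank Flank width in bp (default 249, i.e. 500 bp windows).
#' @param spacer Background bp between windows and at both contig ends
#'   (default 10).
#' @param planted_effects Named numeric vector: motif -> logit-scale weight.
#' @param intercept Logit-scale intercept `b0` (default 0).
#' @param noise_sd Logit-scale Gaussian noise sd (default 0.5).
#' @param base_composition Probabilities of A, C, G, T in the background
#'   sequence (default uniform).
#' @param coverage_lambda Mean of the (shifted) Poisson read coverage
#'   (default 30).
#' @param contig Contig name (default `"synthetic_1"`).
#' @param seed RNG seed.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_sites = 1000L, flank = 249L, spacer = 10L,
                             planted_effects = c(TACGTA = 1),
                             intercept = 0, noise_sd = 0.5,
                             base_composition = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                             coverage_lambda = 30, contig = "synthetic_1",
                             seed = 1L) {
  # accept list form (e.g. parsed YAML) for the named-vector fields
  planted_effects <- unlist(planted_effects) %||% numeric(0)
  base_composition <- unlist(base_composition)
  stopifnot(n_sites >= 1, flank >= 1, spacer >= 0,
            abs(sum(base_composition) - 1) < 1e-8,
            all(base_composition >= 0))
  if (length(planted_effects)) {
    if (is.null(names(planted_effects)) ||
        any(grepl("[^ACGT]", names(planted_effects)))) {
      stop("planted_effects must be named by motifs over {A,C,G,T}",
           call. = FALSE)
    }
    if (any(nchar(names(planted_effects)) > 2 * flank + 2)) {
      stop("a planted motif is longer than the window", call. = FALSE)
    }
  }
  structure(
    list(n_sites = as.integer(n_sites), flank = as.integer(flank),
         spacer = as.integer(spacer), planted_effects = planted_effects,
         intercept = intercept, noise_sd = noise_sd,
         base_composition = base_composition,
         coverage_lambda = coverage_lambda, contig = contig,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' The fixed study conditions used throughout the package
#'
#' `strong_effect_config()` plants five tetramer effects (three positive,
#' two negative) strong enough that window composition carries most of the
#' information about methylation status; `zero_effect_config()` has no
#' planted effects at all, so percent methylation is pure logit noise and
#' any classifier's held-out AUROC should sit at chance.
#'
#' @param n_sites Number of CG sites (defaults: 4000 strong, 1000 zero).
#' @param seed RNG seed.
#' @return A [synthetic_config()].
#' @export
strong_effect_config <- function(n_sites = 4000L, seed = 101L) {
  synthetic_config(
    n_sites = n_sites,
    planted_effects = c(ACGT = 1.2, GATC = 0.9, CCGG = 0.8,
                        AATT = -0.9, TGCA = -0.8),
    intercept = -2.3, noise_sd = 0.5, seed = seed
  )
}

#' @rdname strong_effect_config
#' @export
zero_effect_config <- function(n_sites = 1000L, seed = 202L) {
  synthetic_config(n_sites = n_sites, planted_effects = numeric(0),
                   intercept = 0, noise_sd = 1, seed = seed)
}

#' Generate a synthetic genome, methylation track and truth table
#'
#' Materializes the study defined by a [synthetic_config()]: a FASTA genome
#' with one contig, a `simple5` methylation track giving each central C's
#' 0-based position, and a truth table recording every site's planted motif
#' counts, logit and percent methylation. Fully reproducible from the
#' config's seed.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if missing). When `NULL`,
#'   nothing is written and only the in-memory objects are returned.
#' @return List with `genome` (named character), `calls` (tibble),
#'   `truth` (tibble) and, when written, `fasta_path`, `track_path`,
#'   `truth_path`.
#' @export
generate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_sites
  wlen <- 2L * config$flank + 2L
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(len) {
    paste(sample(bases, len, replace = TRUE, prob = config$base_composition),
          collapse = "")
  }
  windows <- vapply(seq_len(n), function(i) {
    w <- rand_seq(wlen)
    # plant the central CG: positions flank+1, flank+2 (1-based in window)
    paste0(substr(w, 1, config$flank), "CG",
           substr(w, config$flank + 3L, wlen))
  }, character(1))

  motifs <- names(config$planted_effects)
  counts <- if (length(motifs)) count_motifs(windows, motifs)
            else matrix(0L, n, 0)
  logit <- config$intercept +
    (if (length(motifs)) as.numeric(counts %*% config$planted_effects) else 0) +
    stats::rnorm(n, sd = config$noise_sd)
  percent <- 100 * stats::plogis(logit)
  coverage <- stats::rpois(n, config$coverage_lambda) + 1L

  spacers <- vapply(seq_len(n + 1L), function(i) rand_seq(config$spacer),
                    character(1))
  contig_seq <- paste0(paste0(spacers[seq_len(n)], windows, collapse = ""),
                       spacers[n + 1L])
  # window i starts at spacer*i + wlen*(i-1) (0-based); its C sits flank in
  starts <- config$spacer * seq_len(n) + wlen * (seq_len(n) - 1L)
  positions <- as.integer(starts + config$flank)

  genome <- stats::setNames(contig_seq, config$contig)
  calls <- tibble::tibble(
    contig = config$contig, position = positions, strand = "+",
    percent_meth = percent, coverage = as.integer(coverage)
  )
  truth <- tibble::tibble(
    site_id = paste(config$contig, positions, "+", sep = ":"),
    position = positions, logit = logit, percent_meth = percent,
    label = binarize_beta(percent)
  )
  if (length(motifs)) {
    for (m in motifs) truth[[paste0("count_", m)]] <- as.integer(counts[, m])
  }

  out <- list(genome = genome, calls = calls, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fasta_path <- file.path(out_dir, "genome.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome), fasta_path, width = 80L)
    track_path <- file.path(out_dir, "methylation.tsv")
    readr::write_tsv(calls, track_path, col_names = FALSE, progress = FALSE)
    truth_path <- file.path(out_dir, "truth.csv")
    readr::write_csv(truth, truth_path, progress = FALSE)
    out <- c(out, list(fasta_path = fasta_path, track_path = track_path,
                       truth_path = truth_path))
  }
  out
}

#' Generate a linearly separable tabular fixture
#'
#' A smoke-test dataset in which one designated feature determines the
#' label with a clear margin while the remaining features are independent
#' noise: feature `signal_col` is drawn at `+2` (label 1) or `-2` (label 0)
#' plus unit noise truncated so the classes never overlap. Labels are
#' balanced to within one row.
#'
#' @param n_rows,n_features Dimensions of the fixture.
#' @param signal_col Index of the label-determining feature (default 1).
#' @param seed RNG seed.
#' @return List with `X` (matrix with named columns), `labels` (0/1
#'   integer), `signal_col`.
#' @export
generate_separable <- function(n_rows = 200L, n_features = 20L,
                               signal_col = 1L, seed = 1L) {
  stopifnot(n_features >= 1, signal_col >= 1, signal_col <= n_features)
  set.seed(seed)
  labels <- rep(0:1, length.out = n_rows)[sample.int(n_rows)]
  x <- matrix(stats::rnorm(n_rows * n_features), n_rows, n_features)
  margin <- pmin(pmax(stats::rnorm(n_rows), -1.5), 1.5)
  x[, signal_col] <- ifelse(labels == 1, 2 + margin, -2 - margin)
  colnames(x) <- paste0("f", seq_len(n_features))
  list(X = x, labels = as.integer(labels), signal_col = signal_col)
}
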
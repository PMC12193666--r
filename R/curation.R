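#' Packaged default hexamer list (synthetic)
#'
#' Nine distinct CpG-containing hexamers used as the packaged default so the
#' full 349-motif vocabulary can be exercised out of the box. The framework's
#' published experiments used nine hexamers selected by earlier methylation
#' studies whose identities are not restated anywhere we can cite; this list
#' is therefore a synthetic stand-in, clearly non-canonical, and every
#' analysis that matters accepts its own `hexamers` argument. Vocabulary-size
#' arithmetic depends only on the list's length.
#'
#' @return Character vector of nine 6-mers over `{A,C,G,T}`.
#' @export
default_hexamers <- function() {
  c("CGACGT", "CGCGCG", "ACGCGT", "TTCGAA", "GCCGGC",
    "CACGTG", "TCGCGA", "AACGTT", "GACGTC")
}

#' Curation configuration
#'
#' Bundles the tunable parameters of the dataset-curation stage.
#'
#' @param flank Bases of flanking sequence on each side of the CG dinucleotide
#'   (default 249, i.e. a 2*249 + 2 = 500 bp window).
#' @param beta_cutoff Percent-methylation cutoff beta: sites at or above it
#'   are labeled methylated (default 50).
#' @param kmax_full Longest k for which *all* k-mers enter the vocabulary
#'   (default 4: 4 + 16 + 64 + 256 = 340 motifs, plus the hexamers).
#' @param hexamers Extra hexamer motifs appended to the vocabulary
#'   (default [default_hexamers()], a synthetic stand-in list).
#' @param min_coverage Minimum read coverage for a call to be used (default 1).
#' @param drop_edge_sites Drop calls whose window would run past a contig end
#'   (default `TRUE`).
#' @param reverse_complement_minus Reverse-complement windows of minus-strand
#'   calls so motif context is orientation-consistent; CG is palindromic so
#'   the central dinucleotide is unchanged (default `TRUE`).
#' @param drop_n_windows Drop windows containing any `N` (default `FALSE`;
#'   `N` never matches a motif, so retained windows just count fewer k-mers).
#' @return A list of class `"curation_config"`.
#' @export
curation_config <- function(flank = 249L,
                            beta_cutoff = 50,
                            kmax_full = 4L,
                            hexamers = default_hexamers(),
                            min_coverage = 1L,
                            drop_edge_sites = TRUE,
                            reverse_complement_minus = TRUE,
                            drop_n_windows = FALSE) {
  stopifnot(flank >= 1, beta_cutoff >= 0, beta_cutoff <= 100,
            kmax_full >= 1, kmax_full <= 6, min_coverage >= 0)
  if (length(hexamers)) {
    ok <- nchar(hexamers) == 6L & !grepl("[^ACGT]", hexamers)
    if (!all(ok)) {
      stop("hexamers must be 6-mers over {A,C,G,T}: ",
           paste(hexamers[!ok], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(flank = as.integer(flank), beta_cutoff = beta_cutoff,
         kmax_full = as.integer(kmax_full), hexamers = hexamers,
         min_coverage = as.integer(min_coverage),
         drop_edge_sites = isTRUE(drop_edge_sites),
         reverse_complement_minus = isTRUE(reverse_complement_minus),
         drop_n_windows = isTRUE(drop_n_windows)),
    class = "curation_config"
  )
}

#' Enumerate the motif vocabulary
#'
#' All k-mers over `{A,C,G,T}` for k = 1..`kmax_full` (lexicographic within
#' each length, lengths ascending), followed by the configured hexamers in
#' their given order. At the defaults this yields 4 + 16 + 64 + 256 + 9 = 349
#' motifs.
#'
#' @inheritParams curation_config
#' @return Character vector of distinct uppercase motifs.
#' @examples
#' length(enumerate_motifs())          # 349
#' enumerate_motifs(kmax_full = 1, hexamers = character())
#' @export
enumerate_motifs <- function(kmax_full = 4L, hexamers = default_hexamers()) {
  stopifnot(kmax_full >= 1, kmax_full <= 6)
  bases <- c("A", "C", "G", "T")
  kmers <- unlist(lapply(seq_len(kmax_full), function(k) {
    grid <- do.call(expand.grid,
                    c(rep(list(bases), k), stringsAsFactors = FALSE))
    # expand.grid varies the first factor fastest; reverse for lexicographic
    sort(do.call(paste0, grid), method = "radix")
  }), use.names = FALSE)
  if (length(hexamers)) {
    ok <- nchar(hexamers) == 6L & !grepl("[^ACGT]", hexamers)
    if (!all(ok)) {
      stop("hexamers must be 6-mers over {A,C,G,T}", call. = FALSE)
    }
    if (anyDuplicated(hexamers)) {
      stop("duplicate hexamer: ",
           hexamers[duplicated(hexamers)][1], call. = FALSE)
    }
    if (any(hexamers %in% kmers)) {
      stop("hexamer duplicates a vocabulary k-mer", call. = FALSE)
    }
  }
  c(kmers, hexamers)
}

#' Extract the sequence window around a CG site
#'
#' Returns the `2*flank + 2` bp substring covering `flank` bases upstream of
#' the C through `flank` bases downstream of the G, i.e. the half-open
#' 0-based interval `[position - flank, position + 2 + flank)`. For
#' minus-strand calls the reverse complement of that substring is returned
#' (when `reverse_complement` is `TRUE`), so the motif context reads in the
#' strand's own 5'-3' direction. Returns `NA` when the window would run past
#' either contig end.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param contig Contig id.
#' @param position 0-based position of the C of the CG dinucleotide.
#' @param strand `"+"` or `"-"`.
#' @param flank Flank width in bp (default 249).
#' @param reverse_complement Reverse-complement minus-strand windows
#'   (default `TRUE`).
#' @return A single DNA string, or `NA_character_` if out of bounds.
#' @export
extract_window <- function(genome, contig, position, strand = "+",
                           flank = 249L, reverse_complement = TRUE) {
  if (!contig %in% names(genome)) {
    stop("contig '", contig, "' not present in the genome", call. = FALSE)
  }
  seq <- genome[[contig]]
  start0 <- position - flank               # 0-based inclusive
  end0 <- position + 2L + flank            # 0-based exclusive
  if (start0 < 0 || end0 > nchar(seq)) {
    return(NA_character_)
  }
  w <- substr(seq, start0 + 1L, end0)
  if (identical(strand, "-") && isTRUE(reverse_complement)) {
    w <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
  }
  w
}

#' Count overlapping motif occurrences in windows
#'
#' Counts every occurrence of every motif in every window, sliding one base
#' at a time (overlapping matches count). Matching is literal: a window
#' position containing `N` never matches any motif.
#'
#' @param sequences Character vector of windows over `{A,C,G,T,N}`.
#' @param motifs Character vector of motifs, e.g. from [enumerate_motifs()].
#' @return Integer matrix, `length(sequences)` rows by `length(motifs)`
#'   columns, with motif names on the columns.
#' @examples
#' count_motifs("CGCG", c("CG", "GC", "CGC"))
#' @export
count_motifs <- function(sequences, motifs) {
  stopifnot(is.character(sequences), is.character(motifs))
  out <- matrix(0L, nrow = length(sequences), ncol = length(motifs),
                dimnames = list(NULL, motifs))
  if (!length(sequences) || !length(motifs)) return(out)
  nonempty <- nzchar(sequences)
  if (any(nonempty)) {
    subj <- Biostrings::DNAStringSet(sequences[nonempty])
    for (j in seq_along(motifs)) {
      out[nonempty, j] <- Biostrings::vcountPattern(motifs[j], subj,
                                                    fixed = TRUE)
    }
  }
  out
}

#' Binarize percent methylation at the beta cutoff
#'
#' A site is labeled methylated (1) when its percent methylation is at or
#' above the cutoff — the boundary is inclusive — and unmethylated (0)
#' otherwise.
#'
#' @param percent_meth Numeric vector of percent-methylation values in
#'   `[0, 100]`.
#' @param beta_cutoff Cutoff in percent (default 50).
#' @return Integer vector of 0/1 labels.
#' @examples
#' binarize_beta(c(49.99, 50, 100))
#' @export
binarize_beta <- function(percent_meth, beta_cutoff = 50) {
  if (any(!is.finite(percent_meth) | percent_meth < 0 | percent_meth > 100)) {
    stop("percent methylation must lie in [0, 100]", call. = FALSE)
  }
  as.integer(percent_meth >= beta_cutoff)
}

#' Build the labeled feature matrix from a genome and methylation calls
#'
#' Runs the full curation stage: drops calls below the coverage floor, drops
#' calls whose window runs past a contig end (and optionally windows
#' containing `N`), extracts each surviving site's window, counts the motif
#' vocabulary in it, and attaches the binarized beta label. Row order follows
#' input order; row ids are `contig:position:strand`.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param calls Tibble of methylation calls from [read_methylation_track()].
#' @param config A [curation_config()].
#' @return A list of class `"curated_dataset"` with elements
#'   `features` (tibble: `site_id`, one column per motif, `label`) and
#'   `report` (named integer vector of input/kept/dropped counts by reason).
#' @export
build_dataset <- function(genome, calls, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"), is.data.frame(calls))
  motifs <- enumerate_motifs(config$kmax_full, config$hexamers)
  n_in <- nrow(calls)
  report <- c(input = n_in, kept = 0L, low_coverage = 0L,
              edge_dropped = 0L, n_dropped = 0L)

  missing_contig <- setdiff(unique(calls$contig), names(genome))
  if (length(missing_contig)) {
    stop("contig '", missing_contig[1], "' not present in the genome",
         call. = FALSE)
  }

  keep <- calls$coverage >= config$min_coverage
  report["low_coverage"] <- sum(!keep)
  calls <- calls[keep, , drop = FALSE]

  windows <- purrr::pmap_chr(
    list(calls$contig, calls$position, calls$strand),
    function(contig, position, strand) {
      w <- extract_window(genome, contig, position, strand,
                          flank = config$flank,
                          reverse_complement = config$reverse_complement_minus)
      if (is.na(w)) NA_character_ else w
    }
  )
  oob <- is.na(windows)
  if (any(oob) && !config$drop_edge_sites) {
    stop("window out of contig bounds at site ",
         calls$contig[oob][1], ":", calls$position[oob][1],
         " (set drop_edge_sites = TRUE to drop such sites)", call. = FALSE)
  }
  report["edge_dropped"] <- sum(oob)
  calls <- calls[!oob, , drop = FALSE]
  windows <- windows[!oob]

  if (config$drop_n_windows) {
    has_n <- grepl("N", windows, fixed = TRUE)
    report["n_dropped"] <- sum(has_n)
    calls <- calls[!has_n, , drop = FALSE]
    windows <- windows[!has_n]
  }

  report["kept"] <- length(windows)
  counts <- count_motifs(windows, motifs)
  features <- tibble::as_tibble(counts)
  features <- tibble::add_column(
    features,
    site_id = paste(calls$contig, calls$position, calls$strand, sep = ":"),
    .before = 1
  )
  features$label <- binarize_beta(calls$percent_meth, config$beta_cutoff)
  if (nrow(features) == 0L) {
    warning("curation produced an empty feature matrix (all calls dropped)",
            call. = FALSE)
  }
  structure(list(features = features, report = report),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("Curated CpG feature matrix:", x$report["kept"], "sites x",
      length(feature_columns(x$features)), "motifs\n")
  drops <- x$report[c("low_coverage", "edge_dropped", "n_dropped")]
  cat("Dropped:", paste(names(drops), drops, sep = "=", collapse = ", "),
      "of", x$report["input"], "input calls\n")
  invisible(x)
}
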
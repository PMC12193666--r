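# small file fixtures built in code at test time

write_tmp_fasta <- function(records, wrap = NULL) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  lines <- unlist(lapply(names(records), function(id) {
    seqc <- records[[id]]
    body <- if (is.null(wrap)) seqc else {
      starts <- seq(1, nchar(seqc), by = wrap)
      vapply(starts, function(s) substr(seqc, s, min(s + wrap - 1, nchar(seqc))),
             character(1))
    }
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}

write_tmp_track <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a tiny genome with one CG centred in each of a few 2*flank+2 windows
tiny_study <- function(n_sites = 3, flank = 5, seed = 42) {
  set.seed(seed)
  wlen <- 2 * flank + 2
  windows <- vapply(seq_len(n_sites), function(i) {
    w <- random_dna(wlen)
    paste0(substr(w, 1, flank), "CG", substr(w, flank + 3, wlen))
  }, character(1))
  spacer <- strrep("T", 8)
  contig <- paste0(spacer, paste(windows, collapse = spacer), spacer)
  starts <- nchar(spacer) * seq_len(n_sites) + wlen * (seq_len(n_sites) - 1)
  positions <- starts + flank
  list(
    genome = c(chrT = contig),
    calls = tibble::tibble(
      contig = "chrT", position = positions, strand = "+",
      percent_meth = seq(10, 90, length.out = n_sites),
      coverage = 10L
    ),
    windows = windows, flank = flank
  )
}
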
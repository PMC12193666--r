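test_that("motif vocabulary has the expected composition and order", {
  expect_identical(enumerate_motifs(1, character()), c("A", "C", "G", "T"))
  expect_length(enumerate_motifs(2, character()), 20L)   # 4 + 16
  m <- enumerate_motifs(4, default_hexamers())
  expect_length(m, 349L)                                 # 4+16+64+256+9
  expect_false(anyDuplicated(m) > 0)
  # lengths ascending (stable order keeps lexicographic ties in place)
  expect_identical(m, m[order(nchar(m))])
  dimers <- m[nchar(m) == 2]
  expect_identical(dimers, sort(dimers, method = "radix"))
  # configured hexamers come last, in configured order
  expect_identical(utils::tail(m, 9), default_hexamers())
})

test_that("duplicate or invalid hexamers are rejected", {
  expect_error(enumerate_motifs(4, c("ACGTAC", "ACGTAC")), "duplicate")
  expect_error(enumerate_motifs(4, "ACGT"), "6-mers")
  expect_error(enumerate_motifs(4, "ACGTAN"), "6-mers")
})

test_that("window extraction is exact at the boundaries", {
  contig <- paste0(strrep("A", 249), "CG", strrep("T", 249))
  g <- c(c1 = contig)
  w <- extract_window(g, "c1", 249, "+", flank = 249)
  expect_identical(w, contig)          # exact 500 bp fit
  expect_identical(nchar(w), 500L)

  short <- c(c1 = random_dna(500))
  expect_true(is.na(extract_window(short, "c1", 10, "+", flank = 249)))
  expect_error(extract_window(short, "nope", 10, "+"), "contig")
})

test_that("minus-strand windows are reverse-complemented", {
  g <- c(x = "AAACGTTT")
  expect_identical(extract_window(g, "x", 3, "-", flank = 1), "ACGT")
  expect_identical(extract_window(g, "x", 3, "+", flank = 1), "ACGT")
  g2 <- c(x = "GGACGATT")   # the CG's C sits at 0-based position 3
  expect_identical(extract_window(g2, "x", 3, "+", flank = 2), "GACGAT")
  expect_identical(extract_window(g2, "x", 3, "-", flank = 2), "ATCGTC")
  # palindromic central CG is unchanged by the flip
  expect_identical(substr(extract_window(g2, "x", 3, "-", flank = 2), 3, 4),
                   "CG")
})

test_that("overlapping occurrences are counted and N matches nothing", {
  cts <- count_motifs("CGCG", c("CG", "GC", "CGC", "GCG"))
  expect_equal(unname(cts[1, ]), c(2L, 1L, 1L, 1L))
  mono <- count_motifs(c("ACGT", "ANA", ""), c("A", "C", "G", "T"))
  expect_equal(unname(mono[1, ]), rep(1L, 4))
  expect_equal(unname(mono[2, ]), c(2L, 0L, 0L, 0L))
  expect_equal(unname(mono[3, ]), rep(0L, 4))
})

test_that("count_motifs agrees with the naive scanner on random cases", {
  set.seed(77)
  for (i in 1:500) {
    L <- sample(5:60, 1)
    seqc <- random_dna(L, alphabet = c("A", "C", "G", "T",
                                       if (i %% 5 == 0) "N"))
    k <- sample(c(1:4, 6), 1)
    motif <- random_dna(min(k, L))
    expect_identical(count_motifs(seqc, motif)[1, 1],
                     naive_count_motifs(seqc, motif)[1, 1])
  }
})

test_that("monomer counts conserve window length and k-mer counts respect bounds", {
  set.seed(78)
  motifs <- enumerate_motifs(3, character())
  for (i in 1:25) {
    w <- random_dna(500)
    cts <- count_motifs(w, motifs)
    expect_equal(sum(cts[1, c("A", "C", "G", "T")]), 500L)
    for (k in 1:3) {
      expect_true(all(cts[1, nchar(motifs) == k] <= 500 - k + 1))
    }
  }
})

test_that("beta binarization is boundary-inclusive", {
  expect_identical(binarize_beta(c(50, 49.99, 0, 100)), c(1L, 0L, 0L, 1L))
  expect_identical(binarize_beta(75, beta_cutoff = 80), 0L)
  expect_error(binarize_beta(150), "\\[0, 100\\]")
  expect_error(binarize_beta(-1), "\\[0, 100\\]")
})

test_that("build_dataset drops by coverage and window bounds, and reports", {
  st <- tiny_study(n_sites = 3, flank = 5)
  cfg <- curation_config(flank = 5, kmax_full = 2, hexamers = character())
  # push one call within 2 bp of the contig end so its window is truncated
  calls <- st$calls
  calls$position[3] <- nchar(st$genome[[1]]) - 2L
  calls$coverage[2] <- 0L
  ds <- build_dataset(st$genome, calls, cfg)
  expect_equal(nrow(ds$features), 1L)
  expect_equal(unname(ds$report["low_coverage"]), 1L)
  expect_equal(unname(ds$report["edge_dropped"]), 1L)
  expect_equal(unname(ds$report["input"]),
               unname(ds$report["kept"] + ds$report["low_coverage"] +
                        ds$report["edge_dropped"] + ds$report["n_dropped"]))
  expect_identical(ds$features$site_id,
                   paste("chrT", calls$position[1], "+", sep = ":"))
  expect_identical(ds$features$label, binarize_beta(calls$percent_meth[1]))
})

test_that("build_dataset is deterministic and its counts match the windows", {
  st <- tiny_study(n_sites = 4, flank = 6, seed = 9)
  cfg <- curation_config(flank = 6, kmax_full = 2, hexamers = character())
  ds1 <- build_dataset(st$genome, st$calls, cfg)
  ds2 <- build_dataset(st$genome, st$calls, cfg)
  expect_identical(ds1$features, ds2$features)
  motifs <- enumerate_motifs(2, character())
  expect_equal(as.matrix(ds1$features[motifs]),
               naive_count_motifs(st$windows, motifs),
               ignore_attr = TRUE)
})

test_that("empty curation result warns instead of erroring", {
  st <- tiny_study(n_sites = 2, flank = 5)
  calls <- st$calls
  calls$coverage <- 0L
  expect_warning(
    ds <- build_dataset(st$genome, calls,
                        curation_config(flank = 5, kmax_full = 1,
                                        hexamers = character())),
    "empty"
  )
  expect_equal(nrow(ds$features), 0L)
})
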
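test_that("toy reference geometry follows the requested segment lengths", {
  p <- decay_params(n_transcripts = 1L, utr5_len = 60L, cds_len = 300L,
                    utr3_len = 90L, total_reads = 100L, seed = 3L)
  ref <- build_toy_reference(p)
  m <- ref$models[[1L]]
  expect_equal(spliced_length(m), 450L)
  expect_equal(m$cds_start_t, 60L)
  expect_equal(m$cds_stop_t, 357L)
  s <- spliced_seq(m, ref$genome)
  expect_equal(substr(s, 61L, 63L), "ATG")
  expect_true(substr(s, 358L, 360L) %in% c("TAA", "TAG", "TGA"))
})

test_that("toy reference is deterministic and alternates strands", {
  p <- decay_params(n_transcripts = 10L, total_reads = 100L, seed = 5L)
  a <- build_toy_reference(p)
  b <- build_toy_reference(p)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$models, b$models)
  strands <- vapply(a$models, `[[`, "", "strand")
  expect_equal(sum(strands == "+"), 5L)
  expect_equal(sum(strands == "-"), 5L)
  # start/stop codons also on minus-strand transcripts (transcript sense)
  for (m in a$models[strands == "-"][1:2]) {
    s <- spliced_seq(m, a$genome)
    expect_equal(substr(s, m$cds_start_t + 1L, m$cds_start_t + 3L), "ATG")
  }
})

test_that("pure mixture components place 5' ends where the model says", {
  p <- decay_params(n_transcripts = 4L, p_periodic = 1, p_term = 0,
                    p_background = 0, frame_anchor = 0L,
                    total_reads = 4000L, seed = 9L)
  ref <- build_toy_reference(p)
  tr <- sample_fiveprime_ends(p, ref$models)
  starts <- vapply(ref$models, `[[`, 0L, "cds_start_t")[tr$transcript_id]
  expect_true(all((tr$pos_t - starts) %% 3L == 0L))
  stops <- vapply(ref$models, `[[`, 0L, "cds_stop_t")[tr$transcript_id]
  expect_true(all(tr$pos_t >= starts & tr$pos_t < stops - p$term_offset))

  p2 <- decay_params(n_transcripts = 4L, p_periodic = 0, p_term = 1,
                     p_background = 0, term_offset = 17L,
                     total_reads = 1000L, seed = 9L)
  tr2 <- sample_fiveprime_ends(p2, ref$models)
  stops2 <- vapply(ref$models, `[[`, 0L, "cds_stop_t")[tr2$transcript_id]
  expect_true(all(tr2$pos_t == stops2 - 17L))
})

test_that("empirical component fractions match the mixture weights", {
  p <- decay_params(n_transcripts = 10L, total_reads = 10000L, seed = 21L)
  ref <- build_toy_reference(p)
  tr <- sample_fiveprime_ends(p, ref$models)
  frac <- table(tr$component)[c("periodic", "term", "background")] / nrow(tr)
  w <- c(p$p_periodic, p$p_term, p$p_background)
  # binomial standard error at n = 10000
  se <- sqrt(w * (1 - w) / nrow(tr))
  expect_true(all(abs(frac - w) <= 3 * se))
})

test_that("ground-truth genomic positions are consistent with the models", {
  p <- small_params()
  ref <- build_toy_reference(p)
  tr <- sample_fiveprime_ends(p, ref$models)
  idx <- sample(nrow(tr), 500L)
  for (i in idx) {
    m <- ref$models[[tr$transcript_id[i]]]
    expect_equal(transcript_to_genomic(m, tr$pos_t[i]), tr$gpos[i])
  }
})

test_that("autocorrelation of a pure comb peaks at lag 3", {
  p <- decay_params(n_transcripts = 6L, p_periodic = 1, p_term = 0,
                    p_background = 0, total_reads = 6000L, seed = 13L)
  ref <- build_toy_reference(p)
  tr <- sample_fiveprime_ends(p, ref$models)
  # brute-force oracle on the pooled CDS-relative histogram
  rel <- tr$pos_t - vapply(ref$models, `[[`, 0L,
                           "cds_start_t")[tr$transcript_id]
  h <- tabulate(rel + 1L, nbins = max(rel) + 1L)
  ac <- vapply(1:12, function(lag)
    sum(h[seq_len(length(h) - lag)] * h[-seq_len(lag)]), 0)
  expect_equal(which.max(ac), 3L)
})

test_that("emitted FASTQ/BED/alignments conserve reads and regenerate byte-identically", {
  p <- decay_params(n_transcripts = 6L, total_reads = 3000L, seed = 17L)
  ref <- build_toy_reference(p)
  tr <- sample_fiveprime_ends(p, ref$models)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  f1 <- emit_reads(tr, ref$models, ref$genome, p, d1)
  f2 <- emit_reads(tr, ref$models, ref$genome, p, d2)
  expect_equal(nrow(read_fastq(f1[["fastq"]])), nrow(tr))
  expect_equal(length(readLines(f1[["bed"]])), nrow(tr))
  expect_equal(nrow(read.delim(f1[["alignments"]])), nrow(tr))
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
})

test_that("emitted 5'-end BED records are strand-aware single positions", {
  # plus-strand transcript starting at genomic 100: transcript pos 0 -> 100
  mp <- toy_model(g0 = 100L, strand = "+")
  mm <- toy_model(tid = "T2", g0 = 100L, strand = "-")
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 1000L)))
  p <- decay_params(n_transcripts = 1L, total_reads = 1L, seed = 1L)
  tr <- data.frame(read_id = "r1", transcript_id = "T1", pos_t = 0L,
                   component = "background", reference = "chr1",
                   gpos = transcript_to_genomic(mp, 0L), strand = "+")
  f <- emit_reads(tr, list(T1 = mp), genome, p, tempdir(), prefix = "bp")
  expect_equal(strsplit(readLines(f[["bed"]]), "\t")[[1L]][2:3],
               c("100", "101"))
  # minus-strand transcript ending at genomic 550: transcript pos 0 -> 549
  tr2 <- data.frame(read_id = "r1", transcript_id = "T2", pos_t = 0L,
                    component = "background", reference = "chr1",
                    gpos = transcript_to_genomic(mm, 0L), strand = "-")
  expect_equal(tr2$gpos, 549L)
  f2 <- emit_reads(tr2, list(T2 = mm), genome, p, tempdir(), prefix = "bm")
  expect_equal(strsplit(readLines(f2[["bed"]]), "\t")[[1L]][2:3],
               c("549", "550"))
  # empty truth -> valid empty outputs
  f0 <- emit_reads(tr[0, ], list(T1 = mp), genome, p, tempdir(),
                   prefix = "b0")
  expect_equal(nrow(read_fastq(f0[["fastq"]])), 0L)
})

test_that("site sampling validates positions and honours site mass", {
  p <- decay_params(n_transcripts = 5L, total_reads = 20000L, seed = 23L)
  ref <- build_toy_reference(p)
  bad <- site_annotation("TOY0001", 10000L, "mirna_cleavage")
  expect_error(sample_fiveprime_ends(p, ref$models, sites = bad), "beyond")
  sites <- site_annotation(c("TOY0001", "TOY0002"), c(400L, 20L),
                           c("mirna_cleavage", "uorf_stall"))
  tr <- sample_fiveprime_ends(p, ref$models, sites = sites,
                              site_weight = 0.05)
  site_reads <- tr[tr$component == "site", ]
  frac <- nrow(site_reads) / nrow(tr)
  expect_true(abs(frac - 0.10) < 3 * sqrt(0.1 * 0.9 / nrow(tr)))
  expect_setequal(unique(site_reads$pos_t[site_reads$transcript_id ==
                                            "TOY0001"]), 400L)
})
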
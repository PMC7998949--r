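test_that("FASTA round trip uppercases and validates sequences", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt"), fa)
  g <- read_genome(fa)
  expect_length(g, 1L)
  expect_equal(as.character(g[["chr1"]]), "ACGT")

  writeLines(character(0), fa)
  expect_length(read_genome(fa), 0L)

  writeLines(c("ACGT", ">chr1"), fa)
  expect_error(read_genome(fa), "line 1")

  writeLines(c(">chr1", "ACRT"), fa)
  expect_error(read_genome(fa), "outside")
})

test_that("GTF coordinates convert to 0-based transcript coordinates", {
  gtf <- tempfile(fileext = ".gtf")
  write_test_gtf(gtf, list(
    list(chr = "c", type = "exon", start = 1L, end = 300L, strand = "+",
         gene = "gp", tx = "tp"),
    list(chr = "c", type = "CDS", start = 101L, end = 250L, strand = "+",
         gene = "gp", tx = "tp"),
    list(chr = "c", type = "stop_codon", start = 251L, end = 253L,
         strand = "+", gene = "gp", tx = "tp")))
  m <- read_annotation(gtf)[["tp"]]
  expect_equal(m$cds_start_t, 100L)
  expect_equal(m$cds_stop_t, 250L)
  expect_equal(m$spliced_len, 300L)
})

test_that("minus-strand GTF transcript coordinates run 5' to 3'", {
  gtf <- tempfile(fileext = ".gtf")
  write_test_gtf(gtf, list(
    list(chr = "c", type = "exon", start = 1L, end = 300L, strand = "-",
         gene = "gm", tx = "tm"),
    list(chr = "c", type = "CDS", start = 51L, end = 200L, strand = "-",
         gene = "gm", tx = "tm"),
    list(chr = "c", type = "stop_codon", start = 48L, end = 50L,
         strand = "-", gene = "gm", tx = "tm")))
  m <- read_annotation(gtf)[["tm"]]
  # brute-force oracle: transcript position of 0-based genomic g on a
  # single reverse-strand exon [0, 300) is 299 - g; the stop codon bases
  # are genomic 47..49, so its first (5'-most in transcript space)
  # nucleotide is 299 - 49 = 250
  expect_equal(m$cds_stop_t, 250L)
  expect_equal(m$cds_start_t, 100L)
})

test_that("invalid transcripts are rejected with a warning, not an error", {
  gtf <- tempfile(fileext = ".gtf")
  write_test_gtf(gtf, list(
    list(chr = "c", type = "exon", start = 1L, end = 300L, strand = "+",
         gene = "g1", tx = "bad_cds"),
    list(chr = "c", type = "CDS", start = 101L, end = 200L, strand = "+",
         gene = "g1", tx = "bad_cds"),
    list(chr = "c", type = "stop_codon", start = 201L, end = 203L,
         strand = "+", gene = "g1", tx = "bad_cds"),
    list(chr = "c", type = "exon", start = 401L, end = 700L, strand = "+",
         gene = "g2", tx = "no_stop"),
    list(chr = "c", type = "CDS", start = 501L, end = 650L, strand = "+",
         gene = "g2", tx = "no_stop")))
  expect_warning(expect_warning(models <- read_annotation(gtf), "bad_cds"),
                 "no_stop")
  expect_false("bad_cds" %in% names(models))
  expect_false("no_stop" %in% names(models))
})

test_that("genomic/transcript conversion handles strand and splicing", {
  m1 <- transcript_model("t", "g", "c", "+", cbind(100L, 200L), 10L, 70L)
  expect_equal(genomic_to_transcript(m1, 100L), 0L)
  m2 <- transcript_model("t", "g", "c", "-", cbind(100L, 200L), 10L, 70L)
  expect_equal(genomic_to_transcript(m2, 199L), 0L)
  # two exons [0,50) + [100,150): brute-force enumeration of the spliced
  # positions puts genomic 100 at spliced index 50
  spliced <- c(0:49, 100:149)
  m3 <- transcript_model("t", "g", "c", "+",
                         rbind(c(0L, 50L), c(100L, 150L)), 0L, 60L)
  expect_equal(genomic_to_transcript(m3, 100L), which(spliced == 100L) - 1L)
  expect_true(is.na(genomic_to_transcript(m3, 75L)))
})

test_that("conversion round trip is the identity on all exonic positions", {
  for (strand in c("+", "-")) {
    m <- transcript_model("t", "g", "c", strand,
                          rbind(c(10L, 60L), c(80L, 110L), c(200L, 230L)),
                          5L, 65L)
    gpos <- c(10:59, 80:109, 200:229)
    tpos <- genomic_to_transcript(m, gpos)
    expect_false(anyNA(tpos))
    expect_setequal(tpos, 0:(spliced_length(m) - 1L))   # bijection
    expect_equal(transcript_to_genomic(m, tpos), gpos)  # round trip
  }
})

test_that("annotation write/read reproduces the simulator models exactly", {
  ref <- build_toy_reference(small_params())
  gtf <- tempfile(fileext = ".gtf")
  write_annotation(ref$models, gtf)
  back <- read_annotation(gtf)
  expect_setequal(names(back), names(ref$models))
  for (t in names(ref$models))
    expect_equal(back[[t]], ref$models[[t]])
})

test_that("representative model choice: longest isoform, ties by id", {
  a1 <- transcript_model("tA2", "gA", "c", "+", cbind(0L, 100L), 10L, 70L)
  a2 <- transcript_model("tA1", "gA", "c", "+", cbind(0L, 200L), 10L, 70L)
  b1 <- transcript_model("tB2", "gB", "c", "+", cbind(300L, 400L), 10L, 70L)
  b2 <- transcript_model("tB1", "gB", "c", "+", cbind(300L, 400L), 10L, 70L)
  reps <- representative_models(list(tA2 = a1, tA1 = a2, tB2 = b1, tB1 = b2))
  expect_setequal(names(reps), c("tA1", "tB1"))
})

test_that("model invariants are enforced at construction", {
  expect_error(transcript_model("t", "g", "c", "+", cbind(0L, 100L),
                                10L, 60L), "divisible by 3")
  expect_error(transcript_model("t", "g", "c", "+", cbind(0L, 100L),
                                50L, 20L), "out of range")
  expect_error(transcript_model("t", "g", "c", "+",
                                rbind(c(0L, 60L), c(50L, 100L)), 0L, 30L),
               "overlapping")
})
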
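test_that("5' end extraction follows the first-nucleotide convention", {
  aln <- data.frame(read_id = c("p", "m", "d1", "d2"),
                    reference = "c",
                    pos0 = c(100L, 100L, 7L, 7L),
                    strand = c("+", "-", "+", "+"),
                    mapq = 60L, read_len = 50L, stringsAsFactors = FALSE)
  ends <- extract_five_prime_ends(aln)
  expect_equal(ends$pos[ends$strand == "+" & ends$pos != 7L], 100L)
  expect_equal(ends$pos[ends$strand == "-"], 149L)
  # two identical plus reads aggregate to one end with count 2
  expect_equal(ends$count[ends$pos == 7L], 2L)
  expect_equal(sum(ends$count), nrow(aln))  # conservation
  # lengths can come from a named per-read vector instead of the table
  aln$read_len <- NULL
  ends2 <- extract_five_prime_ends(aln, read_lengths = setNames(
    rep(50L, 4L), aln$read_id))
  expect_equal(ends2, ends)
  expect_error(extract_five_prime_ends(aln), "lengths")
})

test_that("union-mode assignment at single-nucleotide resolution", {
  # gene A exon [0,100), gene B exon [50,150): positions 50..99 ambiguous
  a <- transcript_model("tA", "gA", "c", "+", cbind(0L, 100L), 10L, 70L)
  b <- transcript_model("tB", "gB", "c", "+", cbind(50L, 150L), 10L, 70L)
  ends <- ends_table("c", c(10L, 60L, 120L, 500L), "+", c(2L, 3L, 1L, 4L))
  tab <- assign_to_transcripts(ends, list(tA = a, tB = b))
  expect_equal(tab$raw_count[tab$transcript_id == "tA"], 2L)
  expect_equal(tab$raw_count[tab$transcript_id == "tB"], 1L)
  expect_equal(attr(tab, "n_ambiguous"), 3L)
  expect_equal(attr(tab, "n_intergenic"), 4L)
  # conservation: assigned + ambiguous + intergenic = total
  expect_equal(attr(tab, "n_assigned") + attr(tab, "n_ambiguous") +
                 attr(tab, "n_intergenic"), sum(ends$count))
  # RPM identity against the pre-assignment library total
  expect_equal(tab$rpm, tab$raw_count / sum(ends$count) * 1e6)
  # strand-matched only: a minus-strand end in gene A is not counted
  ends_m <- ends_table("c", 10L, "-", 5L)
  tab_m <- assign_to_transcripts(ends_m, list(tA = a, tB = b))
  expect_equal(sum(tab_m$raw_count), 0L)
  expect_equal(attr(tab_m, "n_intergenic"), 5L)
})

test_that("per-transcript counts equal ground truth on non-overlapping genes", {
  p <- small_params()
  ref <- build_toy_reference(p)
  tr <- sample_fiveprime_ends(p, ref$models)
  ends <- truth_to_ends(tr, p$read_length)
  tab <- assign_to_transcripts(ends, ref$models)
  truth_counts <- table(tr$transcript_id)
  for (t in names(truth_counts))
    expect_equal(tab$raw_count[tab$transcript_id == t],
                 as.integer(truth_counts[[t]]))
  expect_equal(attr(tab, "n_ambiguous"), 0L)
  # sum of rpm over assigned transcripts <= 1e6, equality iff no losses
  expect_equal(sum(tab$rpm), 1e6 * attr(tab, "n_assigned") /
                 attr(tab, "library_total"))
})

test_that("detection threshold is a strict inequality at RPM 5", {
  tab <- structure(data.frame(
    transcript_id = c("t49", "t50", "t51"), gene_id = c("g1", "g2", "g3"),
    raw_count = c(49L, 50L, 51L), rpm = c(4.9, 5.0, 5.1),
    stringsAsFactors = FALSE), class = c("count_table", "data.frame"))
  expect_equal(detected_set(tab, 5), "t51")
  expect_equal(detected_set(tab, 0), c("t49", "t50", "t51"))
  tab$rpm <- c(0, 0, 0)
  expect_length(detected_set(tab, 5), 0L)
})

test_that("replicate comparison: identity, disjoint and simulated cases", {
  p <- small_params()
  ref <- build_toy_reference(p)
  tr <- sample_fiveprime_ends(p, ref$models, abundance = ref$abundance)
  tab <- assign_to_transcripts(truth_to_ends(tr, p$read_length), ref$models)
  self <- compare_replicates(tab, tab)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$a_only, 0L)
  expect_equal(self$b_only, 0L)
  # two replicates = same reference and expression, different read seeds
  p2 <- decay_params(n_transcripts = 20L, total_reads = 20000L, seed = 99L)
  tr2 <- sample_fiveprime_ends(p2, ref$models, abundance = ref$abundance)
  tab2 <- assign_to_transcripts(truth_to_ends(tr2, p$read_length),
                                ref$models)
  cmp <- compare_replicates(tab, tab2)
  expect_gt(cmp$common, 5 * max(cmp$a_only, cmp$b_only, 1L))
  expect_gt(cmp$pearson_r, 0.9)
  # disjoint detected sets
  ta <- structure(data.frame(transcript_id = c("x", "y"), gene_id = "g",
                             raw_count = c(10L, 0L), rpm = c(10, 0)),
                  class = c("count_table", "data.frame"))
  tb <- structure(data.frame(transcript_id = c("x", "y"), gene_id = "g",
                             raw_count = c(0L, 10L), rpm = c(0, 10)),
                  class = c("count_table", "data.frame"))
  expect_equal(compare_replicates(ta, tb)$common, 0L)
})

test_that("ends BED round trip preserves positions, strands and counts", {
  ends <- ends_table(c("c1", "c1", "c2"), c(0L, 99L, 5L),
                     c("+", "-", "+"), c(1L, 7L, 2L))
  bed <- tempfile(fileext = ".bed")
  write_ends_bed(ends, bed)
  back <- read_ends_bed(bed)
  back <- back[order(back$reference, back$pos, back$strand), ]
  rownames(back) <- NULL
  expect_equal(back, ends)
})
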
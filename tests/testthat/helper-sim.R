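# shared fixtures, all built in code

# single-exon model: exon [g0, g0 + len) with a CDS placed inside
toy_model <- function(tid = "T1", gid = tid, strand = "+", g0 = 100L,
                      utr5 = 60L, cds = 300L, utr3 = 90L, ref = "chr1") {
  transcript_model(tid, gid, ref, strand,
                   exons = cbind(g0, g0 + utr5 + cds + utr3),
                   cds_start_t = utr5, cds_stop_t = utr5 + cds - 3L)
}

# ends table from explicit vectors
ends_table <- function(reference, pos, strand, count = 1L) {
  structure(data.frame(reference = rep(reference, length.out = length(pos)),
                       pos = as.integer(pos),
                       strand = rep(strand, length.out = length(pos)),
                       count = as.integer(rep(count, length.out = length(pos))),
                       stringsAsFactors = FALSE),
            class = c("five_prime_ends", "data.frame"))
}

# ends on the spliced transcript, given transcript positions
ends_at_tpos <- function(model, tpos, count = 1L) {
  ends_table(model$reference, transcript_to_genomic(model, tpos),
             model$strand, count)
}

# small simulation preset
small_params <- function(...) {
  decay_params(n_transcripts = 20L, total_reads = 20000L, seed = 11L, ...)
}

# aggregate ground truth into a five_prime_ends table through the
# extraction module (exercises the minus-strand 5'-end arithmetic)
truth_to_ends <- function(truth, read_length) {
  len <- pmin(read_length, 10000L)
  aln <- data.frame(read_id = truth$read_id, reference = truth$reference,
                    pos0 = ifelse(truth$strand == "+", truth$gpos,
                                  truth$gpos - (read_length - 1L)),
                    strand = truth$strand, mapq = 60L,
                    read_len = read_length, stringsAsFactors = FALSE)
  extract_five_prime_ends(aln)
}

# minimal GTF writer for hand-built test cases (1-based closed coords)
write_test_gtf <- function(path, rows) {
  lines <- vapply(rows, function(r)
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            r$chr, r$type, r$start, r$end, r$strand, r$gene, r$tx), "")
  writeLines(lines, path)
  path
}
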
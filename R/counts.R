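#' Collapse alignments to single-nucleotide 5'P ends
#'
#' The degradome measurement is the position of the 5'-most nucleotide of
#' each read: for a plus-strand read the leftmost aligned position, for a
#' minus-strand read spanning `[pos0, pos0 + L)` the position `pos0 + L - 1`.
#' Identical (reference, position, strand) triples are aggregated with
#' summed multiplicity; total count is conserved.
#'
#' @param alignments data.frame from [load_alignments()].
#' @param read_lengths per-read aligned lengths when the `read_len` column
#'   is absent or NA: either a single value or a named vector indexed by
#'   `read_id`.
#' @return data.frame of class `five_prime_ends` with columns `reference`,
#'   `pos`, `strand`, `count`.
#' @export
extract_five_prime_ends <- function(alignments, read_lengths = NULL) {
  if (nrow(alignments) == 0L)
    return(structure(data.frame(reference = character(0), pos = integer(0),
                                strand = character(0), count = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("five_prime_ends", "data.frame")))
  len <- alignments$read_len
  if (is.null(len)) len <- rep(NA_integer_, nrow(alignments))
  if (!is.null(read_lengths)) {
    fill <- if (length(read_lengths) == 1L && is.null(names(read_lengths)))
      rep(read_lengths, nrow(alignments))
    else unname(read_lengths[alignments$read_id])
    len <- ifelse(is.na(len), fill, len)
  }
  minus <- alignments$strand == "-"
  if (any(minus & is.na(len)))
    stop("minus-strand alignments need read lengths to locate the 5' end")
  pos <- ifelse(minus, alignments$pos0 + as.integer(len) - 1L,
                alignments$pos0)
  key <- paste(alignments$reference, pos, alignments$strand, sep = "\r")
  agg <- rowsum(rep(1L, length(key)), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    reference = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)),
    strand = vapply(parts, `[[`, "", 3L),
    count = as.integer(agg[, 1L]), stringsAsFactors = FALSE)
  out <- out[order(out$reference, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("five_prime_ends", "data.frame"))
}

.ends_granges <- function(ends) {
  GenomicRanges::GRanges(ends$reference,
                         IRanges::IRanges(start = ends$pos + 1L, width = 1L),
                         strand = ends$strand)
}

.exons_granges <- function(models) {
  refs <- unlist(lapply(models, function(m) rep(m$reference,
                                               nrow(m$exons))))
  starts <- unlist(lapply(models, function(m) m$exons[, 1L]))
  ends_ <- unlist(lapply(models, function(m) m$exons[, 2L]))
  strands <- unlist(lapply(models, function(m) rep(m$strand,
                                                   nrow(m$exons))))
  gids <- unlist(lapply(models, function(m) rep(m$gene_id, nrow(m$exons))))
  tids <- unlist(lapply(models, function(m) rep(m$transcript_id,
                                                nrow(m$exons))))
  gr <- GenomicRanges::GRanges(refs,
                               IRanges::IRanges(start = starts + 1L,
                                                end = ends_),
                               strand = strands)
  gr$gene_id <- gids
  gr$transcript_id <- tids
  gr
}

#' Assign 5'P ends to transcripts and build the RPM count table
#'
#' Union-mode assignment at single-nucleotide resolution: an end is counted
#' for a gene iff its position is exonic in exactly one gene on the matching
#' strand; ends exonic in two or more genes are ambiguous and discarded;
#' ends in no gene are intergenic and discarded. Counts are conserved:
#' assigned + ambiguous + intergenic = total ends. RPM uses
#' `library_total` = the total number of uniquely mapped ends BEFORE
#' assignment (the total-mapped-reads denominator), so
#' `rpm = raw_count / library_total * 1e6`.
#'
#' @param ends a `five_prime_ends` table from [extract_five_prime_ends()].
#' @param models named list of [transcript_model()] objects (one per gene;
#'   see [representative_models()]).
#' @return data.frame of class `count_table` with columns `transcript_id`,
#'   `gene_id`, `raw_count`, `rpm`; attributes `library_total`,
#'   `n_assigned`, `n_ambiguous`, `n_intergenic`.
#' @export
assign_to_transcripts <- function(ends, models) {
  library_total <- sum(ends$count)
  tids <- vapply(models, `[[`, "", "transcript_id")
  raw <- setNames(integer(length(models)), tids)
  n_amb <- 0L; n_int <- 0L
  if (nrow(ends) > 0L && length(models) > 0L) {
    egr <- .ends_granges(ends)
    xgr <- .exons_granges(models)
    hits <- GenomicRanges::findOverlaps(egr, xgr, ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(hits)
    gene_hit <- xgr$gene_id[S4Vectors::subjectHits(hits)]
    tx_hit <- xgr$transcript_id[S4Vectors::subjectHits(hits)]
    # distinct genes per end (an end can hit several exons of one gene)
    key <- paste(qh, gene_hit)
    first <- !duplicated(key)
    qh1 <- qh[first]; gene1 <- gene_hit[first]; tx1 <- tx_hit[first]
    ngenes <- tabulate(qh1, nbins = nrow(ends))
    uniq <- ngenes == 1L
    amb <- ngenes >= 2L
    n_amb <- sum(ends$count[amb])
    n_int <- sum(ends$count[ngenes == 0L])
    sel <- uniq[qh1]
    if (any(sel)) {
      add <- rowsum(ends$count[qh1[sel]], tx1[sel])
      raw[rownames(add)] <- raw[rownames(add)] + as.integer(add[, 1L])
    }
  } else {
    n_int <- library_total
  }
  out <- data.frame(transcript_id = tids,
                    gene_id = vapply(models, `[[`, "", "gene_id"),
                    raw_count = unname(raw),
                    rpm = if (library_total > 0)
                      unname(raw) / library_total * 1e6 else 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("count_table", "data.frame"),
            library_total = library_total,
            n_assigned = sum(raw), n_ambiguous = n_amb, n_intergenic = n_int)
}

#' Transcripts above the RPM detection threshold
#'
#' Applies the detection rule used for degradome transcript inventories:
#' a transcript is detected iff its RPM is STRICTLY greater than the
#' threshold (default 5).
#'
#' @param table a `count_table` from [assign_to_transcripts()].
#' @param rpm_threshold detection threshold (default 5).
#' @return character vector of detected transcript ids.
#' @export
detected_set <- function(table, rpm_threshold = 5) {
  table$transcript_id[table$rpm > rpm_threshold]
}

#' Compare two replicate count tables
#'
#' Pearson correlation of `log2(rpm + 1)` over the union of the two
#' detected sets (transcripts absent from one table contribute rpm 0), plus
#' the overlap partition of the union: common, a-only, b-only.
#'
#' @param a,b `count_table` objects.
#' @param rpm_threshold detection threshold applied to both tables.
#' @return list with `pearson_r` (NA when fewer than 3 transcripts enter
#'   the correlation), `common`, `a_only`, `b_only`, and the id sets.
#' @export
compare_replicates <- function(a, b, rpm_threshold = 5) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty count table")
  da <- detected_set(a, rpm_threshold)
  db <- detected_set(b, rpm_threshold)
  u <- union(da, db)
  rpm_a <- setNames(a$rpm, a$transcript_id)[u]
  rpm_b <- setNames(b$rpm, b$transcript_id)[u]
  rpm_a[is.na(rpm_a)] <- 0
  rpm_b[is.na(rpm_b)] <- 0
  r <- if (length(u) >= 3L) cor(log2(rpm_a + 1), log2(rpm_b + 1)) else NA_real_
  list(pearson_r = r,
       common = length(intersect(da, db)),
       a_only = length(setdiff(da, db)),
       b_only = length(setdiff(db, da)),
       common_ids = intersect(da, db),
       a_only_ids = setdiff(da, db), b_only_ids = setdiff(db, da),
       transform = "log2(rpm+1)")
}

#' Write 5'P ends as BED6
#'
#' Score column carries the end multiplicity.
#'
#' @param ends a `five_prime_ends` table.
#' @param path output path.
#' @export
write_ends_bed <- function(ends, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", ends$reference, ends$pos,
                     ends$pos + 1L, "5p_end", ends$count, ends$strand), path)
  invisible(path)
}

#' Read a 5'P end BED6 file (score = count)
#' @param path BED path as written by [write_ends_bed()].
#' @return a `five_prime_ends` table.
#' @export
read_ends_bed <- function(path) {
  if (file.size(path) == 0L)
    return(structure(data.frame(reference = character(0), pos = integer(0),
                                strand = character(0), count = integer(0)),
                     class = c("five_prime_ends", "data.frame")))
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(reference = as.character(GenomicRanges::seqnames(gr)),
                    pos = GenomicRanges::start(gr) - 1L,
                    strand = as.character(GenomicRanges::strand(gr)),
                    count = as.integer(gr$score), stringsAsFactors = FALSE)
  structure(out, class = c("five_prime_ends", "data.frame"))
}

#' Write a count table as TSV
#' @param table a `count_table`.
#' @param path output path.
#' @param rpm_threshold threshold for the `detected` column.
#' @export
write_count_table <- function(table, path, rpm_threshold = 5) {
  out <- table
  out$detected <- out$rpm > rpm_threshold
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
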
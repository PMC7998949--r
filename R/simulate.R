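#' Parameters of the synthetic co-translational decay model
#'
#' The generator emulates the 5'P end distribution left by 5'->3'
#' exoribonucleolytic decay of translating mRNAs: the exoribonuclease trails
#' the last ribosome codon by codon, so 5'P ends form a frame-anchored 3-nt
#' comb within the CDS, with an over-accumulation at a fixed distance
#' upstream of the stop codon where the terminating ribosome (A site on the
#' stop codon) shields the mRNA. A uniform component models ordinary decay
#' background unlinked to ribosome positions.
#'
#' @param n_transcripts number of toy transcripts.
#' @param utr5_len,cds_len,utr3_len segment lengths in nt; `cds_len`
#'   includes the stop codon and must be divisible by 3.
#' @param abundance_dispersion log-scale standard deviation of the
#'   per-transcript expression draw (log-normal).
#' @param p_periodic,p_term,p_background mixture weights of the
#'   frame-anchored comb, the termination pause, and the uniform background;
#'   must sum to 1.
#' @param term_offset distance in nt from the 5'P end of the termination
#'   pause to the first nucleotide of the stop codon (16 or 17 in
#'   Arabidopsis tissues; default 17).
#' @param frame_anchor phase (0, 1 or 2) of the comb relative to the start
#'   codon.
#' @param read_length sequenced read length in nt (default 75, single-read
#'   75-cycle chemistry).
#' @param total_reads number of reads to emit.
#' @param seed integer seed; every stochastic step derives from it.
#' @param p_contaminant optional mass of reads drawn from a contaminant
#'   reference (rRNA-like), used to exercise the contaminant filter;
#'   default 0.
#' @return a list of class `decay_params`.
#' @export
decay_params <- function(n_transcripts = 50L, utr5_len = 60L, cds_len = 300L,
                         utr3_len = 90L, abundance_dispersion = 0.5,
                         p_periodic = 0.55, p_term = 0.15,
                         p_background = 0.30, term_offset = 17L,
                         frame_anchor = 0L, read_length = 75L,
                         total_reads = 50000L, seed = 1L,
                         p_contaminant = 0) {
  w <- c(p_periodic, p_term, p_background)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("mixture weights must be non-negative and sum to 1")
  if (cds_len %% 3L != 0L) stop("cds_len must be divisible by 3")
  if (term_offset < 0L) stop("term_offset must be >= 0")
  if (read_length < 20L) stop("read_length must be >= 20")
  if (p_contaminant < 0 || p_contaminant >= 1)
    stop("p_contaminant must be in [0, 1)")
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    utr5_len = as.integer(utr5_len), cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len),
    abundance_dispersion = abundance_dispersion,
    p_periodic = p_periodic, p_term = p_term, p_background = p_background,
    term_offset = as.integer(term_offset),
    frame_anchor = as.integer(frame_anchor),
    read_length = as.integer(read_length),
    total_reads = as.integer(total_reads), seed = as.integer(seed),
    p_contaminant = p_contaminant), class = "decay_params")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a toy reference genome and annotation
#'
#' Places `n_transcripts` single-exon transcripts on one contig, separated
#' by >= 100 nt spacers, alternating strand (odd-numbered transcripts on
#' plus, even-numbered on minus). Each transcript carries an ATG at
#' `cds_start_t` and one of TAA/TAG/TGA at `cds_stop_t`. A separate
#' contaminant contig (`chrC_rRNA`, 2000 nt) is always emitted; it carries
#' no annotation and is the source of contaminant reads when
#' `p_contaminant > 0`.
#'
#' Deterministic: calling twice with the same `params$seed` yields identical
#' sequences and models.
#'
#' @param params a [decay_params()] object.
#' @return list with elements `genome` ([Biostrings::DNAStringSet]),
#'   `models` (named list of [transcript_model()]), and `contaminant_name`.
#' @export
build_toy_reference <- function(params) {
  set.seed(params$seed)
  spacer <- 100L
  tlen <- params$utr5_len + params$cds_len + params$utr3_len
  n <- params$n_transcripts
  stops <- sample(c("TAA", "TAG", "TGA"), n, replace = TRUE)
  contig_len <- spacer + n * (tlen + spacer)
  chrom <- strsplit(.rand_dna(contig_len), "")[[1L]]
  models <- vector("list", n)
  for (i in seq_len(n)) {
    g0 <- spacer + (i - 1L) * (tlen + spacer)       # exon start, 0-based
    strand <- if (i %% 2L == 1L) "+" else "-"
    tseq <- strsplit(.rand_dna(tlen), "")[[1L]]
    cds_start_t <- params$utr5_len
    cds_stop_t <- params$utr5_len + params$cds_len - 3L
    tseq[cds_start_t + 1:3] <- c("A", "T", "G")
    tseq[cds_stop_t + 1:3] <- strsplit(stops[i], "")[[1L]]
    placed <- if (strand == "+") tseq else
      rev(chartr("ACGT", "TGCA", tseq))
    chrom[(g0 + 1L):(g0 + tlen)] <- placed
    tid <- sprintf("TOY%04d", i)
    models[[i]] <- transcript_model(
      tid, gene_id = sprintf("G%04d", i), reference = "chrS1",
      strand = strand, exons = cbind(g0, g0 + tlen),
      cds_start_t = cds_start_t, cds_stop_t = cds_stop_t)
  }
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  genome <- Biostrings::DNAStringSet(c(
    chrS1 = paste(chrom, collapse = ""),
    chrC_rRNA = .rand_dna(2000L)))
  # expression is a property of the toy sample: replicate libraries of the
  # same reference share this profile and differ only in read sampling
  ab <- rlnorm(n, meanlog = 0, sdlog = params$abundance_dispersion)
  list(genome = genome, models = models, contaminant_name = "chrC_rRNA",
       abundance = setNames(ab / sum(ab), names(models)))
}

#' Sample ground-truth 5'P end positions
#'
#' Draws `total_reads` reads by a single multinomial over
#' (transcript, component, position) cells. Per transcript, expected read
#' count is proportional to a log-normal abundance draw; within a
#' transcript, the 5' end position comes from the mixture: the periodic
#' component is uniform over `cds_start_t + frame_anchor + 3k` restricted to
#' `[cds_start_t, cds_stop_t - term_offset)`; the termination component sits
#' at exactly `cds_stop_t - term_offset`; the background is uniform over
#' `[0, spliced_length - read_length]`. Each annotated site receives
#' `site_weight` of the TOTAL read mass (a global fraction, so deep spikes
#' stand out against the transcript's own coverage, as endonucleolytic
#' cleavage products do); the decay mixture is scaled down to the remaining
#' mass, as is the contaminant component when `p_contaminant > 0`.
#'
#' @param params a [decay_params()] object (uses `params$seed + 1` so the
#'   reference and the read draw are independently reproducible).
#' @param models transcript models from [build_toy_reference()].
#' @param sites optional [site_annotation()] table of single-position events.
#' @param site_weight probability mass per site (fraction of all reads).
#' @param abundance optional per-transcript expression weights (as returned
#'   by [build_toy_reference()]); replicate libraries pass the same vector
#'   with different seeds. Default: a fresh log-normal draw.
#' @return data.frame (ground truth), one row per read: `read_id`,
#'   `transcript_id`, `pos_t`, `component`
#'   (`periodic`/`term`/`background`/`site`/`contaminant`), `reference`,
#'   `gpos` (genomic position of the 5' nucleotide), `strand`.
#' @export
sample_fiveprime_ends <- function(params, models, sites = NULL,
                                  site_weight = 0.05, abundance = NULL) {
  set.seed(params$seed + 1L)
  n <- length(models)
  if (!is.null(sites) && nrow(sites) > 0L) {
    for (i in seq_len(nrow(sites))) {
      m <- models[[sites$transcript_id[i]]]
      if (is.null(m)) stop("site references unknown transcript: ",
                           sites$transcript_id[i])
      if (sites$position_t[i] < 0L || sites$position_t[i] >= m$spliced_len)
        stop("site position beyond transcript ", m$transcript_id)
    }
  }
  n_sites <- if (is.null(sites)) 0L else nrow(sites)
  site_mass <- n_sites * site_weight
  decay_mass <- 1 - site_mass - params$p_contaminant
  if (decay_mass < 0) stop("site and contaminant mass exceed 1")
  ab <- if (is.null(abundance))
    rlnorm(n, meanlog = 0, sdlog = params$abundance_dispersion)
  else {
    stopifnot(length(abundance) == n)
    as.numeric(abundance)
  }
  ab <- ab / sum(ab)

  cell_tid <- character(0); cell_pos <- integer(0)
  cell_comp <- character(0); cell_p <- numeric(0)
  add <- function(tid, pos, comp, p) {
    cell_tid <<- c(cell_tid, rep(tid, length(pos)))
    cell_pos <<- c(cell_pos, as.integer(pos))
    cell_comp <<- c(cell_comp, rep(comp, length(pos)))
    cell_p <<- c(cell_p, rep(p / length(pos), length(pos)))
  }
  for (i in seq_len(n)) {
    m <- models[[i]]
    mass <- decay_mass * ab[i]
    per_hi <- m$cds_stop_t - params$term_offset   # exclusive
    per_pos <- seq(m$cds_start_t + params$frame_anchor, by = 3L,
                   length.out = max(0L, (per_hi - 1L - m$cds_start_t -
                                           params$frame_anchor) %/% 3L + 1L))
    if (params$p_periodic > 0 && length(per_pos) > 0L)
      add(m$transcript_id, per_pos, "periodic", mass * params$p_periodic)
    if (params$p_term > 0) {
      tpos <- m$cds_stop_t - params$term_offset
      if (tpos < 0L) stop("term_offset larger than CDS end position")
      add(m$transcript_id, tpos, "term", mass * params$p_term)
    }
    if (params$p_background > 0) {
      bg_hi <- m$spliced_len - params$read_length
      add(m$transcript_id, 0L:max(0L, bg_hi), "background",
          mass * params$p_background)
    }
  }
  if (n_sites > 0L)
    for (i in seq_len(n_sites))
      add(sites$transcript_id[i], sites$position_t[i], "site", site_weight)
  if (params$p_contaminant > 0)
    add(".contaminant", 0L:(2000L - params$read_length), "contaminant",
        params$p_contaminant)

  counts <- as.vector(rmultinom(1L, params$total_reads, cell_p))
  idx <- rep.int(seq_along(counts), counts)
  tid <- cell_tid[idx]
  pos_t <- cell_pos[idx]
  comp <- cell_comp[idx]
  gpos <- integer(length(idx)); ref <- character(length(idx))
  strand <- character(length(idx))
  is_cont <- tid == ".contaminant"
  for (t in unique(tid[!is_cont])) {
    m <- models[[t]]
    sel <- tid == t
    gpos[sel] <- transcript_to_genomic(m, pos_t[sel])
    ref[sel] <- m$reference
    strand[sel] <- m$strand
  }
  if (any(is_cont)) {
    gpos[is_cont] <- pos_t[is_cont]
    ref[is_cont] <- "chrC_rRNA"
    strand[is_cont] <- "+"
    tid[is_cont] <- NA_character_
  }
  data.frame(read_id = sprintf("read%07d", seq_along(idx)),
             transcript_id = tid, pos_t = pos_t, component = comp,
             reference = ref, gpos = gpos, strand = strand,
             stringsAsFactors = FALSE)
}

#' Emit reads and alignments from ground truth
#'
#' Writes a FASTQ (read sequence = transcript sequence from the 5'P end for
#' `read_length` nt, truncated at the transcript 3' end; constant quality),
#' a BED6 file of true 5' end genomic positions (one record per read), and
#' an alignment TSV (`read_id reference pos0 strand mapq read_len`,
#' MAPQ 60) so the downstream pipeline can run without an external aligner.
#'
#' @param truth ground truth from [sample_fiveprime_ends()].
#' @param models transcript models.
#' @param genome the toy genome.
#' @param params the [decay_params()] used.
#' @param out_dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the three written paths
#'   (`fastq`, `bed`, `alignments`).
#' @export
emit_reads <- function(truth, models, genome, params, out_dir,
                       prefix = "sim") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(out_dir, paste0(prefix, ".fastq"))
  bed <- file.path(out_dir, paste0(prefix, "_true5p.bed"))
  aln <- file.path(out_dir, paste0(prefix, "_alignments.tsv"))
  L <- params$read_length
  nreads <- nrow(truth)
  if (nreads == 0L) {
    writeLines(character(0), fq)
    writeLines(character(0), bed)
    write.table(data.frame(read_id = character(0), reference = character(0),
                           pos0 = integer(0), strand = character(0),
                           mapq = integer(0), read_len = integer(0)),
                aln, sep = "\t", quote = FALSE, row.names = FALSE)
    return(c(fastq = fq, bed = bed, alignments = aln))
  }
  # source sequence per reference: spliced transcript or contaminant contig
  seqs <- character(nreads)
  src_key <- ifelse(is.na(truth$transcript_id), truth$reference,
                    truth$transcript_id)
  for (k in unique(src_key)) {
    s <- if (!is.null(models[[k]])) spliced_seq(models[[k]], genome)
         else as.character(genome[[k]])
    sel <- src_key == k
    seqs[sel] <- substr(rep(s, sum(sel)), truth$pos_t[sel] + 1L,
                        truth$pos_t[sel] + L)
  }
  rl <- nchar(seqs)
  fq_lines <- character(4L * nreads)
  fq_lines[seq(1L, by = 4L, length.out = nreads)] <- paste0("@", truth$read_id)
  fq_lines[seq(2L, by = 4L, length.out = nreads)] <- seqs
  fq_lines[seq(3L, by = 4L, length.out = nreads)] <- "+"
  fq_lines[seq(4L, by = 4L, length.out = nreads)] <- strrep("I", rl)
  writeLines(fq_lines, fq)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", truth$reference, truth$gpos,
                     truth$gpos + 1L, truth$read_id, truth$strand), bed)
  pos0 <- ifelse(truth$strand == "+", truth$gpos, truth$gpos - (rl - 1L))
  write.table(data.frame(read_id = truth$read_id,
                         reference = truth$reference, pos0 = pos0,
                         strand = truth$strand, mapq = 60L, read_len = rl,
                         stringsAsFactors = FALSE),
              aln, sep = "\t", quote = FALSE, row.names = FALSE)
  c(fastq = fq, bed = bed, alignments = aln)
}

#' Run the full synthetic degradome generator
#'
#' Convenience wrapper: [build_toy_reference()], [sample_fiveprime_ends()],
#' [emit_reads()], plus FASTA/GTF/ground-truth/params files, all under one
#' output directory.
#'
#' @inheritParams sample_fiveprime_ends
#' @inheritParams emit_reads
#' @return list with `params`, `genome`, `models`, `truth`, `sites`, and
#'   `files` (named vector of all written paths).
#' @export
simulate_degradome <- function(params, out_dir, sites = NULL,
                               site_weight = 0.05, prefix = "sim") {
  ref <- build_toy_reference(params)
  truth <- sample_fiveprime_ends(params, ref$models, sites = sites,
                                 site_weight = site_weight,
                                 abundance = ref$abundance)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- emit_reads(truth, ref$models, ref$genome, params, out_dir,
                      prefix = prefix)
  fa <- file.path(out_dir, paste0(prefix, "_genome.fa"))
  gtf <- file.path(out_dir, paste0(prefix, ".gtf"))
  tru <- file.path(out_dir, paste0(prefix, "_truth.tsv"))
  pj <- file.path(out_dir, paste0(prefix, "_params.json"))
  write_genome(ref$genome, fa)
  write_annotation(ref$models, gtf)
  write.table(truth, tru, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(params), pj, auto_unbox = TRUE, digits = NA)
  files <- c(files, genome = fa, gtf = gtf, truth = tru, params = pj)
  list(params = params, genome = ref$genome, models = ref$models,
       truth = truth, sites = sites, files = files)
}
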
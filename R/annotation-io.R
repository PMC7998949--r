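#' @importFrom stats fft median rlnorm rmultinom runif cor setNames
#' @importFrom utils read.delim write.table head
NULL

# Internal coordinate convention, used everywhere in this package:
#   genomic and transcript coordinates are 0-based; intervals half-open.
#   GTF I/O converts from/to 1-based closed; BED I/O is 0-based half-open.

#' Construct a transcript model
#'
#' A `TranscriptModel` describes one spliced transcript: its exon structure
#' on the genome, its strand, and the transcript-coordinate positions of the
#' start codon and of the first nucleotide of the stop codon. All coordinate
#' conversion between genome and spliced transcript goes through this object.
#'
#' Transcript coordinates run 5' to 3' along the mature transcript: position
#' 0 is the genomic 5'-most exon base on the plus strand and the genomic
#' 3'-most exon base on the minus strand. `cds_stop_t` points at the FIRST
#' nucleotide of the stop codon; the stop codon itself is not part of
#' `[cds_start_t, cds_stop_t)`, so "17 nt before the stop codon" is
#' transcript position `cds_stop_t - 17`.
#'
#' @param transcript_id,gene_id identifiers.
#' @param reference name of the reference sequence the exons live on.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of genomic intervals (0-based half-open),
#'   non-overlapping, sorted by genomic coordinate.
#' @param cds_start_t transcript coordinate of the first nucleotide of the
#'   start codon.
#' @param cds_stop_t transcript coordinate of the first nucleotide of the
#'   stop codon.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, reference, strand,
                             exons, cds_start_t, cds_stop_t) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("transcript ", transcript_id, ": no exons")
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript ", transcript_id, ": empty or inverted exon")
  if (is.unsorted(exons[, 1L], strictly = TRUE) && nrow(exons) > 1L)
    stop("transcript ", transcript_id, ": exons not sorted")
  if (nrow(exons) > 1L && any(exons[-nrow(exons), 2L] > exons[-1L, 1L]))
    stop("transcript ", transcript_id, ": overlapping exons")
  spliced_len <- sum(exons[, 2L] - exons[, 1L])
  cds_start_t <- as.integer(cds_start_t)
  cds_stop_t <- as.integer(cds_stop_t)
  if (!(cds_start_t >= 0L && cds_start_t < cds_stop_t &&
        cds_stop_t < spliced_len))
    stop("transcript ", transcript_id, ": CDS coordinates out of range")
  if ((cds_stop_t - cds_start_t) %% 3L != 0L)
    stop("transcript ", transcript_id, ": CDS length not divisible by 3")
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         reference = reference, strand = strand, exons = exons,
         cds_start_t = cds_start_t, cds_stop_t = cds_stop_t,
         spliced_len = as.integer(spliced_len)),
    class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf(
    "TranscriptModel %s (gene %s) %s:%s strand %s\n  %d exon(s), spliced length %d, CDS [%d,%d) + stop codon\n",
    x$transcript_id, x$gene_id, x$reference,
    paste0(x$exons[1, 1], "-", x$exons[nrow(x$exons), 2]),
    x$strand, nrow(x$exons), x$spliced_len, x$cds_start_t, x$cds_stop_t))
  invisible(x)
}

#' Spliced length of a transcript model
#' @param model a [transcript_model()].
#' @return integer spliced length (sum of exon lengths).
#' @export
spliced_length <- function(model) model$spliced_len

# cumulative spliced offset before each exon, in genomic order
.exon_cum <- function(model) {
  lens <- model$exons[, 2L] - model$exons[, 1L]
  cumsum(c(0L, lens[-length(lens)]))
}

#' Convert genomic positions to transcript coordinates
#'
#' Strand-aware, splice-aware conversion. Positions falling outside every
#' exon map to `NA`.
#'
#' @param model a [transcript_model()].
#' @param gpos integer vector of genomic positions (0-based).
#' @return integer vector of transcript positions (0-based), `NA` where the
#'   genomic position is not exonic.
#' @export
genomic_to_transcript <- function(model, gpos) {
  gpos <- as.integer(gpos)
  cum <- .exon_cum(model)
  ex <- model$exons
  idx <- findInterval(gpos, ex[, 1L])
  ok <- idx >= 1L & gpos < ex[pmax(idx, 1L), 2L]
  plus_t <- rep(NA_integer_, length(gpos))
  plus_t[ok] <- cum[idx[ok]] + (gpos[ok] - ex[idx[ok], 1L])
  if (model$strand == "+") plus_t
  else ifelse(is.na(plus_t), NA_integer_,
              model$spliced_len - 1L - plus_t)
}

#' Convert transcript coordinates to genomic positions
#'
#' Inverse of [genomic_to_transcript()]; the round trip is the identity on
#' every exonic position.
#'
#' @param model a [transcript_model()].
#' @param tpos integer vector of transcript positions (0-based).
#' @return integer vector of genomic positions, `NA` where `tpos` is outside
#'   `[0, spliced_length)`.
#' @export
transcript_to_genomic <- function(model, tpos) {
  tpos <- as.integer(tpos)
  out_of_range <- tpos < 0L | tpos >= model$spliced_len
  q <- if (model$strand == "+") tpos else model$spliced_len - 1L - tpos
  cum <- .exon_cum(model)
  ex <- model$exons
  idx <- findInterval(q, cum)
  g <- ex[pmax(idx, 1L), 1L] + (q - cum[pmax(idx, 1L)])
  g[out_of_range] <- NA_integer_
  as.integer(g)
}

#' Read a genome FASTA file
#'
#' @param path path to a (multi-record) FASTA file.
#' @return a [Biostrings::DNAStringSet] with uppercased sequences; `N` is
#'   allowed, any other non-ACGTN letter is an error.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 100L)
  first <- which(nzchar(trimws(lines)))
  if (length(first) && !startsWith(trimws(lines[first[1L]]), ">"))
    stop("malformed FASTA at line ", first[1L], " of ", path,
         ": expected '>' header")
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) return(seqs)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  # keep only the first word of each header as the reference name
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bad <- Biostrings::letterFrequency(seqs, letters = "ACGTN", OR = 0)
  if (any(rowSums(bad) != Biostrings::width(seqs)))
    stop("FASTA record with letters outside {A,C,G,T,N}: ",
         names(seqs)[which(rowSums(bad) != Biostrings::width(seqs))[1L]])
  if (any(Biostrings::width(seqs) == 0L))
    stop("FASTA record with empty sequence")
  seqs
}

#' Write a genome FASTA file
#' @param seqs a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_genome <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Parses `exon`, `CDS` and `stop_codon` features (GTF 1-based closed
#' coordinates) into [transcript_model()] objects with internal 0-based
#' half-open coordinates. Transcripts violating the model invariants --
#' CDS length not divisible by 3, missing stop codon, stop codon not
#' immediately downstream of the CDS -- are skipped with a warning, not
#' fatal, as real annotations contain partial models.
#'
#' @param path path to a GTF file with `transcript_id` and `gene_id`
#'   attributes on each feature.
#' @return named list of `TranscriptModel` objects (names = transcript_id).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- as.character(gr$type) %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]
  if (length(gr) == 0L) return(list())
  tid <- as.character(gr$transcript_id)
  models <- list()
  for (t in unique(tid)) {
    sub <- gr[tid == t]
    m <- tryCatch(.model_from_features(t, sub), error = function(e) {
      warning("skipping transcript ", t, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(m)) models[[t]] <- m
  }
  models
}

.model_from_features <- function(t, sub) {
  type <- as.character(sub$type)
  ex <- sub[type == "exon"]
  if (length(ex) == 0L) stop("no exon features")
  strand <- as.character(GenomicRanges::strand(ex))[1L]
  if (!strand %in% c("+", "-")) stop("unstranded transcript")
  refname <- as.character(GenomicRanges::seqnames(ex))[1L]
  o <- order(GenomicRanges::start(ex))
  exons <- cbind(GenomicRanges::start(ex)[o] - 1L, GenomicRanges::end(ex)[o])
  cds <- sub[type == "CDS"]
  stopc <- sub[type == "stop_codon"]
  if (length(cds) == 0L) stop("no CDS features")
  if (length(stopc) == 0L) stop("missing stop codon")
  gid <- as.character(ex$gene_id)[1L]
  model0 <- transcript_model_nocds(t, gid, refname, strand, exons)
  cds_t <- .span_tpos(model0, cds)
  stop_t <- .span_tpos(model0, stopc)
  if (anyNA(cds_t) || anyNA(stop_t))
    stop("CDS or stop codon outside exons")
  cds_start_t <- min(cds_t)
  cds_stop_t <- min(stop_t)
  if (max(stop_t) - min(stop_t) != 2L || length(stop_t) != 3L)
    stop("stop codon is not 3 contiguous transcript positions")
  # tolerate annotations that include the stop codon inside the CDS feature
  if (max(cds_t) == max(stop_t)) cds_end <- cds_stop_t else
    cds_end <- max(cds_t) + 1L
  if (cds_end != cds_stop_t)
    stop("stop codon not contiguous with CDS")
  transcript_model(t, gid, refname, strand, exons, cds_start_t, cds_stop_t)
}

# transcript coordinates of every genomic base covered by a GRanges
.span_tpos <- function(model, gr) {
  gpos <- unlist(lapply(seq_along(gr), function(i)
    seq(GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i] - 1L)))
  genomic_to_transcript(model, gpos)
}

# exon-only model used internally before the CDS is known
transcript_model_nocds <- function(transcript_id, gene_id, reference, strand,
                                   exons) {
  spliced_len <- sum(exons[, 2L] - exons[, 1L])
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         reference = reference, strand = strand, exons = exons,
         cds_start_t = NA_integer_, cds_stop_t = NA_integer_,
         spliced_len = as.integer(spliced_len)),
    class = "TranscriptModel")
}

#' Write transcript models to a GTF file
#'
#' Emits `exon`, `CDS`, `start_codon` and `stop_codon` features in GTF
#' 1-based closed coordinates. The CDS feature excludes the stop codon
#' (GTF2.2 convention). [read_annotation()] on the output reproduces the
#' input models exactly.
#'
#' @param models list of [transcript_model()] objects.
#' @param path output path.
#' @export
write_annotation <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     m$gene_id, m$transcript_id)
    row <- function(feature, g1, g2) {
      sprintf("%s\tdegradomeQC\t%s\t%d\t%d\t.\t%s\t.\t%s",
              m$reference, feature, g1 + 1L, g2, m$strand, attrs)
    }
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines, row("exon", m$exons[i, 1L], m$exons[i, 2L]))
    # genomic spans of CDS (excl. stop) and codons, via transcript coords
    tmap <- function(t1, t2) { # transcript-coordinate closed range -> rows
      g <- transcript_to_genomic(m, seq(t1, t2))
      g <- sort(g)
      brk <- c(0L, which(diff(g) != 1L), length(g))
      vapply(seq_len(length(brk) - 1L), function(j) {
        seg <- g[(brk[j] + 1L):brk[j + 1L]]
        c(min(seg), max(seg) + 1L)
      }, integer(2))
    }
    for (seg in list(list("CDS", m$cds_start_t, m$cds_stop_t - 1L),
                     list("start_codon", m$cds_start_t, m$cds_start_t + 2L),
                     list("stop_codon", m$cds_stop_t, m$cds_stop_t + 2L))) {
      segs <- tmap(seg[[2L]], seg[[3L]])
      for (j in seq_len(ncol(segs)))
        lines <- c(lines, row(seg[[1L]], segs[1L, j], segs[2L, j]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Pick one representative transcript model per gene
#'
#' When several isoforms share a `gene_id`, metagene anchoring needs a single
#' stop codon per gene: the longest spliced transcript is kept, ties broken
#' lexicographically by `transcript_id`.
#'
#' @param models list of [transcript_model()] objects.
#' @return named list with one model per gene.
#' @export
representative_models <- function(models) {
  if (length(models) == 0L) return(models)
  gid <- vapply(models, `[[`, "", "gene_id")
  len <- vapply(models, `[[`, 0L, "spliced_len")
  tid <- vapply(models, `[[`, "", "transcript_id")
  o <- order(gid, -len, tid)
  keep <- o[!duplicated(gid[o])]
  models[sort(names(models)[keep])]
}

#' Spliced transcript sequence
#'
#' @param model a [transcript_model()].
#' @param genome a [Biostrings::DNAStringSet] (as from [read_genome()]).
#' @return character scalar: the mature transcript sequence, 5' to 3'.
#' @export
spliced_seq <- function(model, genome) {
  if (!model$reference %in% names(genome))
    stop("reference ", model$reference, " not in genome")
  chrom <- genome[[model$reference]]
  parts <- lapply(seq_len(nrow(model$exons)), function(i)
    Biostrings::subseq(chrom, model$exons[i, 1L] + 1L, model$exons[i, 2L]))
  s <- do.call(Biostrings::xscat, parts)
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Site annotations (uORF stalls / miRNA cleavage sites)
#'
#' @param transcript_id,position_t,kind,label vectors of equal length;
#'   `position_t` is the transcript coordinate of the 5'P accumulation,
#'   `kind` is one of `"uorf_stall"`, `"mirna_cleavage"`.
#' @return data.frame with class `site_annotation`.
#' @export
site_annotation <- function(transcript_id, position_t, kind,
                            label = transcript_id) {
  stopifnot(all(kind %in% c("uorf_stall", "mirna_cleavage")))
  out <- data.frame(transcript_id = as.character(transcript_id),
                    position_t = as.integer(position_t),
                    kind = as.character(kind),
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  class(out) <- c("site_annotation", "data.frame")
  out
}

#' Export site annotations as BED6 (genomic coordinates)
#'
#' The BED name column is `kind:label`.
#'
#' @param sites a [site_annotation()] table.
#' @param models transcript models used to map transcript to genomic
#'   coordinates.
#' @param path output path.
#' @export
write_sites_bed <- function(sites, models, path) {
  if (nrow(sites) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gpos <- integer(nrow(sites))
  ref <- character(nrow(sites))
  strand <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    m <- models[[sites$transcript_id[i]]]
    if (is.null(m)) stop("unknown transcript: ", sites$transcript_id[i])
    if (sites$position_t[i] >= m$spliced_len)
      stop("site position beyond transcript ", m$transcript_id)
    gpos[i] <- transcript_to_genomic(m, sites$position_t[i])
    ref[i] <- m$reference
    strand[i] <- m$strand
  }
  gr <- GenomicRanges::GRanges(
    ref, IRanges::IRanges(start = gpos + 1L, width = 1L), strand = strand,
    name = paste0(sites$kind, ":", sites$label), score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
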
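#' Read a FASTQ file
#'
#' @param path FASTQ path (4-line records, uncompressed or gzip).
#' @return data.frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTQ file
#' @param reads data.frame with `read_id`, `seq`, `qual`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Trim reads to a fixed length
#'
#' Truncates sequences (and qualities identically) to `max_len` nt from the
#' 3' end only: the 5' nucleotide is the 5'P measurement itself and must
#' never be clipped. Reads already at or below `max_len` pass unchanged;
#' read count is conserved. Idempotent.
#'
#' @param reads data.frame with `read_id`, `seq`, `qual`.
#' @param max_len maximum read length in nt (default 50).
#' @return data.frame of the same shape.
#' @export
trim_to_length <- function(reads, max_len = 50L) {
  stopifnot(max_len >= 1L)
  reads$seq <- substr(reads$seq, 1L, max_len)
  reads$qual <- substr(reads$qual, 1L, max_len)
  reads
}

#' Remove contaminant-derived reads
#'
#' A read is removed iff its first `k` nucleotides occur as an exact
#' substring of any contaminant sequence or its reverse complement. This is
#' a deterministic subtraction contract standing in for a local-alignment
#' screen against chloroplast, mitochondrial, rRNA and small-RNA references;
#' pre-screened input is equally accepted (pass an empty contaminant set).
#'
#' @param reads data.frame with `read_id`, `seq`, `qual`.
#' @param contaminant_seqs a [Biostrings::DNAStringSet] of contaminant
#'   references (may be empty).
#' @param k prefix seed length in nt (default 20); must not exceed the
#'   shortest read.
#' @return the surviving reads, with attribute `n_removed`.
#' @export
filter_contaminants <- function(reads, contaminant_seqs, k = 20L) {
  if (nrow(reads) == 0L || length(contaminant_seqs) == 0L) {
    attr(reads, "n_removed") <- 0L
    return(reads)
  }
  if (any(nchar(reads$seq) < k))
    stop("k = ", k, " exceeds the shortest read length")
  kmers <- unlist(lapply(as.character(contaminant_seqs), function(s) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    c(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)),
      substring(rc, 1:(nchar(rc) - k + 1L), k:nchar(rc)))
  }), use.names = FALSE)
  hit <- substr(reads$seq, 1L, k) %in% kmers
  out <- reads[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Load alignments with the unique-mapping filter
#'
#' Reads a BAM file (unmapped, secondary and supplementary records are
#' dropped first) or the package's alignment TSV dialect
#' (`read_id reference pos0 strand mapq [read_len]`, header line, 0-based
#' leftmost positions), then drops records with MAPQ strictly below
#' `mapq_min` -- the samtools `-q` semantics, so MAPQ 10 passes at the
#' default threshold 10. The number of dropped records is reported via
#' `message()` and the `n_mapq_dropped` attribute.
#'
#' @param path a `.bam` file or a `.tsv`/`.txt` alignment table.
#' @param mapq_min minimum mapping quality kept (default 10).
#' @return data.frame with columns `read_id`, `reference`, `pos0`, `strand`,
#'   `mapq`, `read_len` (aligned query length; from BAM qwidth, or the TSV
#'   column when present, otherwise `NA`).
#' @export
load_alignments <- function(path, mapq_min = 10L) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") {
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    p <- Rsamtools::ScanBamParam(
      flag = flag, what = c("qname", "rname", "pos", "strand", "mapq",
                            "qwidth"))
    b <- Rsamtools::scanBam(path, param = p)[[1L]]
    aln <- data.frame(read_id = b$qname,
                      reference = as.character(b$rname),
                      pos0 = b$pos - 1L,
                      strand = as.character(b$strand),
                      mapq = b$mapq, read_len = b$qwidth,
                      stringsAsFactors = FALSE)
  } else if (ext %in% c("tsv", "txt")) {
    aln <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("read_id", "reference", "pos0", "strand", "mapq")
    if (!all(need %in% names(aln)))
      stop("alignment TSV must have columns: ", paste(need, collapse = " "))
    if (!"read_len" %in% names(aln)) aln$read_len <- NA_integer_
    aln <- aln[, c(need, "read_len")]
  } else {
    stop("unknown alignment format '", ext,
         "': expected .bam or .tsv/.txt alignment table")
  }
  drop <- aln$mapq < mapq_min
  if (any(drop))
    message(sum(drop), " alignment(s) dropped with MAPQ < ", mapq_min)
  out <- aln[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_mapq_dropped") <- sum(drop)
  out
}
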
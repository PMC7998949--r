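# per-transcript table of (pos_t, count) for ends falling in the model's
# exons on the matching strand
.ends_on_transcript <- function(ends, model) {
  sel <- ends$reference == model$reference & ends$strand == model$strand
  if (!any(sel)) return(data.frame(pos_t = integer(0), count = integer(0)))
  sub <- ends[sel, , drop = FALSE]
  tpos <- genomic_to_transcript(model, sub$pos)
  keep <- !is.na(tpos)
  data.frame(pos_t = tpos[keep], count = sub$count[keep])
}

#' Call single-position 5'P accumulation peaks
#'
#' Detects sharp per-nucleotide spikes -- uORF ribosome stalls in 5'UTRs
#' and miRNA cleavage sites -- as positions whose end count is at least
#' `min_count` reads AND at least `min_fold` times the transcript's own mean
#' per-position coverage (total ends / spliced length). Enrichment against
#' the transcript's own track makes calls depth-invariant; no p-value is
#' attached, both thresholds are reported with the calls. The universal
#' termination pause would be called on every well-expressed transcript, so
#' stop-relative offsets -18..-15 are masked by default.
#'
#' @param ends a `five_prime_ends` table.
#' @param models named list of [transcript_model()] objects.
#' @param min_count minimum read count at the position (default 10).
#' @param min_fold minimum fold enrichment over the transcript mean
#'   (default 20).
#' @param mask_term_window stop-relative offsets excluded from calling
#'   (default `c(-18L, -15L)`); `NULL` disables masking.
#' @return data.frame of class `peak_calls`, sorted by `fold_enrichment`
#'   descending: `transcript_id`, `position_t`, `count`, `fold_enrichment`,
#'   `region` (`5UTR`/`CDS`/`3UTR`; CDS includes the stop codon).
#' @export
call_peaks <- function(ends, models, min_count = 10L, min_fold = 20,
                       mask_term_window = c(-18L, -15L)) {
  stopifnot(min_count > 0L, min_fold > 0)
  out <- list()
  for (m in models) {
    te <- .ends_on_transcript(ends, m)
    if (nrow(te) == 0L) next
    total <- sum(te$count)
    mean_cov <- total / m$spliced_len
    hit <- te$count >= min_count & te$count >= min_fold * mean_cov
    if (!is.null(mask_term_window)) {
      off <- te$pos_t - m$cds_stop_t
      hit <- hit & !(off >= mask_term_window[1L] & off <= mask_term_window[2L])
    }
    if (!any(hit)) next
    pos <- te$pos_t[hit]
    region <- ifelse(pos < m$cds_start_t, "5UTR",
                     ifelse(pos < m$cds_stop_t + 3L, "CDS", "3UTR"))
    out[[m$transcript_id]] <- data.frame(
      transcript_id = m$transcript_id, position_t = pos,
      count = te$count[hit], fold_enrichment = te$count[hit] / mean_cov,
      region = region, stringsAsFactors = FALSE)
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(transcript_id = character(0), position_t = integer(0),
               count = integer(0), fold_enrichment = numeric(0),
               region = character(0), stringsAsFactors = FALSE)
  calls <- calls[order(-calls$fold_enrichment), , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("peak_calls", "data.frame"),
            min_count = min_count, min_fold = min_fold)
}

#' Score peak calls against annotated sites
#'
#' A truth site is hit iff a call exists on the same transcript within
#' `tolerance` nt of the annotated position. Recall = hit sites / all
#' sites; precision = calls matching some site / all calls.
#'
#' @param calls a `peak_calls` table.
#' @param truth_sites a [site_annotation()] table.
#' @param tolerance positional tolerance in nt (default 0: exact).
#' @return list: `recall`, `precision` (`NA` when there are no calls),
#'   `site_table` (per-site hit record).
#' @export
evaluate_recovery <- function(calls, truth_sites, tolerance = 0L) {
  n_sites <- nrow(truth_sites)
  hit <- logical(n_sites)
  nearest <- rep(NA_integer_, n_sites)
  matched_call <- rep(FALSE, nrow(calls))
  for (i in seq_len(n_sites)) {
    same <- calls$transcript_id == truth_sites$transcript_id[i]
    d <- abs(calls$position_t - truth_sites$position_t[i])
    ok <- same & d <= tolerance
    hit[i] <- any(ok)
    if (any(same)) nearest[i] <- min(d[same])
    matched_call <- matched_call | ok
  }
  list(recall = if (n_sites > 0L) mean(hit) else NA_real_,
       precision = if (nrow(calls) > 0L) mean(matched_call) else NA_real_,
       site_table = cbind(truth_sites,
                          data.frame(hit = hit, nearest_call_nt = nearest)))
}

#' Write peak calls as TSV (and optionally genomic BED6)
#' @param calls a `peak_calls` table.
#' @param path TSV output path.
#' @param models transcript models; when given, a BED6 with genomic
#'   coordinates is written alongside (`.bed` extension).
#' @export
write_peaks <- function(calls, path, models = NULL) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(models) && nrow(calls) > 0L) {
    g <- integer(nrow(calls)); ref <- character(nrow(calls))
    strand <- character(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      m <- models[[calls$transcript_id[i]]]
      g[i] <- transcript_to_genomic(m, calls$position_t[i])
      ref[i] <- m$reference; strand[i] <- m$strand
    }
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", ref, g, g + 1L,
                       paste0(calls$transcript_id, ":", calls$position_t),
                       calls$count, strand),
               sub("\\.tsv$", ".bed", path))
  }
  invisible(path)
}
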
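# named count vector keyed by reference\rpos\rstrand, for O(1) position lookup
.ends_lookup <- function(ends) {
  setNames(ends$count, paste(ends$reference, ends$pos, ends$strand,
                             sep = "\r"))
}

# counts at given transcript positions of one model (0 where absent)
.counts_at_tpos <- function(lookup, model, tpos) {
  g <- transcript_to_genomic(model, tpos)
  v <- lookup[paste(model$reference, g, model$strand, sep = "\r")]
  v[is.na(v)] <- 0L
  unname(v)
}

#' Build an anchor-centred 5'P metagene profile
#'
#' Pools per-transcript 5'P end counts in a fixed coordinate frame anchored
#' on the first nucleotide of the stop (or start) codon, binned at 1 nt.
#' Offset 0 is the first nucleotide of the anchor codon; negative offsets
#' are upstream, so the termination pause of co-translational decay appears
#' at offset -17 (or -16). Only transcripts whose spliced length covers the
#' full window contribute; the rest are excluded and counted. Normalization
#' divides each bin by the total raw count inside the window (a single
#' global denominator), so the normalized profile sums to 1.
#'
#' @param ends a `five_prime_ends` table.
#' @param models named list of [transcript_model()] objects, one per gene.
#' @param anchor `"stop"` or `"start"`.
#' @param win_up,win_down window bounds in nt (default -50 .. +10);
#'   `win_up <= 0 <= win_down`.
#' @return list of class `metagene_profile`: `anchor`, `offsets`, `raw`,
#'   `normalized`, `n_transcripts`, `n_excluded`, `total`.
#' @export
build_metagene <- function(ends, models, anchor = c("stop", "start"),
                           win_up = -50L, win_down = 10L) {
  anchor <- match.arg(anchor)
  stopifnot(win_up <= 0L, win_down >= 0L)
  offsets <- seq(as.integer(win_up), as.integer(win_down))
  raw <- setNames(numeric(length(offsets)), offsets)
  lookup <- .ends_lookup(ends)
  n_used <- 0L; n_excl <- 0L
  for (m in models) {
    a <- if (anchor == "stop") m$cds_stop_t else m$cds_start_t
    if (a + win_up < 0L || a + win_down >= m$spliced_len) {
      n_excl <- n_excl + 1L
      next
    }
    n_used <- n_used + 1L
    if (length(lookup))
      raw <- raw + .counts_at_tpos(lookup, m, a + offsets)
  }
  if (n_used == 0L)
    stop("no transcript covers the window [", win_up, ",", win_down,
         "]; use a smaller window")
  total <- sum(raw)
  structure(list(anchor = anchor, offsets = offsets, raw = raw,
                 normalized = if (total > 0) raw / total else
                   setNames(rep(NA_real_, length(raw)), names(raw)),
                 n_transcripts = n_used, n_excluded = n_excl,
                 total = total),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: anchor=%s window [%d,%d], %d transcripts (%d excluded), %g ends\n",
              x$anchor, min(x$offsets), max(x$offsets), x$n_transcripts,
              x$n_excluded, x$total))
  invisible(x)
}

#' Locate the peak of a metagene profile
#'
#' @param profile a `metagene_profile` from [build_metagene()].
#' @return list: `offset` (argmax of the normalized profile; ties broken
#'   toward the most negative offset and flagged via `tie`; `NA` with
#'   `degenerate = TRUE` when all bins are equal), `prominence`
#'   (normalized peak height / median of the other bins; `Inf` when that
#'   median is 0).
#' @export
peak_offset <- function(profile) {
  if (profile$total <= 0) stop("empty profile: total raw count is 0")
  v <- profile$normalized
  if (diff(range(v)) == 0)
    return(list(offset = NA_integer_, prominence = NA_real_,
                degenerate = TRUE, tie = FALSE))
  mx <- max(v)
  cand <- profile$offsets[v == mx]
  off <- min(cand)
  others <- v[profile$offsets != off]
  med <- median(others)
  list(offset = off,
       prominence = if (med > 0) mx / med else Inf,
       degenerate = FALSE, tie = length(cand) > 1L)
}

#' Write a metagene profile as TSV
#' @param profile a `metagene_profile`.
#' @param path output path.
#' @export
write_metagene <- function(profile, path) {
  write.table(data.frame(offset = profile$offsets, raw = unname(profile$raw),
                         normalized = unname(profile$normalized)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
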
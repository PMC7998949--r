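#' Pooled CDS-anchored 5'P end count vector
#'
#' For each transcript, 5'P ends with CDS-relative offset in
#' `[start_margin, cds_length - stop_margin)` (offsets measured from the
#' first nucleotide of the start codon; `cds_length` excludes the stop
#' codon) are collected; vectors are truncated to the shortest common
#' analysis length L over transcripts, L forced down to a multiple of 3 so
#' period 3 is an exact DFT frequency, and summed element-wise. The margins
#' exclude the initiation region and the termination pile-up (the -17
#' peak), which would otherwise leak power into the elongation-periodicity
#' spectrum.
#'
#' @param ends a `five_prime_ends` table.
#' @param models named list of [transcript_model()] objects.
#' @param start_margin,stop_margin nt excluded at the CDS 5' and 3' ends
#'   (defaults 9 and 24).
#' @return numeric vector of length L with attributes `n_transcripts` and
#'   `start_margin`; all-zero (flagged via attribute `empty`) when no CDS
#'   end exists.
#' @export
cds_end_vector <- function(ends, models, start_margin = 9L,
                           stop_margin = 24L) {
  stopifnot(start_margin >= 0L, stop_margin >= 0L)
  cds_len <- vapply(models, function(m) m$cds_stop_t - m$cds_start_t, 0L)
  lens <- cds_len - start_margin - stop_margin
  if (!any(lens > 0L))
    stop("no transcript with CDS length > start_margin + stop_margin")
  L <- min(lens[lens > 0L])
  L <- L - (L %% 3L)
  if (L < 30L)
    stop("analysis length L = ", L,
         " < 30: use longer CDS or smaller margins")
  lookup <- .ends_lookup(ends)
  v <- numeric(L)
  n_used <- 0L
  for (m in models) {
    if (m$cds_stop_t - m$cds_start_t - start_margin - stop_margin <= 0L)
      next
    n_used <- n_used + 1L
    if (length(lookup))
      v <- v + .counts_at_tpos(lookup, m,
                               m$cds_start_t + start_margin + 0:(L - 1L))
  }
  structure(v, n_transcripts = n_used, start_margin = start_margin,
            empty = sum(v) == 0)
}

#' DFT periodicity spectrum of a 5'P end count vector
#'
#' Computes discrete Fourier transform magnitudes of the mean-subtracted
#' count vector at frequencies k = 1 .. floor(L/2) and summarizes them as
#' the dominant period L/k* (k* = argmax magnitude) and the relative power
#' at period 3 (magnitude at k = L/3 divided by the sum of magnitudes).
#' Mean subtraction removes the k = 0 component, which would otherwise
#' dominate any spectrum of non-negative counts. Deterministic.
#'
#' @param vector numeric count vector; length L >= 30 and divisible by 3
#'   (see [cds_end_vector()]).
#' @return list of class `periodicity_spectrum`: `period` (L/k),
#'   `amplitude`, `dominant_period` (`NA` for a constant vector),
#'   `relative_power_3nt`, `L`.
#' @export
fft_periodicity <- function(vector) {
  L <- length(vector)
  if (L < 30L) stop("vector length ", L, " < 30")
  if (L %% 3L != 0L) stop("vector length must be a multiple of 3")
  x <- as.numeric(vector) - mean(vector)
  k <- seq_len(L %/% 2L)
  amp <- Mod(fft(x))[k + 1L]
  tot <- sum(amp)
  if (diff(range(vector)) == 0)
    return(structure(list(period = L / k, amplitude = amp * 0,
                          dominant_period = NA_real_,
                          relative_power_3nt = 0, L = L),
                     class = "periodicity_spectrum"))
  kstar <- which.max(amp)
  structure(list(period = L / k, amplitude = amp,
                 dominant_period = L / kstar,
                 relative_power_3nt = amp[k == L %/% 3L] / tot,
                 L = L),
            class = "periodicity_spectrum")
}

#' @export
print.periodicity_spectrum <- function(x, ...) {
  cat(sprintf("periodicity_spectrum: L=%d, dominant period %s nt, relative power at 3 nt = %.3f\n",
              x$L, format(x$dominant_period), x$relative_power_3nt))
  invisible(x)
}

#' Reading-frame distribution of CDS-mapped 5'P ends
#'
#' Partitions CDS-mapped end counts by frame
#' `(transcript position - cds_start_t) mod 3`. A frame-anchored comb puts
#' all mass in one frame; pure background spreads it evenly.
#'
#' @param ends a `five_prime_ends` table.
#' @param models named list of [transcript_model()] objects.
#' @return list: `fractions` (length 3, frames 0/1/2; `NA` when no CDS end
#'   exists), `counts`, `total`.
#' @export
frame_fractions <- function(ends, models) {
  counts <- c(`0` = 0, `1` = 0, `2` = 0)
  lookup <- .ends_lookup(ends)
  for (m in models) {
    if (!length(lookup)) break
    tpos <- m$cds_start_t + 0:(m$cds_stop_t - m$cds_start_t - 1L)
    v <- .counts_at_tpos(lookup, m, tpos)
    fr <- (tpos - m$cds_start_t) %% 3L
    counts <- counts + vapply(0:2, function(f) sum(v[fr == f]), 0)
  }
  total <- sum(counts)
  list(fractions = if (total > 0) counts / total else
         setNames(rep(NA_real_, 3L), 0:2),
       counts = counts, total = total)
}

#' Write a periodicity spectrum as TSV + JSON summary
#' @param spectrum a `periodicity_spectrum`.
#' @param path TSV output path (`period amplitude`); a `.json` summary is
#'   written alongside.
#' @param frame optional result of [frame_fractions()] to include.
#' @export
write_periodicity <- function(spectrum, path, frame = NULL) {
  write.table(data.frame(period = spectrum$period,
                         amplitude = spectrum$amplitude),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(dominant_period = spectrum$dominant_period,
               relative_power_3nt = spectrum$relative_power_3nt,
               L = spectrum$L)
  if (!is.null(frame)) summ$frame_fractions <- unname(frame$fractions)
  jsonlite::write_json(summ, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
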
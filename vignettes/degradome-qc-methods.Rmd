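---
title: "Methods: 5'P degradome read-outs and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5'P degradome read-outs and their synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradomeQC)
```

## The signal model

5'P degradome libraries (GMUCT/PARE-style protocols) capture RNA decay
intermediates by ligating an adapter to their 5' monophosphate end and
sequencing from that extremity, so the first nucleotide of each read is the
exact position at which a decay intermediate begins. During co-translational
decay, the cytoplasmic 5'->3' exoribonuclease (XRN1 in yeast, XRN4 in
Arabidopsis) degrades an mRNA while it is still being translated, advancing
only as fast as the last ribosome translocates. Two signatures follow:

* **A 3-nt comb.** Because the ribosome steps one codon at a time, 5'P ends
  within the CDS fall preferentially into one reading frame, producing a
  3-nt periodicity of end positions.
* **A termination pause.** Termination is slower than elongation, so the
  exoribonuclease piles up against the last ribosome while its A site holds
  the stop codon. The protected distance places the excess of 5'P ends
  16-17 nt upstream of the first nucleotide of the stop codon (the distance
  varies with tissue and condition in Arabidopsis).

On top of these, endonucleolytic events leave single-position spikes:
miRNA-guided cleavage produces a 5'P end exactly at the cleavage site, and a
ribosome stalled on a uORF leaves a localized footprint boundary in the
5'UTR. A broad background of ends from ribosome-independent decay underlies
everything.

This package computes the two QC read-outs (periodicity, stop-proximal
accumulation), the RPM-based transcript inventory, and single-position peak
calls, and ships a generator that simulates exactly this signal structure so
each read-out can be validated by parameter recovery.

## Coordinate conventions

All internal coordinates are 0-based with half-open intervals; GTF I/O
converts from/to 1-based closed coordinates and BED I/O is 0-based
half-open, matching the bedtools convention. Transcript coordinates run
5'->3' along the mature transcript. `cds_stop_t` is the **first nucleotide
of the stop codon** and the stop codon is excluded from the CDS interval, so
"17 nt before the stop codon" is unambiguously metagene offset -17. Fixing
this convention matters: off-by-one differences in where "the stop codon"
starts are a recurring source of disagreement between degradome analyses.

When several isoforms share a gene, one representative model is kept for
anchoring (the longest spliced isoform, ties broken lexicographically by
transcript id). The choice is a package convention; annotation sets that
designate a canonical isoform can be pre-filtered instead.

## The synthetic generator

`decay_params()` fixes the study conditions; `build_toy_reference()`,
`sample_fiveprime_ends()` and `emit_reads()` (or the `simulate_degradome()`
wrapper) produce a toy genome, GTF, FASTQ, a BED of true 5' ends, an
alignment table, and a per-read ground-truth table.

* **Geometry.** Single-exon transcripts of 60 nt 5'UTR + 300 nt CDS
  (including the stop codon) + 90 nt 3'UTR, alternating strand, separated by
  100-nt spacers on one contig. These lengths are compact but leave a CDS
  long enough (297 nt coding) for a 264-nt periodicity analysis window.
  Exon structure is exercised by the annotation unit fixtures rather than by
  the generator, whose job is the positional signal.
* **Mixture.** Each read's 5' end is drawn from a mixture per transcript:
  a frame-anchored comb, uniform over `cds_start + frame_anchor + 3k` below
  the termination position (weight `p_periodic`, default 0.55); the
  termination pause at exactly `cds_stop_t - term_offset` (weight `p_term`,
  default 0.15; `term_offset` defaults to 17 nt, 16 is reachable by
  parameter); and a uniform background over all positions that can carry a
  full read (weight `p_background`, default 0.30). The relative magnitude
  of pause versus comb is not constrained by the biology summarized above,
  so the defaults are package choices, exposed as parameters.
* **Expression.** Per-transcript abundances are one log-normal draw
  (meanlog 0, sdlog `abundance_dispersion`, default 0.5 -- a moderate,
  desk-scale stand-in for expression spread) made when the reference is
  built: expression is a property of the toy sample, so replicate libraries
  of the same reference share the profile and differ only in read sampling.
  Reads are allocated by a single multinomial over
  (transcript, component, position) cells, making every run exactly
  reproducible from the seed.
* **Sites.** Each annotated uORF-stall or miRNA-cleavage site receives a
  stated fraction of the **total** read mass (`site_weight`, default 0.05).
  The global base reflects what such events look like in real tracks: a
  cleavage product is an independent RNA species whose abundance is not tied
  to the host transcript's decay coverage, and it lets a site on a
  weakly-expressed transcript still rise far above that transcript's own
  mean coverage, which is what the per-transcript fold-enrichment caller
  keys on.
* **Reads.** Reads copy the transcript sequence from the 5'P end for
  `read_length` nt (default 75, single-read 75-cycle chemistry), constant
  quality. No sequencing-error or duplicate model: the read-outs under test
  are positional, and adding error would only exercise the aligner, which
  is out of scope. An optional contaminant component (`p_contaminant`)
  emits reads from an unannotated rRNA-like contig to exercise the
  subtraction filter.

What the generator does **not** emulate: isoform mixtures, intron-containing
genes, codon-specific pausing, stop-codon-type effects on the pause
distance, length-dependent coverage biases, and sequencing error. Passing
recovery tests therefore demonstrates that the read-outs are computed
correctly and are sensitive at realistic signal fractions -- not that real
libraries will be this clean.

## Pre-alignment contracts

Trimming truncates to 50 nt from the 3' end only (the 5' nucleotide is the
measurement). Contaminant subtraction is an exact-match contract: a read is
removed iff its first 20 nt (`k`, configurable) occur verbatim in a
contaminant reference or its reverse complement -- deterministic and
sufficient for synthetic data; real pipelines may keep their aligner-based
screen and feed pre-filtered BAM instead. Alignment ingestion accepts BAM
(unmapped/secondary/supplementary dropped first) or the simulator's TSV, and
keeps records with MAPQ >= 10, reproducing the samtools `-q 10` behaviour of
dropping only records strictly below the threshold.

## Counting and detection

Assignment is union-mode at single-nucleotide resolution: the 5'P end (not
the read span) must be exonic in exactly one gene on the matching strand;
ends exonic in two or more genes are ambiguous and discarded, so
assigned + ambiguous + intergenic always equals the number of mapped ends.
This diverges deliberately from interval-overlap counting on full reads:
once the data are reduced to first-nucleotide positions, span-based
ambiguity rules have no meaning. RPM uses the total of uniquely mapped ends
before assignment as denominator, and the detection rule is strict:
`rpm > 5`. Replicate agreement is summarized by Pearson correlation of
`log2(rpm + 1)` (the transform tames the heteroscedasticity of raw RPM and
is recorded in the output) over the union of detected sets, plus the
common/exclusive partition of that union.

## Metagene and periodicity

The stop metagene pools end counts at 1-nt bins over offsets -50..+10
around the first stop-codon nucleotide. The window is a configurable
default chosen to bracket the -17 signal with margin; transcripts that do
not span the whole window are excluded (zero-padding would bias the outer
bins), and normalization is a single global division by the in-window total,
so the normalized profile sums to 1. The peak is the argmax; ties break
toward the most negative offset and are flagged; prominence is the peak
height over the median of the remaining bins.

Periodicity is quantified on the pooled CDS-anchored count vector:
per-transcript ends with CDS-relative offsets in
`[start_margin, cds_length - stop_margin)` (defaults 9 and 24 nt) are
truncated to the shortest common length L, forced down to a multiple of 3,
and summed. The margins keep initiation and termination pile-ups -- above
all the -17 pause -- from leaking power into the elongation spectrum; L
divisible by 3 makes period 3 an exact DFT frequency, avoiding spectral
leakage at the read-out frequency. The spectrum is the DFT magnitude of the
mean-subtracted vector at k = 1..L/2 (mean subtraction removes the k = 0
term, which otherwise dominates any spectrum of non-negative counts);
summaries are the dominant period L/argmax and the relative magnitude at
period 3. One pooled DFT (rather than averaged per-transcript spectra) is
the robust choice at modest depth; a per-transcript mode would be a natural
extension. A constant vector has an all-zero spectrum and an undefined
dominant period. The frame distribution of CDS ends is reported alongside
as the direct time-domain view of the same signal.

## Peak calling

A position is called iff its count is at least `min_count` (10) reads and at
least `min_fold` (20) times the transcript's own mean per-position coverage.
Normalizing within the transcript makes calls depth-invariant and mirrors
how such events are identified on browser tracks -- spikes against their own
transcript. Offsets -18..-15 relative to the stop are masked by default,
because the universal termination pause would otherwise be called on every
well-expressed transcript. No p-value is attached: with no agreed null
model for degradome coverage, a descriptive call with both thresholds
reported is more honest than a silently invented test.

## The QC verdict

The two read-outs proposed as systematic library QC are combined into a
machine-readable verdict: **pass** iff the dominant period is 3 with the
period-3 harmonic carrying at least 10% of total spectral magnitude AND the
stop-metagene peak falls in -18..-15 (covering the 16-17-nt pause reports);
**warn** if exactly one holds; **fail** otherwise. The windowed peak rule
and the 10% power floor are explicit package conventions (the floor guards
against a chance argmax at period 3 in a signal-free library); the report
labels every threshold with its provenance (`paper`-fixed contract vs
package `default` vs user `config`) so the rule is auditable and
reproducible from the numeric fields alone.

## Problem sizes and determinism

The recovery checks run at 200 transcripts and 5x10^5 reads (the scale at
which both read-outs are comfortably identified), site-recovery at 50
transcripts and 10^5 reads over ten seeds, and unit tests at a few thousand
reads; all complete in minutes on one core. Every stochastic step flows
from the single integer seed in `decay_params()` (the reference build uses
`seed`, the read draw `seed + 1`), and reruns are byte-identical across all
emitted files and reports.

## Known limitations

Single-nucleotide counting ignores isoform ambiguity (no EM reassignment);
the periodicity estimate pools transcripts, so a minority of out-of-frame
transcripts is invisible; the peak caller has no statistical calibration and
its thresholds are tuned for sharp single-position events, not broad
pauses; and the QC verdict is a convention for flagging libraries, not a
biological classifier.
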
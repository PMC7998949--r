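# degradomeQC

Analysis and quality control of 5′P degradome sequencing libraries.

## What this is for

Degradome protocols (GMUCT, PARE and their descendants) ligate an adapter
to the 5′ monophosphate (5′P) end of RNA decay intermediates and sequence
from that extremity, so the first nucleotide of every read marks the exact
position where a decay intermediate begins. Because the cytoplasmic 5′→3′
exoribonuclease (XRN1/XRN4) degrades mRNAs while they are still being
translated — advancing codon by codon behind the last ribosome — a healthy
library carries two diagnostic signatures:

* a **3-nt periodicity** of 5′P ends within coding regions (the comb left
  by codon-stepped exonucleolytic progress), and
* an **over-accumulation of 5′P ends 16–17 nt upstream of stop codons**,
  the footprint boundary of a ribosome terminating with its A site on the
  stop codon.

`degradomeQC` computes these read-outs and the standard companions for
anyone running or validating a 5′P degradome experiment:

* single-nucleotide **5′P end extraction** from BAM or an alignment table,
  with fixed-length trimming, contaminant subtraction and the
  unique-mapping (MAPQ ≥ 10) filter;
* a **transcript count table** (union-mode assignment of 5′ ends, RPM
  normalization, detection at RPM > 5, replicate comparison);
* the **stop-codon metagene** at 1-nt bins with in-window normalization and
  peak localization;
* **3-nt periodicity** via a discrete Fourier transform of the pooled
  CDS-anchored end vector, plus reading-frame fractions;
* **single-position peak calls** for uORF ribosome stalls and miRNA
  cleavage sites;
* a machine-readable **QC verdict** combining the two library read-outs;
* a **synthetic degradome generator** reproducing the whole signal
  structure with per-read ground truth, so every read-out is validated by
  parameter recovery — no external data needed.

The core quantities, in the field's notation: for transcript *t* with
raw 5′P end count *n_t* in a library of *N* uniquely mapped ends,
RPM_t = n_t / N × 10⁶, detected iff RPM_t > 5. The metagene profile is
M(o) = Σ_t c_t(stop_t + o) for offsets o ∈ [−50, +10], normalized by
Σ_o M(o); the termination pause appears at o = −17 (or −16). Periodicity is
read from |DFT| of the mean-subtracted pooled CDS end vector; the dominant
period is L/argmax_k |F_k|.

## Worked example

Simulate a 50-transcript library of 10⁵ reads with the default mixture
(55% frame-anchored comb, 15% termination pause at −17, 30% background),
then run the full QC pipeline on the emitted FASTQ + alignments + GTF:

```r
library(degradomeQC)

params <- decay_params(n_transcripts = 50, total_reads = 100000, seed = 20)
sim <- simulate_degradome(params, "demo")

report <- run_pipeline(list(
  fastq      = sim$files[["fastq"]],
  alignments = sim$files[["alignments"]],
  gtf        = sim$files[["gtf"]],
  out_dir    = "demo/qc",
  library_id = "demo"))
```

The report (also written to `demo/qc/qc_report.json`) prints:

```
$ library_id             : chr "demo"
$ n_reads_in             : int 100000
$ n_uniquely_mapped      : int 100000
$ dominant_period        : num 3
$ relative_power_3nt     : num 0.628
$ frame_fractions        : num [1:3] 0.6699 0.246 0.0841
$ stop_peak_offset       : int -17
$ stop_peak_prominence   : num 185
$ n_detected_transcripts : int 50
$ verdict                : chr "pass"
```

Reading this: all 10⁵ reads survive trimming/filtering and map uniquely;
the DFT of the CDS 5′P end vector peaks at period 3 nt, with the period-3
harmonic carrying 63% of total spectral magnitude and 67% of CDS ends in
frame 0; the stop metagene attains its maximum 17 nt upstream of the stop
codon, 185× the median bin — both library read-outs hold, so the verdict
is `pass`. A pure-background simulation (`p_periodic = 0, p_term = 0`)
yields `fail` with both read-outs named in `reasons`.

A thin command-line wrapper over the same functions ships in
`inst/scripts/fivep.R`
(`Rscript fivep.R simulate|qc|count|metagene|periodicity|peaks ...`).

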
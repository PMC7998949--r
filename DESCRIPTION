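Package: degradomeQC
Title: Analysis and Quality Control of 5'P Degradome Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of 5' monophosphate (5'P) degradome
    sequencing libraries (GMUCT/PARE-style protocols) that capture
    co-translational mRNA decay intermediates. Converts alignments to
    single-nucleotide 5'P ends, builds RPM-normalized transcript count
    tables with a detection threshold, computes stop-codon-anchored
    metagene profiles at 1-nt resolution, quantifies the 3-nucleotide
    periodicity of 5'P ends by discrete Fourier transform, and detects
    single-position accumulation events such as uORF ribosome stalls and
    miRNA cleavage sites. Includes a synthetic degradome generator that
    emulates the XRN4 footprint signal structure (frame-anchored 3-nt
    comb, termination pause 16-17 nt upstream of the stop codon, sharp
    cleavage spikes) with per-read ground truth, so every read-out can be
    validated by parameter recovery, plus a machine-readable library QC
    verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
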
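Package: mtbreaks
Title: Non-B DNA Elements and Sequence Motifs at Human mtDNA Deletion
    Breakpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of the association between human mitochondrial DNA
    deletion breakpoints and non-canonical (non-B) DNA elements.  Provides
    wrap-aware handling of the circular mitochondrial genome and its
    arc/origin partition, parsing and de-duplication of published deletion
    breakpoint tables, DNA curvature and bendability profiles from
    dinucleotide step geometry and trinucleotide DNase-I parameters,
    canonical G-quadruplex scanning, GC-content/GC-skew window profiles,
    degenerate IUPAC motif scanning with breakpoint-motif distance
    statistics, k-let-preserving genome shuffles, and randomization-based
    enrichment tests (z-scores with complementary-error-function p values).
    A synthetic-data generator plants features and breakpoints with known
    enrichment structure so that every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
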
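# mtbreaks

Tools for analysing the association between human mitochondrial DNA
(mtDNA) deletion breakpoints and non-canonical (non-B) DNA elements,
compositional skews and degenerate sequence motifs.

## The problem

Deletions of the 16,569 bp circular human mitochondrial genome accumulate
in aged tissue and underlie a range of disorders.  Their breakpoints are
strongly non-uniform: most deletions fall entirely within the major arc,
and hotspots recur near a few positions.  One line of explanation holds
that breakpoints co-locate with sequence contexts prone to non-B DNA
conformations — intrinsically curved and rigid DNA, G-quadruplexes,
triplex and Z-DNA — and with GC-skewed regions and degenerate motifs that
may stall the replication fork.  `mtbreaks` provides the complete
computational toolchain for that analysis:

* **Circular genome handling** — 1-based wrap-aware coordinates, the
  major/minor-arc + replication-origin partition (OH 110–441,
  minor arc 442–5,720, OL 5,721–5,798, major arc 5,799→109), circular
  distances and subsequences.
* **Breakpoint tables** — parsing of published deletion tables with
  interval fields collapsed to their smallest value ("7,508–7,515" →
  7,508), de-duplication of repeated (5′, 3′) pairs, arc classification,
  and breakpoint densities per 0.1 kb: count / pooled interval size × 100.
* **Curvature/bendability** — per-position intrinsic curvature as the
  windowed vector sum of dinucleotide step geometry (degrees per helical
  turn; 10.5°/turn = 1°/bp), DNase-I trinucleotide bendability, their
  ratio, ratio peaks, and breakpoint densities in ±50 bp peak bins.
* **G-quadruplex scanning** — exact detection of the canonical rule
  `G≥3 N1–7 G≥3 N1–7 G≥3 N1–7 G≥3` (and the C-strand analogue), with
  overlapping matches merged into single sites; triplex/Z-DNA accepted as
  annotated BED intervals.
* **Composition** — GC-content and GC-skew `(G−C)/(G+C)` in
  non-overlapping 20 bp windows; breakpoint density stratified by
  composition bins.
* **Motifs** — IUPAC motif scanning (registry includes the
  breakpoint-associated 11-mer `YMMYMNNMMHM`, `CCNCCNTNNCCNC`,
  `CCCCACCCC` and the mTERF consensus `CCN8CC`), breakpoint–motif
  distances, threshold percentages, k-let-preserving genome shuffles
  (Altschul–Erickson Euler-path construction for k ≥ 2) for background
  counts, and binned Spearman correlation of motif and breakpoint
  profiles.
* **Randomization statistics** — the *random* (uniform) and *partially
  random* (per-region counts preserved) null models;
  `z = (P − P̄)/σ_P`, `p = erfc(|z|/√2)`.
* **Synthetic data** — circular genomes with segment-wise composition,
  planted elements, and breakpoints drawn from a mixture of a uniform
  background with a feature-proximal component (fraction π within ±d bp),
  with ground truth for parameter-recovery tests.

## Worked example

```r
library(mtbreaks)

# a synthetic study: mtDNA-scale genome with two large planted
# quadruplexes and 1,508 breakpoints, half of them within 10 bp of a
# planted feature
truth <- generate_genome(plants = list(
  list(at = 8252L,  seq = "GGGTTGGGTTGGGTTGGGTTGGGTTGGGTTGGGTTGGGTTGGGG",
       name = "G2", class = "quadruplex_G"),
  list(at = 15516L, seq = "GGGAGGGGTAGGGGGTAGGGAGGGGGTGGG",
       name = "G5", class = "quadruplex_G")), seed = 7L)
truth <- generate_breakpoints(truth, n = 1508L, enrichment_fraction = 0.5,
                              proximity = 10L, seed = 8L)
dir <- tempfile(); write_fixture(truth, dir)

genome    <- load_genome_fasta(file.path(dir, "genome.fasta"))
deletions <- parse_deletions(file.path(dir, "breakpoints.tsv"), genome$length)
regions   <- default_mito_regions(genome$length)
summ      <- deletion_summary(deletions, regions, genome$length)
quads     <- scan_quadruplex(genome)

pos  <- breakpoint_positions(deletions)
stat <- function(p) breakpoint_density(p, quads, genome$length)
enrichment_test(stat, pos, genome$length, model = "random",
                n_datasets = 200L, seed = 9L)
estimate_enrichment_fraction(truth$breakpoints, truth)
```

Output (abridged):

```
deletions: 754   distinct breakpoints: 853
global density per 0.1 kb: 9.1

  name start   end        class
1   G1  8252  8295 quadruplex_G
2   G2 15516 15545 quadruplex_G
3   C1   484   505 quadruplex_C
4   C2  9907  9926 quadruplex_C

observed 439.7 | null 8.961 +/- 2.697 (n=200)
z = 159.691, p = 2.23e-308 ***

recovered enrichment fraction: 0.498 +/- 0.013
```

The planted quadruplexes are recovered at their exact coordinates (two
background C-pattern sites arise by chance in the C-rich light strand).
The observed breakpoint density inside quadruplex sites, 439.7 per
0.1 kb, towers over the uniform-null expectation of about 9 — the global
density of 1,508 breakpoints on a 16.6 kb circle — because half of all
breakpoints were planted near features; and inverting the mixture model
recovers the planted enrichment fraction π = 0.5 within its standard
error.

The full pipeline (all stages plus both null models and shuffle
backgrounds, one consolidated JSON report and per-stage TSV/BED files):

```r
run_pipeline(file.path(dir, "genome.fasta"), file.path(dir, "breakpoints.tsv"),
             out_dir = "results", seed = 1L)
```

or from the shell via `inst/scripts/mtbreaks-pipeline.R`.

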
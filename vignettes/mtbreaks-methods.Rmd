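---
title: "Methods: non-B DNA elements and sequence motifs at mtDNA deletion breakpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-B DNA elements and sequence motifs at mtDNA deletion breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbreaks)
```

## The scientific question

Human mitochondrial DNA (mtDNA) deletions accumulate in aged post-mitotic
tissue and cause a range of disorders.  Their breakpoints are not spread
uniformly over the 16,569 bp circular genome: most deletions remove part
of the major arc, and breakpoint hotspots cluster near a handful of
positions.  `mtbreaks` tests one family of explanations: that breakpoints
co-locate with sequence contexts able to adopt non-canonical (non-B) DNA
conformations — intrinsically curved/rigid DNA, G-quadruplexes, triplex
and Z-DNA — or with compositionally skewed regions and degenerate
sequence motifs.  The package takes a circular reference genome and a
table of deletion breakpoints, computes the relevant sequence features,
and quantifies breakpoint enrichment with randomization statistics.

## Coordinates and the arc/origin partition

All coordinates are 1-based and inclusive on the light strand.  An
interval whose end is smaller than its start wraps through the sequence
origin, so the major arc is the single region 5,799 → 109.  The built-in
partition for a 16,569 bp genome is: heavy-strand replication origin OH
(110–441), minor arc (442–5,720), light-strand origin OL (5,721–5,798)
and major arc (5,799–16,569 wrapping to 1–109).  These four regions tile
the circle exactly; `validate_regions()` enforces the same property for
user-supplied partitions.  Deletions are classified `major_only` /
`minor_only` when the removed span *and* both flanking breakpoints lie in
one arc, and `involves_origins` when either touches OH or OL; on a circle
a span cannot change arcs without crossing an origin, so the three
classes are exhaustive.

## Breakpoint tables

Published deletion tables often report an interval rather than an exact
breakpoint because a flanking direct repeat makes the position ambiguous
(e.g. "7,508–7,515").  The parser collapses every interval to its
smallest value, accepts hyphen, en-dash, em-dash and minus delimiters and
comma thousands separators, drops rows whose (5′, 3′) pair repeats an
earlier row, and keeps rows that share only one breakpoint.  Densities
are reported per 0.1 kb: `count / pooled interval size × 100`, with
wrap-aware interval sizes, and a position inside several intervals
counted once.

## Curvature and bendability

Intrinsic curvature is predicted from dinucleotide step geometry: each
step contributes a deflection of magnitude equal to its wedge angle,
applied at the helical phase accumulated from the step twists.  The
profile value at a position is the magnitude of the vector sum of the
deflections over a centered window, divided by the window length and
expressed in degrees per helical turn (10.5°/turn = 1°/bp).  The step
table is the Bolshoy/Trifonov twist/wedge/direction set; the window
default is 31 bp (about three helical turns), the conventional choice
for curvature servers.  Because only differences of accumulated phase
within a window matter, the profile is rotation-invariant on the circle;
windows crossing the origin are computed over a phase-continuous
circular extension.

Bendability (flexibility under external force, as probed by DNase I) is
the windowed mean of the Brukner trinucleotide scale.  The raw scale is
signed; it is linearly rescaled to 0–10 across the table range so that
the curvature/bendability ratio is everywhere well defined, and the
default window is 3 bp (essentially the raw centered value).  The
absolute scale of both profiles is parameterisation-dependent; the
analysis rests on *peak positions* and on densities in ±50 bp bins
around them, not on absolute values.  Positions with rescaled
bendability below `eps` are masked from the ratio.  Local maxima use a
strict-majorization rule within ±`min_separation/2` (default ±50 bp)
with plateau ties resolved to the leftmost position, and by default only
peaks with ratio > 1 enter the bin-density analysis.

## G-quadruplex scanning

The canonical folding rule is four runs of at least three G separated by
loops of 1–7 nucleotides, `G3+ N1-7 G3+ N1-7 G3+ N1-7 G3+`, together
with the C-strand analogue; both patterns are scanned on the light
strand, which jointly represents both strands' quadruplexes.  Loops may
contain any of A/C/G/T (including G), so the full match set is not a
simple regular scan: the scanner computes, by a right-to-left dynamic
program over G-run chain reachability, the furthest extent of any
valid ≥4-tract chain from every tract start, takes the union of all
match intervals, and reports maximal covered runs as single sites.  This
reproduces the single-site-per-locus behaviour of classical quadruplex
detectors, which merge overlapping matches irrespective of how many G
runs they contain.  The scan is wrap-aware by default (`circular =
FALSE` disables it).  The suite checks the scanner against an
independent anchored-regex enumeration oracle on 1,000 random 500-mers.

Triplex and Z-DNA detection is *not* re-implemented: the published
detection criteria of the external annotation tools are not specified in
a reproducible form.  Such elements are accepted as BED intervals
(0-based half-open, converted to 1-based inclusive) and enter the same
per-element density and enrichment machinery.

## Composition profiles

GC-content and GC-skew `(G − C)/(G + C)` are computed in non-overlapping
20 bp windows anchored at position 1; the trailing 9 bp partial window
of a 16,569 bp genome is dropped unless wrap-completion is requested.
`N` bases are excluded from counts; a window with no G or C has
undefined skew.  Genome means are averaged per-window (the convention of
window-analysis tools; a per-base alternative would weight windows by
their informative length).  For density stratification each breakpoint
inherits its containing window's value; bins are left-closed right-open
(gc-skew width 0.2 over [−1, 1], GC-content width 10 percentage points),
matching the "[55–75[" interval convention.

## Motif statistics

Degenerate motifs are IUPAC strings; the registry ships the
breakpoint-associated 11-mer YMMYMNNMMHM, the nuclear recombination
hotspot 13-mer CCNCCNTNNCCNC, its 9-mer core CCCCACCCC, and the minimal
mTERF binding consensus CCN8CC.  Scanning is light-strand only by
default (the 11-mer is pyrimidine-rich on that strand), counts
overlapping occurrences — the motif is degenerate enough that overlap
exclusion would be a strong unstated assumption — and includes
wrap-spanning matches.  A genome `N` placeholder satisfies only the
motif code `N`.

Breakpoint–motif distance is 0 inside a match span, otherwise the
circular distance to the nearest span edge.  Threshold percentages use a
strict comparison at 5 bp ("less than 5 bp") and an inclusive one at
20 bp ("maximum distance of 20 bp"); the function exposes both choices
per threshold.

Motif background counts come from shuffled genomes that exactly preserve
k-mer multisets.  `k = 1` permutes letters; `k ≥ 2` uses the
Altschul–Erickson construction — a random last-exit arborescence towards
the terminal (k−1)-mer vertex of the de Bruijn multigraph, resampled
until it is a valid arborescence, then a random Eulerian walk.  The
defaults (130 shuffles, k ∈ {1, 3}) mirror the standard analysis.
Observed counts are compared by z-score; a zero-variance null (e.g. the
motif `N`, whose count is conserved) is flagged rather than reported as
an infinite z.

## Randomization statistics

Two null models generate breakpoint position multisets: *random* — 1,508
positions (twice the deletion count) i.i.d. uniform on the circle, with
replacement — and *partially random* — the same total but preserving the
observed per-region counts over the four-region partition, uniform
within each region.  200 datasets per model is the default.  For a
statistic `P`, `z = (P_obs − mean(P_null)) / sd(P_null)` with the
unbiased (n−1) standard deviation, and `p = erfc(|z|/√2)`, the two-sided
normal tail.  Reports attach the conventional stars (* p<0.05,
** p<0.01, *** p<0.001).  No multiple-testing correction is applied, in
keeping with the analysis the package reproduces; reports state single
test p values.

## The synthetic generator

`generate_genome()` draws background bases i.i.d. per segment from
stated frequencies (default: one segment with A 0.31, C 0.31, G 0.13,
T 0.25 — the approximate light-strand composition of human mtDNA, which
reproduces its strongly negative GC-skew) and overwrites planted literal
or IUPAC-sampled sequences, recording exact coordinates as ground truth.
`generate_breakpoints()` draws each of `n` positions from a mixture:
with probability π uniform over the ±d bp neighborhoods of planted
features, otherwise uniform over the genome; positions are paired into a
deletion table.  Defaults n = 1,508, π = 0.5, d = 10 bp match the scale
of the real dataset and give a strong but not saturated enrichment
signal.  Because the footprint fraction q of the neighborhoods is known,
π is recoverable as `(f_obs − q)/(1 − q)`; the suite requires agreement
within three binomial standard errors across seeds.

The generator emulates the statistical structure the analysis assumes —
segment-wise composition, planted elements, feature-proximal breakpoint
excess — and deliberately not the biology of deletion formation:
no replication mechanics, no direct repeats, no Markov dependence by
default (a k = 3 Markov background can be exercised through the shuffler
itself).  Passing tests on synthetic data therefore validate the
*computations*, not the biological claims; real-genome summaries require
the real reference sequence and curated deletion table as inputs.

## Numerical choices and degenerate inputs

* Curvature windows must span at least one helical turn; sequences
  shorter than the window are errors.
* An all-masked ratio profile (bendability ≤ eps everywhere) is an
  error; masked positions are excluded from means and never become
  peaks.
* Breakpoints past the last full composition window are assigned to the
  last full window (documented; affects at most 9 bp on the standard
  genome, none when wrap-completion is on).
* Interval parsing failures and out-of-range positions report the
  offending row; BED intervals beyond the genome length report the line.
* `sd = 0` nulls are flagged; z is 0 when the observed value coincides
  with the degenerate null and undefined otherwise, with p reported
  as 1.
* All stochastic stages accept a single integer seed; the pipeline
  derives every stage from one seed and two runs with equal inputs and
  seed produce byte-identical reports (input md5 sums, no timestamps).

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
a 16,569 bp synthetic genome with five planted elements and 1,508
breakpoints; 200 randomized datasets per null model and 130 k-let
shuffles per order for the full pipeline run; 1,000 random 500-mers for
the scanner/oracle comparison; 500 repetitions for the z-score
calibration.  These sizes keep the whole battery in the low tens of
seconds while leaving every statistical check with comfortable power.

## Known limitations

* The geometry tables are one published parameterisation each; absolute
  curvature/bendability values (and hence the genome-mean ratio) shift
  under alternative tables, which is why only peak locations are treated
  as meaningful.  The tables live in `bend_geometry()` and can be
  swapped wholesale.
* The quadruplex rule is the canonical one; two-tetrad or long-loop
  variants are out of scope.
* Triplex/Z-DNA annotation is input, not computed.
* De novo motif discovery is out of scope; the registry motifs are
  scanned as given.
* Region classification counts a breakpoint lying exactly on a region
  boundary in the single region that contains it under the partition;
  published analyses do not state their convention for this edge case.
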
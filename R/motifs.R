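# Degenerate IUPAC motif scanning, breakpoint-motif distances,
# k-let-preserving shuffles and binned profile correlation.

#' Built-in registry of breakpoint-associated motifs
#'
#' The degenerate 11-mer over-represented near mitochondrial deletion
#' breakpoints, the 13-mer nuclear recombination hot-spot consensus, its
#' 9-mer core, and the minimal mTERF binding consensus CCN8CC.
#'
#' @return Named character vector of IUPAC motifs.
#' @export
breakpoint_motifs <- function() {
  c(breakpoint_11mer   = "YMMYMNNMMHM",
    recombination_13mer = "CCNCCNTNNCCNC",
    recombination_9mer  = "CCCCACCCC",
    mterf_minimal       = "CCNNNNNNNNCC")
}

iupac_ok <- function(motif) {
  grepl("^[ACGTRYSWKMBDHVN]+$", toupper(motif))
}

# IUPAC motif -> character-class regex (genome N matches only motif N)
iupac_to_regex <- function(motif) {
  classes <- c(A = "A", C = "C", G = "G", T = "T",
               R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
               K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
               H = "[ACT]", V = "[ACG]", N = "[ACGTN]")
  paste(classes[strsplit(toupper(motif), "")[[1L]]], collapse = "")
}

#' Scan a genome for a degenerate IUPAC motif
#'
#' All start positions (light strand) whose window satisfies the IUPAC
#' pattern.  Overlapping occurrences are counted and matches may wrap
#' through the origin when `circular`.  An `N` in the genome is treated
#' as an unknown placeholder: it satisfies only the motif code `N`, not
#' the specific codes.
#'
#' @param genome A [circular_genome()] or character sequence.
#' @param motif IUPAC motif string.
#' @param allow_overlap Count overlapping occurrences (default TRUE).
#' @param circular Include wrap-spanning matches (default TRUE).
#' @return List of class `"motif_matches"`: `motif`, `length`, `starts`
#'   (1-based, sorted), `genome_length`.
#' @export
scan_motif <- function(genome, motif, allow_overlap = TRUE, circular = TRUE) {
  motif <- toupper(motif)
  if (!iupac_ok(motif)) stop("invalid IUPAC code in motif: ", motif)
  s <- genome_sequence(genome)
  L <- nchar(s)
  m <- nchar(motif)
  if (m > L) stop("motif longer than genome")
  subject <- if (circular && m > 1L) paste0(s, substr(s, 1L, m - 1L)) else s
  # zero-width lookahead finds overlapping occurrences
  rx <- paste0("(?=", iupac_to_regex(motif), ")")
  hit <- gregexpr(rx, subject, perl = TRUE)[[1L]]
  starts <- if (hit[1L] == -1L) integer(0) else as.integer(hit)
  starts <- sort(unique(starts[starts <= L]))
  if (!allow_overlap && length(starts) > 1L) {
    kept <- starts[1L]
    for (p in starts[-1L]) {
      if (p - kept[length(kept)] >= m) kept <- c(kept, p)
    }
    starts <- kept
  }
  structure(list(motif = motif, length = m, starts = as.integer(starts),
                 genome_length = L),
            class = "motif_matches")
}

#' @export
print.motif_matches <- function(x, ...) {
  cat(sprintf("%d occurrences of %s on a %d bp circular genome\n",
              length(x$starts), x$motif, x$genome_length))
  invisible(x)
}

#' Circular distance from breakpoints to the nearest motif match
#'
#' A breakpoint inside a match span has distance 0; otherwise the distance
#' is the circular distance to the nearest span edge.
#'
#' @param positions Breakpoint positions (vectorized).
#' @param matches A `"motif_matches"` object from [scan_motif()].
#' @return Numeric vector of distances in bp.
#' @export
nearest_motif_distance <- function(positions, matches) {
  if (length(matches$starts) == 0L) stop("empty match set")
  L <- matches$genome_length
  starts <- matches$starts
  ends <- (starts + matches$length - 2L) %% L + 1L
  vapply(positions, function(p) {
    inside <- in_interval(p, starts, ends)
    if (any(inside)) return(0)
    min(pmin(circular_distance(p, starts, L),
             circular_distance(p, ends, L)))
  }, numeric(1))
}

#' Fraction of breakpoints within a distance of the nearest motif
#'
#' @param positions Breakpoint positions.
#' @param matches `"motif_matches"` object.
#' @param thresholds Distance thresholds in bp (default 5 and 20).
#' @param inclusive Logical per threshold: compare with `<=` instead of
#'   `<`.  The defaults mirror the conventional phrasing "less than 5 bp"
#'   (strict) and "a maximum distance of 20 bp" (inclusive).
#' @return Named numeric vector of percentages.
#' @export
distance_percentages <- function(positions, matches,
                                 thresholds = c(5, 20),
                                 inclusive = c(FALSE, TRUE)) {
  inclusive <- rep_len(inclusive, length(thresholds))
  d <- nearest_motif_distance(positions, matches)
  out <- vapply(seq_along(thresholds), function(i) {
    if (inclusive[i]) mean(d <= thresholds[i]) * 100
    else mean(d < thresholds[i]) * 100
  }, numeric(1))
  names(out) <- paste0(ifelse(inclusive, "le_", "lt_"), thresholds, "bp")
  out
}

#' k-let-preserving sequence shuffle
#'
#' Random permutation of a sequence that exactly preserves its k-mer
#' multiset.  `k = 1` is a plain shuffle of the letters; `k >= 2` uses the
#' Altschul-Erickson construction: a random Eulerian path through the
#' (k-1)-mer de Bruijn multigraph of the sequence, drawn by sampling a
#' last-exit arborescence towards the terminal vertex.
#'
#' @param sequence Character scalar.
#' @param k k-mer order to preserve (default 3).
#' @param seed Optional integer seed for reproducibility.
#' @return Shuffled character scalar with identical k-mer counts.
#' @export
klet_shuffle <- function(sequence, k = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < k) stop("sequence shorter than k")
  chars <- strsplit(s, "")[[1L]]
  if (k == 1L) return(paste(sample(chars), collapse = ""))
  # vertices: (k-1)-mers present in the sequence
  km1 <- substring(s, seq_len(n - k + 2L), seq.int(k - 1L, n))
  verts <- unique(km1)
  vid <- match(km1, verts)           # n-k+2 vertex visits
  from <- vid[-length(vid)]          # n-k+1 edges
  to <- vid[-1L]
  last_char <- chars[seq.int(k, n)]  # character emitted by each edge
  nv <- length(verts)
  start_v <- vid[1L]
  end_v <- vid[length(vid)]
  out_edges <- split(seq_along(from), factor(from, levels = seq_len(nv)))
  # last-exit edge per vertex (except end): must form an arborescence to end
  repeat {
    last_exit <- rep(NA_integer_, nv)
    for (v in seq_len(nv)) {
      if (v == end_v) next
      ee <- out_edges[[v]]
      if (length(ee) == 0L) next
      last_exit[v] <- ee[sample.int(length(ee), 1L)]
    }
    if (is_arborescence(last_exit, to, end_v, nv)) break
  }
  # per-vertex edge order: random permutation with the last-exit edge last
  order_out <- vector("list", nv)
  for (v in seq_len(nv)) {
    ee <- out_edges[[v]]
    if (length(ee) == 0L) next
    le <- last_exit[v]
    rest <- ee[is.na(le) | ee != le]
    if (length(rest) > 1L) rest <- sample(rest)
    order_out[[v]] <- if (is.na(le)) rest else c(rest, le)
  }
  # walk the Eulerian path
  ptr <- rep(1L, nv)
  path <- integer(length(from))
  v <- start_v
  for (i in seq_along(from)) {
    e <- order_out[[v]][ptr[v]]
    ptr[v] <- ptr[v] + 1L
    path[i] <- e
    v <- to[e]
  }
  paste0(verts[start_v], paste(last_char[path], collapse = ""))
}

# do the chosen last-exit edges form a tree directed towards `root`?
is_arborescence <- function(last_exit, to, root, nv) {
  reach <- logical(nv)
  for (v in seq_len(nv)) {
    u <- v
    trail <- integer(0)
    while (!is.na(u) && u != root && !reach[u]) {
      trail <- c(trail, u)
      e <- last_exit[u]
      if (is.na(e)) return(FALSE)
      u <- to[e]
      if (u %in% trail) return(FALSE)  # cycle not through root
    }
    if (is.na(u)) return(FALSE)
    reach[trail] <- TRUE
  }
  TRUE
}

#' Motif background frequency from shuffled genomes
#'
#' Counts motif occurrences in `n` k-let-preserving shuffles of the genome
#' and compares the observed count by z-score and erfc p value.
#'
#' @param genome A [circular_genome()] or character sequence.
#' @param motif IUPAC motif.
#' @param n Number of shuffles (default 130).
#' @param k k-mer order preserved by the shuffle (1 or 3 in the standard
#'   analysis; any `k >= 1` works).
#' @param seed Optional seed.
#' @param circular Passed to [scan_motif()].
#' @return An `"enrichment_result"` (see [enrichment_test()]), with
#'   `null_counts` attached.
#' @export
motif_background <- function(genome, motif, n = 130L, k = 3L, seed = NULL,
                             circular = TRUE) {
  if (n < 2L) stop("need at least 2 shuffles")
  if (!is.null(seed)) set.seed(seed)
  s <- genome_sequence(genome)
  observed <- length(scan_motif(s, motif, circular = circular)$starts)
  counts <- vapply(seq_len(n), function(i) {
    sh <- klet_shuffle(s, k = k)
    length(scan_motif(sh, motif, circular = circular)$starts)
  }, numeric(1))
  res <- zscore(observed, counts)
  res$statistic <- paste0("count(", motif, "), k=", k)
  res$null_counts <- counts
  res
}

#' Rank correlation of binned motif and breakpoint profiles
#'
#' Counts breakpoints and motif starts in consecutive bins along the
#' genome and computes the Spearman rank correlation across bins.
#'
#' @param positions Breakpoint positions.
#' @param matches `"motif_matches"` object.
#' @param bin_size Bin width in bp (default 500).
#' @return List: `rho`, `p`, `table` (per-bin counts).
#' @export
binned_profile_correlation <- function(positions, matches, bin_size = 500L) {
  if (bin_size < 1L) stop("bin_size must be >= 1")
  L <- matches$genome_length
  n_bins <- ceiling(L / bin_size)
  if (n_bins < 3L) stop("fewer than 3 bins")
  bin_of <- function(p) pmin((p - 1L) %/% bin_size + 1L, n_bins)
  bp <- tabulate(bin_of(positions), n_bins)
  mo <- tabulate(bin_of(matches$starts), n_bins)
  ct <- suppressWarnings(
    stats::cor.test(bp, mo, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value,
       table = data.frame(bin = seq_len(n_bins), breakpoints = bp,
                          motifs = mo))
}
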
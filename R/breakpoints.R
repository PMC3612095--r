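# Deletion-table parsing, the interval-collapsing rule, arc classification
# and breakpoint densities.

#' Parse a deletion breakpoint table
#'
#' Reads a tab-separated table with columns id, 5' breakpoint, 3'
#' breakpoint and (optionally) source.  Breakpoint fields may be single
#' positions or intervals ("7,508-7,515", en-dash or hyphen); intervals
#' arise when flanking direct repeats make the exact breakpoint ambiguous
#' and are collapsed to their smallest value.  Rows repeating both
#' extremities of an earlier row are dropped; rows sharing one breakpoint
#' but differing in the other are kept as distinct deletions.
#'
#' @param path TSV file with header.
#' @param genome_length Genome length for range validation.
#' @return data.frame with columns `id`, `five_prime`, `three_prime`,
#'   `source`.
#' @export
parse_deletions <- function(path, genome_length) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3L) stop("deletion table needs at least 3 columns")
  ids <- tab[[1L]]
  src <- if (ncol(tab) >= 4L) tab[[4L]] else rep(NA_character_, nrow(tab))
  five  <- vapply(seq_len(nrow(tab)), function(i)
    collapse_breakpoint_field(tab[[2L]][i], i), numeric(1))
  three <- vapply(seq_len(nrow(tab)), function(i)
    collapse_breakpoint_field(tab[[3L]][i], i), numeric(1))
  out_of_range <- five < 1 | five > genome_length |
    three < 1 | three > genome_length
  if (any(out_of_range)) {
    stop(sprintf("row %d: breakpoint outside 1..%d",
                 which(out_of_range)[1L], genome_length))
  }
  if (any(five == three)) {
    stop(sprintf("row %d: identical 5' and 3' breakpoints",
                 which(five == three)[1L]))
  }
  keep <- !duplicated(paste(five, three))
  data.frame(id = ids[keep], five_prime = as.integer(five[keep]),
             three_prime = as.integer(three[keep]), source = src[keep],
             stringsAsFactors = FALSE)
}

# One breakpoint field -> smallest value of the interval.  Accepts comma
# thousands separators and hyphen / en-dash / em-dash / minus delimiters.
collapse_breakpoint_field <- function(field, row) {
  x <- gsub("[,  ]", "", field)
  parts <- strsplit(x, "[-–—−]")[[1L]]
  parts <- parts[nzchar(parts)]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) == 0L || anyNA(vals)) {
    stop(sprintf("row %d: cannot parse breakpoint field '%s'", row, field))
  }
  min(vals)
}

#' Breakpoint multiset of a deletion table
#'
#' @param deletions data.frame from [parse_deletions()].
#' @return Integer vector with two positions per deletion (the multiset of
#'   5' and 3' breakpoints).
#' @export
breakpoint_positions <- function(deletions) {
  as.integer(c(deletions$five_prime, deletions$three_prime))
}

#' Number of distinct breakpoint positions
#'
#' @param positions Breakpoint position multiset.
#' @return Count of distinct positions.
#' @export
distinct_breakpoint_count <- function(positions) {
  length(unique(as.integer(positions)))
}

#' Breakpoint density per 0.1 kb
#'
#' Density is the number of breakpoints falling inside any of the given
#' intervals divided by the summed interval sizes, expressed per 0.1 kb
#' (i.e. multiplied by 100).  Intervals may wrap (`end < start`); a
#' position inside several intervals is counted once.
#'
#' @param positions Breakpoint position multiset.
#' @param intervals data.frame with `start` and `end` columns (regions or
#'   feature intervals).
#' @param L Genome length.
#' @return Density in breakpoints per 0.1 kb.
#' @export
breakpoint_density <- function(positions, intervals, L) {
  if (nrow(intervals) == 0L) stop("no intervals given")
  total <- sum(interval_size(intervals$start, intervals$end, L))
  if (total == 0) stop("total interval size is zero")
  inside <- rep(FALSE, length(positions))
  for (i in seq_len(nrow(intervals))) {
    inside <- inside | in_interval(positions, intervals$start[i],
                                   intervals$end[i])
  }
  sum(inside) / total * 100
}

#' Classify a deletion by the arc it removes
#'
#' The removed span runs from `five_prime` to `three_prime` in the
#' light-strand direction (wrapping through the origin when
#' `three_prime < five_prime`); the flanking breakpoints themselves are
#' retained sequence.  A deletion is `major_only` / `minor_only` when the
#' removed span and both breakpoints lie in that arc, and
#' `involves_origins` when the span or a breakpoint touches OH or OL.
#'
#' @param five_prime,three_prime Breakpoint positions (vectorized).
#' @param regions Region partition (see [default_mito_regions()]).
#' @param L Genome length.
#' @return Character vector in
#'   `c("major_only", "minor_only", "involves_origins")`.
#' @export
classify_deletion <- function(five_prime, three_prime, regions, L) {
  stopifnot(length(five_prime) == length(three_prime))
  if (any(five_prime == three_prime)) {
    stop("deletion with identical 5' and 3' breakpoints is ambiguous")
  }
  origin_iv <- regions[regions$class %in% c("OH", "OL"), , drop = FALSE]
  mapply(function(fp, tp) {
    span_start <- fp %% L + 1L
    span_end <- (tp - 2L) %% L + 1L
    # adjacent breakpoints delete nothing between them
    empty_span <- (fp %% L + 1L) == tp
    touched <- c(fp, tp)
    hits_origin <- FALSE
    for (i in seq_len(nrow(origin_iv))) {
      s <- origin_iv$start[i]; e <- origin_iv$end[i]
      if (any(in_interval(touched, s, e))) hits_origin <- TRUE
      if (!empty_span && intervals_overlap(span_start, span_end, s, e, L)) {
        hits_origin <- TRUE
      }
    }
    if (hits_origin) return("involves_origins")
    cls <- classify_position(touched, regions)
    if (all(cls == "major_arc")) "major_only" else "minor_only"
  }, five_prime, three_prime, USE.NAMES = FALSE)
}

# Wrap-aware overlap of two inclusive intervals on a circle of length L.
intervals_overlap <- function(s1, e1, s2, e2, L) {
  p2 <- interval_positions(s2, e2, L)
  any(in_interval(p2, s1, e1))
}

#' Per-class deletion fractions and per-region breakpoint densities
#'
#' @param deletions data.frame from [parse_deletions()].
#' @param regions Region partition.
#' @param L Genome length.
#' @return List with `class_fractions` (named fractions over
#'   major_only/minor_only/involves_origins), `region_density` (named
#'   densities per region class, per 0.1 kb) and `global_density`.
#' @export
deletion_summary <- function(deletions, regions, L) {
  cls <- classify_deletion(deletions$five_prime, deletions$three_prime,
                           regions, L)
  lev <- c("major_only", "minor_only", "involves_origins")
  fr <- table(factor(cls, levels = lev)) / length(cls)
  pos <- breakpoint_positions(deletions)
  dens <- vapply(split(regions, regions$class), function(r)
    breakpoint_density(pos, r, L), numeric(1))
  list(class_fractions = c(fr),
       region_density = dens,
       global_density = length(pos) / L * 100,
       n_deletions = nrow(deletions),
       n_breakpoints = length(pos),
       n_distinct_breakpoints = distinct_breakpoint_count(pos))
}
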
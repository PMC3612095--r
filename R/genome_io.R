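# Circular genome handling and the mitochondrial arc/origin partition.
#
# All coordinates are 1-based inclusive.  A region (or any interval) whose
# end is smaller than its start wraps through the origin of the coordinate
# system, so the major arc of the human mtDNA is the single interval
# 5799 -> 109.

#' Construct a circular genome object
#'
#' @param sequence Nucleotide sequence (character scalar). Uppercased;
#'   only A, C, G, T and N are accepted.
#' @param id Sequence identifier.
#' @return An object of class `"circular_genome"`: a list with elements
#'   `id`, `sequence` and `length`.
#' @export
circular_genome <- function(sequence, id = "genome") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("genome sequence is empty")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  }
  structure(list(id = as.character(id), sequence = sequence,
                 length = nchar(sequence)),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("Circular genome '%s': %d bp\n", x$id, x$length))
  invisible(x)
}

#' Load a single-record FASTA file as a circular genome
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return A [circular_genome()] object.
#' @export
load_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop(sprintf("expected exactly one FASTA record, found %d", length(set)))
  }
  circular_genome(as.character(set[[1L]]), id = names(set)[1L])
}

#' The four-region partition of the human mitochondrial genome
#'
#' Returns the canonical partition of the 16,569 bp human mtDNA into the
#' major arc (5,799-16,569 wrapping to 1-109), the heavy-strand origin OH
#' (110-441), the minor arc (442-5,720) and the light-strand origin OL
#' (5,721-5,798).
#'
#' @param genome_length Genome length in bp; only 16,569 has a built-in
#'   partition, other lengths must supply regions via [read_regions_tsv()].
#' @return A data.frame with columns `name`, `start`, `end`, `class`
#'   (one of `major_arc`, `minor_arc`, `OH`, `OL`). `end < start` encodes
#'   wrapping through the origin.
#' @export
default_mito_regions <- function(genome_length = 16569L) {
  if (genome_length != 16569L) {
    stop("no built-in region partition for genome length ", genome_length,
         "; supply regions explicitly")
  }
  regions <- data.frame(
    name  = c("OH", "minor_arc", "OL", "major_arc"),
    start = c(110L, 442L, 5721L, 5799L),
    end   = c(441L, 5720L, 5798L, 109L),
    class = c("OH", "minor_arc", "OL", "major_arc"),
    stringsAsFactors = FALSE
  )
  validate_regions(regions, genome_length)
  regions
}

#' Read a region partition from a TSV file
#'
#' @param path TSV with columns name, start, end, class.
#' @param genome_length Genome length used to validate the partition.
#' @return Region data.frame as in [default_mito_regions()].
#' @export
read_regions_tsv <- function(path, genome_length) {
  regions <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(regions)[1:4] <- c("name", "start", "end", "class")
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  validate_regions(regions, genome_length)
  regions
}

# Partition must tile the circle exactly once.
validate_regions <- function(regions, genome_length) {
  stopifnot(all(c("name", "start", "end", "class") %in% names(regions)))
  if (any(regions$start < 1L | regions$start > genome_length |
          regions$end < 1L | regions$end > genome_length)) {
    stop("region coordinates outside 1..", genome_length)
  }
  covered <- logical(genome_length)
  for (i in seq_len(nrow(regions))) {
    idx <- interval_positions(regions$start[i], regions$end[i], genome_length)
    if (any(covered[idx])) stop("regions overlap at position ", idx[covered[idx]][1L])
    covered[idx] <- TRUE
  }
  if (!all(covered)) stop("regions do not cover position ", which(!covered)[1L])
  invisible(regions)
}

#' Size of a (possibly wrapping) interval on a circular genome
#'
#' @param start,end 1-based inclusive endpoints; `end < start` wraps.
#' @param L Genome length.
#' @return Interval length in bp.
#' @export
interval_size <- function(start, end, L) {
  ifelse(end >= start, end - start + 1L, L - start + 1L + end)
}

# All positions of a wrap-aware interval, in 5'->3' order.
interval_positions <- function(start, end, L) {
  if (end >= start) start:end else c(start:L, 1:end)
}

# Wrap-aware membership: is position p inside [start, end] on the circle?
# Vectorized over positions or over intervals (recycling).
in_interval <- function(p, start, end) {
  linear <- p >= start & p <= end
  wrapped <- p >= start | p <= end
  ifelse(rep_len(end >= start, length(linear)), linear, wrapped)
}

#' Classify positions by genome region
#'
#' @param positions Integer vector of 1-based positions.
#' @param regions Region data.frame (see [default_mito_regions()]).
#' @return Character vector of region classes, one per position.
#' @export
classify_position <- function(positions, regions) {
  out <- rep(NA_character_, length(positions))
  for (i in seq_len(nrow(regions))) {
    hit <- in_interval(positions, regions$start[i], regions$end[i])
    out[hit] <- regions$class[i]
  }
  if (anyNA(out)) stop("position not covered by any region: ",
                       positions[is.na(out)][1L])
  out
}

#' Shortest distance between two positions on a circle
#'
#' @param a,b 1-based positions.
#' @param L Genome length.
#' @return `min(|a - b|, L - |a - b|)`, vectorized over `a` and `b`.
#' @export
circular_distance <- function(a, b, L) {
  if (any(a < 1L | a > L) || any(b < 1L | b > L)) {
    stop("positions must lie in 1..", L)
  }
  d <- abs(a - b)
  pmin(d, L - d)
}

#' Extract a (possibly wrapping) subsequence
#'
#' @param genome A [circular_genome()] or a plain character sequence.
#' @param start,end 1-based inclusive; `end < start` wraps through the
#'   origin.
#' @return Character scalar.
#' @export
subsequence <- function(genome, start, end) {
  s <- genome_sequence(genome)
  L <- nchar(s)
  if (start < 1L || start > L || end < 1L || end > L) {
    stop("positions must lie in 1..", L)
  }
  if (end >= start) substr(s, start, end)
  else paste0(substr(s, start, L), substr(s, 1L, end))
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character scalar over A/C/G/T/N (IUPAC codes allowed).
#' @return Reverse-complemented character scalar.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Accept either a circular_genome or a bare character string.
genome_sequence <- function(genome) {
  if (inherits(genome, "circular_genome")) genome$sequence
  else if (is.character(genome) && length(genome) == 1L) toupper(genome)
  else stop("expected a circular_genome or a character sequence")
}

genome_length <- function(genome) nchar(genome_sequence(genome))
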
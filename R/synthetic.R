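# Synthetic circular genomes with planted features and breakpoints with
# known enrichment structure, so every pipeline stage can be validated
# against ground truth without external data.

#' Generate a synthetic circular genome with planted features
#'
#' Background bases are drawn i.i.d. per segment from the stated base
#' frequencies; planted sequences (literal or IUPAC, sampled uniformly
#' over each code's allowed bases) then overwrite the background.  The
#' default composition mimics the light strand of the human mitochondrial
#' genome (C- and A-rich, G-poor), at the same 16,569 bp scale.
#'
#' @param length Genome length in bp (default 16,569).
#' @param segments Optional list of segments, each
#'   `list(start =, end =, freq = c(A=,C=,G=,T=))`; segments must tile
#'   the genome.  Default: one segment with A .31, C .31, G .13, T .25.
#' @param plants Optional list of `list(at =, seq =, name =, class =)`
#'   features to plant (name/class optional); overlapping plants are an
#'   error.
#' @param id Genome identifier.
#' @param seed Optional integer seed.
#' @return List of class `"synthetic_truth"`: `genome`
#'   ([circular_genome()]), `planted` (data.frame `name`, `start`, `end`,
#'   `class`, `sequence`), `seed`.
#' @export
generate_genome <- function(length = 16569L, segments = NULL, plants = NULL,
                            id = "synthetic_mtDNA", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(segments)) {
    segments <- list(list(start = 1L, end = length,
                          freq = c(A = 0.31, C = 0.31, G = 0.13, T = 0.25)))
  }
  chars <- rep(NA_character_, length)
  for (seg in segments) {
    idx <- interval_positions(seg$start, seg$end, length)
    if (any(!is.na(chars[idx]))) stop("segments overlap")
    f <- seg$freq[c("A", "C", "G", "T")]
    chars[idx] <- sample(names(f), length(idx), replace = TRUE,
                         prob = f / sum(f))
  }
  if (any(is.na(chars))) stop("segments do not tile the genome")
  planted <- data.frame(name = character(0), start = integer(0),
                        end = integer(0), class = character(0),
                        sequence = character(0), stringsAsFactors = FALSE)
  occupied <- logical(length)
  for (i in seq_along(plants)) {
    pl <- plants[[i]]
    seqc <- sample_iupac(toupper(pl$seq))
    m <- nchar(seqc)
    idx <- ((pl$at - 1L):(pl$at + m - 2L)) %% length + 1L
    if (any(occupied[idx])) stop("overlapping plants at position ", pl$at)
    occupied[idx] <- TRUE
    chars[idx] <- strsplit(seqc, "")[[1L]]
    planted <- rbind(planted, data.frame(
      name = if (!is.null(pl$name)) pl$name else paste0("P", i),
      start = as.integer(pl$at), end = as.integer(idx[m]),
      class = if (!is.null(pl$class)) pl$class else "motif",
      sequence = seqc, stringsAsFactors = FALSE))
  }
  structure(list(genome = circular_genome(paste(chars, collapse = ""),
                                          id = id),
                 planted = planted, seed = seed),
            class = "synthetic_truth")
}

# sample a concrete sequence from an IUPAC pattern
sample_iupac <- function(x) {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  chars <- strsplit(x, "")[[1L]]
  bad <- !(chars %in% names(codes))
  if (any(bad)) stop("invalid IUPAC code in plant: ", chars[bad][1L])
  paste(vapply(chars, function(ch) {
    opts <- codes[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Generate breakpoints with known feature enrichment
#'
#' Each of `n` breakpoint positions is, with probability `enrichment_
#' fraction`, drawn uniformly from the union of the `+/- proximity` bp
#' neighborhoods of the planted features, and otherwise uniformly from
#' the whole genome.  Positions are paired into deletions (consecutive
#' pairs, smaller position as the 5' breakpoint).
#'
#' @param truth A `"synthetic_truth"` from [generate_genome()].
#' @param n Number of breakpoints (default 1,508, i.e. 754 deletions).
#' @param enrichment_fraction Mixture weight pi of the feature-proximal
#'   component (default 0.5).
#' @param proximity Half-width d of the feature neighborhoods in bp
#'   (default 10).
#' @param seed Optional integer seed.
#' @return The truth object with added `breakpoints` (integer vector),
#'   `deletions` (data.frame `id`, `five_prime`, `three_prime`,
#'   `source`), `enrichment_fraction`, `proximity`, `n_breakpoints`.
#' @export
generate_breakpoints <- function(truth, n = 1508L, enrichment_fraction = 0.5,
                                 proximity = 10L, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (enrichment_fraction < 0 || enrichment_fraction > 1) {
    stop("enrichment_fraction must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  L <- truth$genome$length
  pool <- feature_neighborhood(truth$planted, proximity, L)
  if (enrichment_fraction > 0 && length(pool) == 0L) {
    stop("positive enrichment_fraction with no planted features")
  }
  near <- stats::runif(n) < enrichment_fraction
  pos <- integer(n)
  pos[!near] <- sample.int(L, sum(!near), replace = TRUE)
  if (any(near)) {
    pos[near] <- pool[sample.int(length(pool), sum(near), replace = TRUE)]
  }
  # pair consecutive positions into deletions; 5' is the smaller position
  if (n %% 2L == 1L) pos <- c(pos, sample.int(L, 1L))
  a <- pos[seq(1L, length(pos), by = 2L)]
  b <- pos[seq(2L, length(pos), by = 2L)]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  same <- a == b
  b[same] <- a[same] %% L + 1L
  truth$breakpoints <- pos[seq_len(n)]
  truth$deletions <- data.frame(
    id = paste0("D", seq_along(a)), five_prime = a, three_prime = b,
    source = "synthetic", stringsAsFactors = FALSE)
  truth$enrichment_fraction <- enrichment_fraction
  truth$proximity <- proximity
  truth$n_breakpoints <- n
  truth
}

# union of +/- d neighborhoods of planted features (positions on circle)
feature_neighborhood <- function(planted, d, L) {
  if (nrow(planted) == 0L) return(integer(0))
  unique(unlist(lapply(seq_len(nrow(planted)), function(i) {
    s <- (planted$start[i] - d - 1L) %% L + 1L
    e <- (planted$end[i] + d - 1L) %% L + 1L
    interval_positions(s, e, L)
  })))
}

#' Estimate the planted enrichment fraction from breakpoints
#'
#' Inverts the mixture: with footprint fraction `q` (share of the genome
#' within `d` of a planted feature), the expected fraction of breakpoints
#' in the neighborhood is `pi + (1 - pi) q`, so
#' `pi-hat = (f_obs - q) / (1 - q)`.
#'
#' @param positions Breakpoint positions.
#' @param truth A `"synthetic_truth"` with planted features.
#' @param proximity Neighborhood half-width d used in generation.
#' @return List: `pi_hat`, `f_obs`, `footprint` (q), `se` (binomial
#'   standard error of `pi_hat`).
#' @export
estimate_enrichment_fraction <- function(positions, truth,
                                         proximity = truth$proximity) {
  L <- truth$genome$length
  pool <- feature_neighborhood(truth$planted, proximity, L)
  q <- length(pool) / L
  f_obs <- mean(positions %in% pool)
  n <- length(positions)
  pi_hat <- (f_obs - q) / (1 - q)
  se <- sqrt(f_obs * (1 - f_obs) / n) / (1 - q)
  list(pi_hat = pi_hat, f_obs = f_obs, footprint = q, se = se)
}

#' Write a synthetic fixture to disk
#'
#' Writes `genome.fasta`, `breakpoints.tsv` (deletion table) and
#' `truth.json` (planted features and generation parameters) so the
#' fixture round-trips through the pipeline readers.
#'
#' @param truth A `"synthetic_truth"` with breakpoints.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(truth$genome$sequence)
  names(seqs) <- truth$genome$id
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fasta"))
  utils::write.table(truth$deletions, file.path(dir, "breakpoints.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    genome_id = truth$genome$id,
    genome_length = truth$genome$length,
    planted = truth$planted,
    enrichment_fraction = truth$enrichment_fraction,
    proximity = truth$proximity,
    n_breakpoints = truth$n_breakpoints,
    seed = truth$seed
  )
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a synthetic fixture
#'
#' @param dir Directory written by [write_fixture()].
#' @return List: `genome`, `deletions`, `truth` (parsed truth.json).
#' @export
load_fixture <- function(dir) {
  genome <- load_genome_fasta(file.path(dir, "genome.fasta"))
  deletions <- parse_deletions(file.path(dir, "breakpoints.tsv"),
                               genome$length)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(genome = genome, deletions = deletions, truth = truth)
}
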
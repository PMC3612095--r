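# Canonical G-quadruplex scanning and externally annotated non-B elements.
#
# The canonical folding rule is four runs of >= 3 G separated by loops of
# 1-7 bases (and the C-strand analogue).  All matches of the rule are
# computed exactly by a dynamic program over G-run chain reachability;
# overlapping matches are merged so each locus is reported as a single
# site, mirroring the behaviour of the classical Quadparser tool.

#' Scan a genome for canonical quadruplex-forming sequences
#'
#' Finds maximal, mutually non-overlapping sites matching
#' `G3+ N1-7 G3+ N1-7 G3+ N1-7 G3+` and the C-strand analogue on the given
#' (light) strand.  Loops may contain any of A/C/G/T; overlapping matches
#' of the rule are merged into one site.
#'
#' @param genome A [circular_genome()] or character sequence.
#' @param circular Allow matches to wrap through the sequence origin.
#' @return data.frame of feature intervals: `name` (G1.., C1..), `start`,
#'   `end` (1-based inclusive, `end < start` wraps), `class`
#'   (`quadruplex_G` / `quadruplex_C`), `sequence`.
#' @export
scan_quadruplex <- function(genome, circular = TRUE) {
  s <- genome_sequence(genome)
  g_sites <- quad_sites(s, "G", circular)
  c_sites <- quad_sites(s, "C", circular)
  lab <- function(df, prefix, cls) {
    if (nrow(df) == 0L) {
      return(data.frame(name = character(0), start = integer(0),
                        end = integer(0), class = character(0),
                        sequence = character(0), stringsAsFactors = FALSE))
    }
    df <- df[order(df$start), , drop = FALSE]
    data.frame(name = paste0(prefix, seq_len(nrow(df))),
               start = df$start, end = df$end,
               class = cls,
               sequence = vapply(seq_len(nrow(df)), function(i)
                 subsequence(s, df$start[i], df$end[i]), character(1)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(lab(g_sites, "G", "quadruplex_G"),
               lab(c_sites, "C", "quadruplex_C"))
  rownames(out) <- NULL
  out
}

# Union of all matches of the canonical rule for one base, as merged sites.
quad_sites <- function(s, base, circular) {
  L <- nchar(s)
  work <- if (circular) paste0(s, s) else s
  reach <- quad_reach(work, base)
  covered <- logical(L)
  starts <- which(!is.na(reach))
  for (a in starts) {
    if (a > L) next
    b <- min(reach[a], a + L - 1L)
    covered[((a - 1L):(b - 1L)) %% L + 1L] <- TRUE
  }
  if (!circular) {
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    st <- ends - runs$lengths + 1L
    keep <- runs$values
    return(data.frame(start = st[keep], end = ends[keep]))
  }
  covered_runs_circular(covered)
}

# Maximal runs of TRUE on a circle, reported as wrap-aware intervals.
covered_runs_circular <- function(covered) {
  L <- length(covered)
  if (!any(covered)) return(data.frame(start = integer(0), end = integer(0)))
  if (all(covered)) return(data.frame(start = 1L, end = L))
  # rotate so position 1 is uncovered, find linear runs, rotate back
  z <- which(!covered)[1L]
  rot <- covered[((z - 1L):(z + L - 2L)) %% L + 1L]
  runs <- rle(rot)
  ends <- cumsum(runs$lengths)
  st <- ends - runs$lengths + 1L
  keep <- runs$values
  back <- function(i) (i + z - 2L) %% L + 1L
  data.frame(start = back(st[keep]), end = back(ends[keep]))
}

# For every position p where a tract (>= 3 of `base`) starts, the furthest
# end of any chain of >= 4 tracts with 1-7 nt loops beginning at p; NA if
# none.  Computed right-to-left:
#   F1(p) = max(end of longest single tract at p, max over next starts of F1)
#   Ft(p) = max over next tract starts s in [p+4, p+run(p)+7] of F(t-1)(s)
quad_reach <- function(s, base) {
  n <- nchar(s)
  is_b <- strsplit(s, "")[[1L]] == base
  # run[p]: number of consecutive `base` characters starting at p
  run <- integer(n)
  acc <- 0L
  for (p in n:1L) {
    acc <- if (is_b[p]) acc + 1L else 0L
    run[p] <- acc
  }
  tract <- run >= 3L
  F1 <- rep(NA_integer_, n); F2 <- F1; F3 <- F1; F4 <- F1
  suppress <- function(x) x[!is.na(x)]
  for (p in n:1L) {
    if (!tract[p]) next
    lo <- p + 4L
    hi <- min(p + run[p] + 7L, n)
    nxt <- if (lo <= hi) (lo:hi)[tract[lo:hi]] else integer(0)
    own_end <- p + run[p] - 1L
    f1n <- suppress(F1[nxt])
    F1[p] <- max(own_end, f1n)
    f2 <- suppress(F1[nxt]); if (length(f2)) F2[p] <- max(f2)
    f3 <- suppress(F2[nxt]); if (length(f3)) F3[p] <- max(f3)
    f4 <- suppress(F3[nxt]); if (length(f4)) F4[p] <- max(f4)
  }
  F4
}

#' Load annotated non-B elements from a BED file
#'
#' Elements detected by external tools (e.g. triplex or Z-DNA annotations)
#' are accepted as intervals.  BED is 0-based half-open; coordinates are
#' converted to the package's 1-based inclusive convention.  The BED name
#' field carries the element name, and an optional fifth column (or a
#' name suffix after a colon) the element class.
#'
#' @param path BED file.
#' @param genome_length Genome length for validation.
#' @return data.frame with `name`, `start`, `end`, `class`.
#' @export
load_elements <- function(path, genome_length) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file: ",
                                          conditionMessage(e)))
  start <- as.integer(GenomicRanges::start(gr))
  end <- as.integer(GenomicRanges::end(gr))
  nm <- if (!is.null(gr$name)) as.character(gr$name)
        else paste0("E", seq_along(gr))
  if (any(end > genome_length | start < 1L)) {
    stop("BED interval exceeds genome length ", genome_length,
         " at line ", which(end > genome_length | start < 1L)[1L])
  }
  cls <- sub("^[^:]*:?", "", nm)
  cls[!nzchar(cls)] <- "element"
  nm <- sub(":.*$", "", nm)
  data.frame(name = nm, start = start, end = end, class = cls,
             stringsAsFactors = FALSE)
}

#' Export feature intervals as BED
#'
#' Converts 1-based inclusive intervals to BED (0-based half-open);
#' wrapping intervals are split at the genome origin into two BED rows.
#'
#' @param elements data.frame with `name`, `start`, `end` (and optionally
#'   `class`, appended to the name after a colon).
#' @param path Output BED path.
#' @param genome [circular_genome()] providing the sequence name/length.
#' @export
write_elements_bed <- function(elements, path, genome) {
  L <- genome_length(genome)
  id <- if (inherits(genome, "circular_genome")) genome$id else "genome"
  id <- strsplit(id, "\\s+")[[1L]][1L]
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    nm <- elements$name[i]
    if (!is.null(elements$class)) nm <- paste0(nm, ":", elements$class[i])
    s <- elements$start[i]; e <- elements$end[i]
    if (e >= s) {
      rows[[length(rows) + 1L]] <- data.frame(start = s, end = e, name = nm)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(start = s, end = L, name = nm)
      rows[[length(rows) + 1L]] <- data.frame(start = 1L, end = e, name = nm)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = id,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    name = df$name
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Breakpoint density per element with randomization enrichment
#'
#' @param elements data.frame of feature intervals.
#' @param positions Breakpoint position multiset.
#' @param L Genome length.
#' @param null_positions Optional list of randomized position multisets
#'   (e.g. from [random_breakpoints()]); when given, each element and the
#'   pooled set get z-scores and p values.
#' @return data.frame with one row per element plus a final `pooled` row:
#'   `name`, `size_bp`, `n_breakpoints`, `density` and, with nulls,
#'   `null_mean`, `null_sd`, `z`, `p`.
#' @export
element_density_table <- function(elements, positions, L,
                                  null_positions = NULL) {
  one <- function(iv, pos) breakpoint_density(pos, iv, L)
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    iv <- elements[i, , drop = FALSE]
    size <- interval_size(iv$start, iv$end, L)
    n_in <- sum(in_interval(positions, iv$start, iv$end))
    data.frame(name = iv$name, size_bp = size, n_breakpoints = n_in,
               density = one(iv, positions), stringsAsFactors = FALSE)
  })
  pooled <- data.frame(
    name = "pooled",
    size_bp = sum(interval_size(elements$start, elements$end, L)),
    n_breakpoints = NA_integer_,
    density = one(elements, positions), stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), pooled)
  if (!is.null(null_positions)) {
    stats <- lapply(c(seq_len(nrow(elements)), list(NULL)), function(i) {
      iv <- if (is.null(i)) elements else elements[i, , drop = FALSE]
      obs <- one(iv, positions)
      nulls <- vapply(null_positions, function(pos) one(iv, pos), numeric(1))
      zs <- zscore(obs, nulls)
      data.frame(null_mean = zs$null_mean, null_sd = zs$null_sd,
                 z = zs$z, p = zs$p)
    })
    out <- cbind(out, do.call(rbind, stats))
  }
  rownames(out) <- NULL
  out
}
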
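# Independent oracles and small generators shared across the suite.

random_seq <- function(n, bases = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

kmer_counts <- function(s, k) {
  n <- nchar(s)
  table(substring(s, seq_len(n - k + 1L), seq.int(k, n)))
}

# Regex-enumeration oracle for the canonical quadruplex rule: for every
# candidate start, the maximal full-match extent is found by anchored
# regex trials; coverage is the union of [start, max end]; sites are the
# maximal covered runs.  Independent of the package's run-chain DP.
oracle_quad_sites <- function(s, base = "G", circular = TRUE) {
  L <- nchar(s)
  work <- if (circular) paste0(s, s) else s
  n <- nchar(work)
  full <- sprintf("^%s{3,}([ACGT]{1,7}%s{3,}){3,}$", base, base)
  some <- sprintf("^%s{3,}([ACGT]{1,7}%s{3,}){3,}", base, base)
  tract3 <- paste0(base, base, base)
  covered <- logical(L)
  # a match cannot cross a run of >= 8 non-base characters (loops are 1-7)
  deserts <- gregexpr(sprintf("[^%s]{8,}", base), work)[[1L]]
  deserts <- if (deserts[1L] == -1L) integer(0) else as.integer(deserts)
  for (a in seq_len(min(L, n - 14L))) {
    if (substr(work, a, a + 2L) != tract3) next
    if (regexpr(some, substr(work, a, n), perl = TRUE) == -1L) next
    after <- deserts[deserts > a]
    bmax <- if (length(after)) min(after) - 1L else n
    if (bmax < a + 14L) next
    for (b in bmax:(a + 14L)) {
      if (substr(work, b, b) != base) next
      if (grepl(full, substr(work, a, b), perl = TRUE)) {
        bmax <- min(b, a + L - 1L)
        covered[((a - 1L):(bmax - 1L)) %% L + 1L] <- TRUE
        break
      }
    }
  }
  if (!any(covered)) return(data.frame(start = integer(0), end = integer(0)))
  if (all(covered)) return(data.frame(start = 1L, end = L))
  # maximal circular runs of covered positions, by explicit scan
  first_gap <- which(!covered)[1L]
  ord <- ((first_gap - 1L):(first_gap + L - 2L)) %% L + 1L
  starts <- integer(0); ends <- integer(0); open <- FALSE
  for (p in ord) {
    if (covered[p] && !open) { starts <- c(starts, p); open <- TRUE }
    if (!covered[p] && open) { ends <- c(ends, ord[match(p, ord) - 1L]); open <- FALSE }
  }
  if (open) ends <- c(ends, ord[L])
  df <- data.frame(start = starts, end = ends)
  df[order(df$start), , drop = FALSE]
}

# 3D path-reconstruction curvature oracle: composes per-step rotation
# matrices (twist about the helix axis, wedge deflection at the given
# direction) and measures the angle between helix-axis vectors one
# window apart, in degrees per helical turn.
oracle_curvature_3d <- function(s, window = 31L) {
  geo <- mtbreaks::bend_geometry()$dinucleotide
  chars <- strsplit(s, "")[[1L]]
  L <- length(chars)
  rot_z <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  }
  rot_x <- function(a) {
    a <- a * pi / 180
    matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
  }
  axes <- matrix(0, 3, L + 1L)
  M <- diag(3)
  axes[, 1L] <- M[, 3L]
  for (i in seq_len(L)) {
    d <- paste0(chars[i], chars[i %% L + 1L])
    j <- match(d, geo$dinuc)
    deflect <- rot_z(geo$direction[j]) %*% rot_x(geo$wedge[j]) %*%
      rot_z(-geo$direction[j])
    M <- M %*% rot_z(geo$twist[j]) %*% deflect
    axes[, i + 1L] <- M[, 3L]
  }
  n_ax <- L + 1L
  vapply(seq_len(n_ax - window), function(i) {
    ca <- sum(axes[, i] * axes[, i + window])
    acos(pmin(1, pmax(-1, ca))) * 180 / pi / window * 10.5
  }, numeric(1))
}

# exhaustive breakpoint-to-motif distance: minimum circular distance to
# any position inside any match span (0 when contained)
oracle_nearest_distance <- function(p, starts, len, L) {
  span_pos <- unique(unlist(lapply(starts, function(s0)
    ((s0 - 1L):(s0 + len - 2L)) %% L + 1L)))
  min(vapply(span_pos, function(q) {
    d <- abs(p - q); min(d, L - d)
  }, numeric(1)))
}

make_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_fasta <- function(seqs, ids = paste0("seq", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
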
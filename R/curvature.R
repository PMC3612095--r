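# Curvature and bendability profiles of circular DNA.
#
# Curvature is computed as the magnitude of the vector sum of dinucleotide
# step deflections (wedge angle applied at the helical phase accumulated
# from the step twists) over a centered window, expressed in degrees per
# helical turn (10.5 deg/turn = 1 deg/bp).  Bendability is a windowed
# average of a trinucleotide DNase-I-derived flexibility scale, linearly
# rescaled to a positive 0-10 range so that the curvature/bendability
# ratio is well defined.

#' Dinucleotide and trinucleotide geometry tables
#'
#' Returns the built-in step-geometry parameterisation: the
#' Bolshoy/Trifonov dinucleotide twist/wedge/direction angles (degrees)
#' used for the curvature vector sum, and the Brukner DNase-I trinucleotide
#' bendability scale (32 complement classes mirrored onto all 64
#' trinucleotides).
#'
#' @return List with data.frames `dinucleotide` (`dinuc`, `twist`, `wedge`,
#'   `direction`) and `trinucleotide` (`triplet`, `bendability`).
#' @export
bend_geometry <- function() {
  dinuc <- data.frame(
    dinuc = c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
              "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT"),
    twist = c(35.62, 34.4, 27.7, 31.5, 34.5, 33.67, 29.8, 27.7,
              36.9, 40.0, 33.67, 34.4, 36.0, 36.9, 34.5, 35.62),
    wedge = c(7.2, 1.1, 8.4, 2.6, 3.5, 2.1, 6.7, 8.4,
              5.3, 5.0, 2.1, 1.1, 0.9, 5.3, 3.5, 7.2),
    direction = c(-154, 143, 2, 0, -64, -57, 0, -2,
                  120, 180, 57, -143, 0, -120, 64, 154),
    stringsAsFactors = FALSE
  )
  tri_class <- c(
    AAA = -0.274, AAC = -0.205, AAG = -0.081, AAT = -0.280,
    ACA = -0.006, ACC = -0.032, ACG = -0.033, ACT = -0.183,
    AGA =  0.027, AGC =  0.017, AGG = -0.057, ATA =  0.182,
    ATC = -0.110, ATG =  0.134, CAA =  0.015, CAC =  0.040,
    CAG =  0.175, CCA = -0.246, CCC = -0.012, CCG = -0.136,
    CGA = -0.003, CGC = -0.077, CTA =  0.090, CTC =  0.031,
    GAA = -0.037, GAC = -0.013, GCA =  0.076, GCC =  0.107,
    GGA =  0.013, GTA =  0.025, TAA =  0.068, TCA =  0.194
  )
  bases <- c("A", "C", "G", "T")
  all_tri <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  val <- vapply(all_tri, function(t) {
    if (t %in% names(tri_class)) tri_class[[t]]
    else tri_class[[chartr("ACGT", "TGCA",
                           paste(rev(strsplit(t, "")[[1L]]), collapse = ""))]]
  }, numeric(1))
  list(
    dinucleotide = dinuc,
    trinucleotide = data.frame(triplet = all_tri, bendability = unname(val),
                               stringsAsFactors = FALSE)
  )
}

# Per-step geometry (twist/wedge/direction, degrees) for a circular
# sequence: step i is the dinucleotide (i, i+1 mod L).  Steps touching N
# get zero wedge and the mean twist.
step_geometry <- function(genome, geometry) {
  s <- genome_sequence(genome)
  L <- nchar(s)
  chars <- strsplit(s, "")[[1L]]
  nxt <- c(chars[-1L], chars[1L])
  dinucs <- paste0(chars, nxt)
  g <- geometry$dinucleotide
  idx <- match(dinucs, g$dinuc)
  twist <- g$twist[idx]
  wedge <- g$wedge[idx]
  direction <- g$direction[idx]
  unknown <- is.na(idx)
  twist[unknown] <- mean(g$twist)
  wedge[unknown] <- 0
  direction[unknown] <- 0
  list(twist = twist, wedge = wedge, direction = direction)
}

#' DNA curvature profile
#'
#' Per-position intrinsic curvature of a circular sequence, in degrees per
#' helical turn, from the vector sum of dinucleotide step deflections over
#' a centered window (wrap-aware).
#'
#' @param genome A [circular_genome()] or character sequence.
#' @param window Window size in bp (odd; default 31, about three helical
#'   turns).
#' @param geometry Geometry tables from [bend_geometry()].
#' @return Numeric vector of length `L`, `>= 0`.
#' @export
curvature_profile <- function(genome, window = 31L, geometry = bend_geometry()) {
  L <- genome_length(genome)
  if (window < 11L) stop("window must span at least one helical turn")
  if (L <= window) stop("sequence shorter than the window")
  geo <- step_geometry(genome, geometry)
  half <- window %/% 2L
  # circularly extend the step arrays, then accumulate helical phase over
  # the extension so windows crossing the origin stay phase-continuous
  # (|window sum| is invariant under a global phase, so the profile of a
  # rotated sequence is the rotated profile)
  idx <- c((L - half + 1L):L, 1:L, 1L:half)
  twist <- geo$twist[idx]
  phase <- cumsum(c(0, twist[-length(twist)])) * pi / 180
  vv <- geo$wedge[idx] * exp(1i * (phase + geo$direction[idx] * pi / 180))
  cs <- cumsum(vv)
  win <- cs[(window):(window + L - 1L)] - c(0, cs[1L:(L - 1L)])
  Mod(win) / window * 10.5
}

#' DNA bendability profile
#'
#' Windowed average of the trinucleotide bendability scale, linearly
#' rescaled to 0-10 across the table range (wrap-aware).
#'
#' @inheritParams curvature_profile
#' @param window Window size in bp (odd; default 3, i.e. essentially the
#'   raw trinucleotide value centered on each position).
#' @return Numeric vector of length `L`.
#' @export
bendability_profile <- function(genome, window = 3L, geometry = bend_geometry()) {
  L <- genome_length(genome)
  if (window < 1L) stop("window must be positive")
  if (L <= window) stop("sequence shorter than the window")
  s <- genome_sequence(genome)
  chars <- strsplit(s, "")[[1L]]
  tri <- paste0(chars,
                c(chars[-1L], chars[1L]),
                c(chars[-(1:2)], chars[1:2]))
  g <- geometry$trinucleotide
  val <- g$bendability[match(tri, g$triplet)]
  rng <- range(g$bendability)
  val <- (val - rng[1L]) / (rng[2L] - rng[1L]) * 10
  val[is.na(val)] <- NA  # trinucleotides containing N
  # value of the triplet starting at i-1 is centered on i
  centered <- c(val[L], val[-L])
  half <- window %/% 2L
  if (half == 0L) return(centered)
  vv <- c(centered[(L - half + 1L):L], centered, centered[1L:half])
  vapply(seq_len(L), function(i) mean(vv[i:(i + window - 1L)], na.rm = TRUE),
         numeric(1))
}

#' Curvature/bendability ratio profile
#'
#' @param curvature,bendability Aligned numeric profiles.
#' @param eps Positions with bendability `<= eps` are masked (`NA`).
#' @return Numeric vector of ratios with masked positions `NA`.
#' @export
ratio_profile <- function(curvature, bendability, eps = 1e-9) {
  stopifnot(length(curvature) == length(bendability))
  ratio <- ifelse(!is.na(bendability) & bendability > eps,
                  curvature / bendability, NA_real_)
  if (all(is.na(ratio))) stop("all positions masked: bendability <= eps everywhere")
  ratio
}

#' Mean curvature/bendability ratio of a genome
#'
#' @param ratio Ratio profile from [ratio_profile()]; masked positions are
#'   excluded.
#' @return Scalar mean.
#' @export
genome_mean_ratio <- function(ratio) mean(ratio, na.rm = TRUE)

#' Local maxima of a circular profile
#'
#' A position is a peak when its value is at least as large as every value
#' within `min_separation/2` on either side (circular) and strictly larger
#' than every earlier position in that window, so a plateau of ties
#' reports its leftmost position.
#'
#' @param profile Numeric profile (NAs allowed, never peaks).
#' @param min_separation Minimum separation between reported peaks, bp.
#' @param min_value Only peaks with value `> min_value` are reported
#'   (default 1.0, the discrete-peak threshold used for bin-density
#'   analysis); use `-Inf` for all.
#' @return Integer positions sorted by profile value, decreasing.
#' @export
local_maxima <- function(profile, min_separation = 100L, min_value = 1.0) {
  L <- length(profile)
  half <- max(1L, min_separation %/% 2L)
  x <- ifelse(is.na(profile), -Inf, profile)
  peaks <- integer(0)
  for (p in seq_len(L)) {
    if (!is.finite(x[p]) || x[p] <= min_value) next
    idx <- ((p - half - 1L):(p + half - 1L)) %% L + 1L
    vals <- x[idx]
    center <- half + 1L
    if (all(vals <= x[p]) &&
        all(vals[seq_len(center - 1L)] < x[p])) {
      peaks <- c(peaks, p)
    }
  }
  peaks[order(x[peaks], decreasing = TRUE)]
}

#' Breakpoint density in bins centered on profile peaks
#'
#' @param positions Breakpoint position multiset.
#' @param peaks Peak positions.
#' @param L Genome length.
#' @param halfwidth Half-width of the bin around each peak (default 50 bp,
#'   i.e. 0.1 kb bins).
#' @return data.frame with `peak`, `start`, `end`, `density` (per 0.1 kb).
#' @export
peak_bin_density <- function(positions, peaks, L, halfwidth = 50L) {
  start <- (peaks - halfwidth - 1L) %% L + 1L
  end <- (peaks + halfwidth - 1L) %% L + 1L
  dens <- vapply(seq_along(peaks), function(i)
    breakpoint_density(positions,
                       data.frame(start = start[i], end = end[i]), L),
    numeric(1))
  data.frame(peak = peaks, start = start, end = end, density = dens)
}
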
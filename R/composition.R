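# Non-overlapping window profiles of GC-content and GC-skew, and
# breakpoint-density stratification by composition bins.

#' GC-content / GC-skew window profile
#'
#' Tiles the genome with non-overlapping windows anchored at position 1.
#' GC-skew is `(G - C) / (G + C)` (undefined when the window has no G or
#' C); GC-content is `(G + C) / (A + C + G + T)`.  N bases are excluded
#' from all counts.  A trailing partial window is dropped unless
#' `wrap_complete` is set, in which case it is completed with bases
#' wrapped from the genome start.
#'
#' @param genome A [circular_genome()] or character sequence.
#' @param window Window size in bp (default 20).
#' @param wrap_complete Complete the final partial window through the
#'   origin instead of dropping it.
#' @return data.frame with `start`, `end`, `gc_content` (fraction),
#'   `gc_skew`.
#' @export
window_profile <- function(genome, window = 20L, wrap_complete = FALSE) {
  if (window < 1L) stop("window must be >= 1")
  s <- genome_sequence(genome)
  L <- nchar(s)
  n_win <- L %/% window
  if (n_win == 0L) stop("genome shorter than one window")
  chars <- strsplit(s, "")[[1L]]
  use <- n_win * window
  if (wrap_complete && use < L) {
    n_win <- n_win + 1L
    chars <- c(chars, chars[seq_len(n_win * window - L)])
    use <- n_win * window
  }
  m <- matrix(chars[seq_len(use)], nrow = window)
  count <- function(b) colSums(m == b)
  G <- count("G"); C <- count("C"); A <- count("A"); T <- count("T")
  tot <- A + C + G + T
  # with wrap_complete the final end may exceed L, denoting wrapped bases
  data.frame(
    start = as.integer((seq_len(n_win) - 1L) * window + 1L),
    end = as.integer(seq_len(n_win) * window),
    gc_content = ifelse(tot > 0, (G + C) / tot, NA_real_),
    gc_skew = ifelse(G + C > 0, (G - C) / (G + C), NA_real_)
  )
}

#' Genome-average composition over windows
#'
#' @param profile Window profile from [window_profile()].
#' @return Named vector: `gc_content_pct` (percent) and `gc_skew`.
#' @export
composition_means <- function(profile) {
  c(gc_content_pct = mean(profile$gc_content, na.rm = TRUE) * 100,
    gc_skew = mean(profile$gc_skew, na.rm = TRUE))
}

#' Breakpoint density stratified by composition bin
#'
#' Each breakpoint inherits the composition value of its containing
#' window (breakpoints beyond the last full window are assigned to the
#' last window).  Windows are grouped into left-closed right-open bins of
#' the chosen variable; the density in a bin is the pooled breakpoint
#' count over its windows divided by their summed size, per 0.1 kb.
#'
#' @param positions Breakpoint position multiset.
#' @param profile Window profile from [window_profile()].
#' @param variable `"gc_skew"` or `"gc_content"`; gc_content is binned on
#'   the percent scale.
#' @param bin_edges Numeric bin edges; defaults: width 0.2 over `[-1, 1]`
#'   for gc_skew, width 10 over `[0, 100]` for gc_content.
#' @return List: `bins` (data.frame `bin_low`, `bin_high`, `n_windows`,
#'   `total_bp`, `n_breakpoints`, `density`), `fraction_below_mean` and
#'   `fraction_above_mean` (fractions of breakpoints in windows with the
#'   variable strictly below / above the genome mean).
#' @export
density_by_bin <- function(positions, profile,
                           variable = c("gc_skew", "gc_content"),
                           bin_edges = NULL) {
  variable <- match.arg(variable)
  window <- profile$end[1L] - profile$start[1L] + 1L
  val <- if (variable == "gc_content") profile$gc_content * 100
         else profile$gc_skew
  if (is.null(bin_edges)) {
    bin_edges <- if (variable == "gc_skew") seq(-1, 1, by = 0.2)
                 else seq(0, 100, by = 10)
  }
  if (min(val, na.rm = TRUE) < bin_edges[1L] ||
      max(val, na.rm = TRUE) > bin_edges[length(bin_edges)]) {
    stop("bin_edges do not cover the observed range of ", variable)
  }
  widx <- pmin((positions - 1L) %/% window + 1L, nrow(profile))
  # left-closed right-open; the top edge is absorbed into the last bin
  wbin <- findInterval(val, bin_edges, rightmost.closed = TRUE)
  bbin <- wbin[widx]
  n_bins <- length(bin_edges) - 1L
  bins <- data.frame(
    bin_low = bin_edges[-length(bin_edges)],
    bin_high = bin_edges[-1L],
    n_windows = tabulate(wbin, n_bins),
    n_breakpoints = tabulate(bbin, n_bins)
  )
  bins$total_bp <- bins$n_windows * window
  bins$density <- ifelse(bins$total_bp > 0,
                         bins$n_breakpoints / bins$total_bp * 100, NA_real_)
  bins <- bins[, c("bin_low", "bin_high", "n_windows", "total_bp",
                   "n_breakpoints", "density")]
  mu <- mean(val, na.rm = TRUE)
  bp_val <- val[widx]
  list(bins = bins,
       fraction_below_mean = mean(bp_val < mu, na.rm = TRUE),
       fraction_above_mean = mean(bp_val > mu, na.rm = TRUE))
}
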
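# Null models for breakpoint positions and the shared z-score / erfc
# p-value machinery.

#' Fully random breakpoint datasets
#'
#' Draws `n_datasets` multisets of `n_positions` positions i.i.d. uniform
#' on `1..L`, with replacement (repeated positions allowed).
#'
#' @param n_positions Positions per dataset (the standard analysis uses
#'   twice the number of deletions, 1,508).
#' @param L Genome length.
#' @param n_datasets Number of datasets (default 200).
#' @param seed Optional integer seed.
#' @return List of integer vectors.
#' @export
random_breakpoints <- function(n_positions, L, n_datasets = 200L,
                               seed = NULL) {
  if (n_positions < 1L) stop("n_positions must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_datasets), function(i)
    sample.int(L, n_positions, replace = TRUE))
}

#' Per-region breakpoint counts of an observed dataset
#'
#' @param positions Observed breakpoint positions.
#' @param regions Region partition (see [default_mito_regions()]).
#' @return Named integer vector of counts per region class.
#' @export
region_breakpoint_counts <- function(positions, regions) {
  cls <- classify_position(positions, regions)
  counts <- table(factor(cls, levels = unique(regions$class)))
  stats::setNames(as.integer(counts), names(counts))
}

#' Partially random breakpoint datasets
#'
#' Random datasets that preserve the observed abundance of breakpoints
#' within each region class (arcs and origins of replication): within
#' every region class the prescribed count of positions is drawn
#' uniformly, with replacement.
#'
#' @param region_counts Named integer vector, counts per region class.
#' @param regions Region partition.
#' @param L Genome length.
#' @param n_datasets Number of datasets (default 200).
#' @param seed Optional integer seed.
#' @return List of integer vectors (each of length `sum(region_counts)`).
#' @export
partially_random_breakpoints <- function(region_counts, regions, L,
                                         n_datasets = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pools <- lapply(names(region_counts), function(cl) {
    rr <- regions[regions$class == cl, , drop = FALSE]
    if (nrow(rr) == 0L && region_counts[[cl]] > 0L) {
      stop("no region of class ", cl, " but a positive count prescribed")
    }
    unlist(lapply(seq_len(nrow(rr)), function(i)
      interval_positions(rr$start[i], rr$end[i], L)))
  })
  names(pools) <- names(region_counts)
  lapply(seq_len(n_datasets), function(d) {
    unlist(lapply(names(region_counts), function(cl) {
      k <- region_counts[[cl]]
      if (k == 0L) integer(0)
      else pools[[cl]][sample.int(length(pools[[cl]]), k, replace = TRUE)]
    }), use.names = FALSE)
  })
}

#' z-score of an observed statistic against null samples
#'
#' `z = (observed - mean(null)) / sd(null)` with the sample (n-1)
#' standard deviation.  When the null variance is zero the result is
#' flagged: `z` is `NA` and `p` is reported as 1 (degenerate).
#'
#' @param observed Observed statistic value.
#' @param null_samples Numeric vector of the statistic on randomized
#'   datasets (length >= 2).
#' @return List of class `"enrichment_result"`: `observed`, `null_mean`,
#'   `null_sd`, `z`, `p`, `n_datasets`, `flagged`.
#' @export
zscore <- function(observed, null_samples) {
  if (length(null_samples) < 2L) stop("need at least 2 null samples")
  m <- mean(null_samples)
  s <- stats::sd(null_samples)
  if (s == 0) {
    # degenerate null: z undefined unless the observed value coincides
    res <- list(observed = observed, null_mean = m, null_sd = 0,
                z = if (observed == m) 0 else NA_real_, p = 1,
                n_datasets = length(null_samples), flagged = TRUE)
  } else {
    z <- (observed - m) / s
    res <- list(observed = observed, null_mean = m, null_sd = s,
                z = z, p = pvalue_from_z(z),
                n_datasets = length(null_samples), flagged = FALSE)
  }
  class(res) <- "enrichment_result"
  res
}

#' Two-sided normal-tail p value from a z-score
#'
#' `p = erfc(|z| / sqrt(2))`, the two-sided tail probability of the
#' standard normal distribution.
#'
#' @param z Finite z-score (vectorized).
#' @return p value(s) in (0, 1].
#' @export
pvalue_from_z <- function(z) {
  stopifnot(all(is.finite(z)))
  # clamp the erfc underflow for extreme z so p stays in (0, 1]
  pmax(erfc(abs(z) / sqrt(2)), .Machine$double.xmin)
}

# complementary error function
erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

significance_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (!is.null(x$statistic)) cat("statistic:", x$statistic, "\n")
  cat(sprintf("observed %.4g | null %.4g +/- %.4g (n=%d)\n",
              x$observed, x$null_mean, x$null_sd, x$n_datasets))
  if (isTRUE(x$flagged)) {
    cat("degenerate null (sd = 0); z suppressed\n")
  } else {
    cat(sprintf("z = %.3f, p = %.3g %s\n", x$z, x$p,
                significance_stars(x$p)))
  }
  invisible(x)
}

#' Randomization enrichment test of a breakpoint statistic
#'
#' Applies `statistic` to the observed positions and to each randomized
#' dataset under the requested null model(s), returning z-scores and erfc
#' p values.
#'
#' @param statistic Function of a position multiset returning a scalar.
#' @param observed_positions Observed breakpoint positions.
#' @param L Genome length.
#' @param model `"random"`, `"partially_random"`, or both.
#' @param regions Region partition (required for the partially random
#'   model; per-region counts are derived from the observed dataset).
#' @param n_datasets Number of randomized datasets (default 200).
#' @param seed Optional integer seed.
#' @return A single `"enrichment_result"` if one model was requested,
#'   otherwise a named list of results.
#' @export
enrichment_test <- function(statistic, observed_positions, L,
                            model = c("random", "partially_random"),
                            regions = NULL, n_datasets = 200L,
                            seed = NULL) {
  model <- match.arg(model, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  observed <- statistic(observed_positions)
  n_pos <- length(observed_positions)
  out <- list()
  for (mod in model) {
    nulls <- if (mod == "random") {
      random_breakpoints(n_pos, L, n_datasets)
    } else {
      if (is.null(regions)) stop("partially_random model needs regions")
      counts <- region_breakpoint_counts(observed_positions, regions)
      partially_random_breakpoints(counts, regions, L, n_datasets)
    }
    vals <- vapply(nulls, statistic, numeric(1))
    res <- zscore(observed, vals)
    res$model <- mod
    out[[mod]] <- res
  }
  if (length(out) == 1L) out[[1L]] else out
}
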
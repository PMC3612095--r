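# End-to-end orchestration: breakpoint parsing, region densities,
# quadruplex scan, composition, curvature, motif scan and background,
# and randomization enrichment, consolidated into one JSON report.

#' Run the full breakpoint-association pipeline
#'
#' Executes every analysis stage on a genome plus deletion table and
#' writes a consolidated JSON report together with per-stage TSV/BED
#' files.  All stochastic stages derive from the single `seed`, so two
#' runs with the same inputs and seed produce byte-identical reports.
#'
#' @param genome_path Single-record FASTA of the circular genome.
#' @param deletions_path Deletion breakpoint TSV (see
#'   [parse_deletions()]).
#' @param out_dir Output directory (created if needed).
#' @param elements_path Optional BED of externally annotated non-B
#'   elements (triplex/Z-DNA) to include alongside scanned quadruplexes.
#' @param regions Region partition; default the human mtDNA partition
#'   when the genome is 16,569 bp, otherwise a single `major_arc` region
#'   spanning the genome.
#' @param motif IUPAC motif for the motif stages (default the
#'   breakpoint-associated 11-mer YMMYMNNMMHM).
#' @param curvature_window,bendability_window Profile windows in bp.
#' @param composition_window Composition window in bp (default 20).
#' @param peak_min_separation Minimum separation of ratio peaks, bp.
#' @param n_datasets Randomized datasets per null model (default 200).
#' @param n_shuffles k-let shuffles for the motif background (default
#'   130).
#' @param thresholds Breakpoint-motif distance thresholds (default 5
#'   strict, 20 inclusive).
#' @param seed Integer seed for all randomized stages.
#' @return The report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(genome_path, deletions_path, out_dir,
                         elements_path = NULL, regions = NULL,
                         motif = breakpoint_motifs()[["breakpoint_11mer"]],
                         curvature_window = 31L, bendability_window = 3L,
                         composition_window = 20L,
                         peak_min_separation = 100L,
                         n_datasets = 200L, n_shuffles = 130L,
                         thresholds = c(5, 20), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- load_genome_fasta(genome_path)
  L <- genome$length
  if (is.null(regions)) {
    regions <- if (L == 16569L) default_mito_regions(L)
    else data.frame(name = "genome", start = 1L, end = L,
                    class = "major_arc", stringsAsFactors = FALSE)
  }
  deletions <- parse_deletions(deletions_path, L)
  positions <- breakpoint_positions(deletions)

  # stage: breakpoints
  summ <- deletion_summary(deletions, regions, L)

  # null models shared by the enrichment stages
  set.seed(seed)
  nulls_random <- random_breakpoints(length(positions), L, n_datasets)
  counts <- region_breakpoint_counts(positions, regions)
  nulls_partial <- partially_random_breakpoints(counts, regions, L,
                                                n_datasets)

  # stage: quadruplex scan (+ optional annotated elements)
  quad <- scan_quadruplex(genome)
  elements <- quad[, c("name", "start", "end", "class")]
  if (!is.null(elements_path)) {
    elements <- rbind(elements, load_elements(elements_path, L))
  }
  el_random <- element_density_table(elements, positions, L, nulls_random)
  el_partial <- element_density_table(elements, positions, L, nulls_partial)
  if (nrow(quad) > 0L) {
    write_elements_bed(quad, file.path(out_dir, "quadruplexes.bed"), genome)
  }

  # stage: composition
  comp <- window_profile(genome, window = composition_window)
  comp_means <- composition_means(comp)
  skew_bins <- density_by_bin(positions, comp, "gc_skew")
  gc_bins <- density_by_bin(positions, comp, "gc_content")
  utils::write.table(comp, file.path(out_dir, "composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage: curvature
  curv <- curvature_profile(genome, window = curvature_window)
  bend <- bendability_profile(genome, window = bendability_window)
  ratio <- ratio_profile(curv, bend)
  peaks <- local_maxima(ratio, min_separation = peak_min_separation)
  peak_dens <- peak_bin_density(positions, peaks, L)
  utils::write.table(
    data.frame(position = seq_len(L), curvature = curv, bendability = bend,
               ratio = ratio),
    file.path(out_dir, "curvature.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # stage: motif scan, distances, background
  matches <- scan_motif(genome, motif)
  dist_pct <- distance_percentages(positions, matches,
                                   thresholds = thresholds)
  dist_null <- lapply(list(random = nulls_random,
                           partially_random = nulls_partial),
                      function(nulls) {
    vals <- vapply(nulls, function(pos)
      distance_percentages(pos, matches, thresholds),
      numeric(length(thresholds)))
    vals <- matrix(vals, nrow = length(thresholds))
    lapply(seq_along(thresholds), function(i) {
      res <- zscore(dist_pct[[i]], vals[i, ])
      res[c("observed", "null_mean", "null_sd", "z", "p")]
    })
  })
  bg_k1 <- motif_background(genome, motif, n = n_shuffles, k = 1L)
  bg_k3 <- motif_background(genome, motif, n = n_shuffles, k = 3L)
  corr <- binned_profile_correlation(positions, matches)
  write_elements_bed(
    data.frame(name = paste0("M", seq_along(matches$starts)),
               start = matches$starts,
               end = (matches$starts + matches$length - 2L) %% L + 1L,
               class = "motif"),
    file.path(out_dir, "motif_matches.bed"), genome)

  strip <- function(res) res[c("observed", "null_mean", "null_sd",
                               "z", "p", "flagged")]
  report <- list(
    inputs = list(
      genome = unname(tools::md5sum(genome_path)),
      deletions = unname(tools::md5sum(deletions_path)),
      genome_id = genome$id, genome_length = L, seed = seed,
      n_datasets = n_datasets, n_shuffles = n_shuffles, motif = motif),
    breakpoints = summ,
    elements = list(table = elements,
                    density_random = el_random,
                    density_partially_random = el_partial,
                    n_quadruplex_sites = nrow(quad)),
    composition = list(means = as.list(comp_means),
                       skew_bins = skew_bins$bins,
                       gc_bins = gc_bins$bins,
                       fraction_below_mean_skew =
                         skew_bins$fraction_below_mean,
                       fraction_above_mean_gc =
                         gc_bins$fraction_above_mean),
    curvature = list(mean_ratio = genome_mean_ratio(ratio),
                     peaks = peaks, peak_density = peak_dens),
    motif = list(n_occurrences = length(matches$starts),
                 distance_percentages = as.list(dist_pct),
                 distance_null = dist_null,
                 background_k1 = strip(bg_k1),
                 background_k3 = strip(bg_k3),
                 spearman_rho = corr$rho, spearman_p = corr$p)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(report)
}
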
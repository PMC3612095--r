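test_that("IUPAC motif scanning counts overlapping and wrapped matches", {
  L <- 100L
  s <- random_seq(L)
  m <- scan_motif(s, "NN")
  expect_equal(length(m$starts), L)  # every position on a circle
  m2 <- scan_motif(s, "NN", circular = FALSE)
  expect_equal(length(m2$starts), L - 1L)

  bg <- strrep("T", 200L)
  planted <- paste0(substr(bg, 1, 80), "CCCCACCCC", substr(bg, 90, 200))
  hits <- scan_motif(planted, "CCCCACCCC")
  expect_equal(hits$starts, 81L)
  expect_error(scan_motif(s, "QQ"), "IUPAC")

  # wrap-spanning match
  sw <- paste0("CT", strrep("A", 50L), "CC")
  expect_true(53L %in% scan_motif(sw, "CCCT")$starts)
  expect_false(53L %in% scan_motif(sw, "CCCT", circular = FALSE)$starts)
})

test_that("literal motif scanning equals plain substring search", {
  set.seed(3)
  for (i in 1:20) {
    s <- random_seq(400L)
    word <- random_seq(4L)
    got <- scan_motif(s, word, circular = FALSE)$starts
    want <- integer(0)
    for (p in 1:(400L - 3L)) {
      if (substr(s, p, p + 3L) == word) want <- c(want, p)
    }
    expect_equal(got, want)
  }
})

test_that("overlap suppression keeps only greedily non-overlapping matches", {
  s <- paste0(strrep("A", 10L), "CCCCCC", strrep("A", 10L))
  with_ov <- scan_motif(s, "CCC", circular = FALSE)
  expect_equal(length(with_ov$starts), 4L)
  no_ov <- scan_motif(s, "CCC", allow_overlap = FALSE, circular = FALSE)
  expect_equal(no_ov$starts, c(11L, 14L))
})

test_that("nearest breakpoint-motif distance equals the exhaustive oracle", {
  L <- 500L
  m <- structure(list(motif = "X", length = 10L,
                      starts = c(50L, 480L), genome_length = L),
                 class = "motif_matches")
  expect_equal(nearest_motif_distance(55L, m), 0)   # inside a span
  expect_equal(nearest_motif_distance(47L, m), 3)   # 3 bp left of a start
  expect_equal(nearest_motif_distance(2L, m), 13)   # wraps to span 480-489
  expect_error(nearest_motif_distance(1L, structure(
    list(motif = "X", length = 3L, starts = integer(0), genome_length = L),
    class = "motif_matches")), "empty")

  set.seed(29)
  for (i in 1:25) {
    starts <- sort(sample.int(L, 5L))
    mm <- structure(list(motif = "X", length = 7L, starts = starts,
                         genome_length = L), class = "motif_matches")
    p <- sample.int(L, 1L)
    expect_equal(nearest_motif_distance(p, mm),
                 oracle_nearest_distance(p, starts, 7L, L))
  }
})

test_that("distance percentages honor strict/inclusive thresholds and are monotone", {
  L <- 300L
  mm <- structure(list(motif = "X", length = 5L, starts = 100L,
                       genome_length = L), class = "motif_matches")
  pos <- c(100L, 103L, 95L, 109L, 200L)  # distances 0, 0, 5, 5, ~91
  pct <- distance_percentages(pos, mm, thresholds = c(5, 5),
                              inclusive = c(FALSE, TRUE))
  expect_equal(unname(pct[1L]), 40)  # strict <5: only the two contained
  expect_equal(unname(pct[2L]), 80)  # inclusive <=5 adds both at 5

  all_in <- distance_percentages(c(100L, 102L, 104L), mm,
                                 thresholds = c(1, 10, 50))
  expect_true(all(all_in == 100))

  set.seed(17)
  posr <- sample.int(L, 40L, replace = TRUE)
  ts <- c(1, 2, 5, 10, 20, 50)
  pr <- distance_percentages(posr, mm, thresholds = ts,
                             inclusive = rep(TRUE, length(ts)))
  expect_true(all(diff(pr) >= 0))
})

test_that("k-let shuffles preserve k-mer counts exactly and are seed-deterministic", {
  x1 <- klet_shuffle("AACG", k = 1L, seed = 4L)
  expect_equal(sort(strsplit(x1, "")[[1L]]), c("A", "A", "C", "G"))

  set.seed(35)
  for (i in 1:10) {
    s <- random_seq(200L)
    sh <- klet_shuffle(s, k = 3L, seed = i)
    expect_equal(kmer_counts(sh, 3L), kmer_counts(s, 3L))
    # lower-order counts follow automatically
    expect_equal(kmer_counts(sh, 2L), kmer_counts(s, 2L))
    expect_equal(kmer_counts(sh, 1L), kmer_counts(s, 1L))
  }
  expect_identical(klet_shuffle("ACGTACGTTGCA", k = 3L, seed = 9L),
                   klet_shuffle("ACGTACGTTGCA", k = 3L, seed = 9L))
  # k = 2 also supported
  s <- random_seq(100L)
  expect_equal(kmer_counts(klet_shuffle(s, k = 2L, seed = 1L), 2L),
               kmer_counts(s, 2L))
  expect_error(klet_shuffle("AC", k = 3L), "shorter")
})

test_that("k=1 shuffles actually permute while k=3 preserves local structure", {
  set.seed(41)
  s <- strrep("ACG", 60L)
  sh3 <- klet_shuffle(s, k = 3L, seed = 2L)
  # the periodic sequence has a rigid de Bruijn graph: counts identical
  expect_equal(kmer_counts(sh3, 3L), kmer_counts(s, 3L))
  sh1 <- klet_shuffle(s, k = 1L, seed = 2L)
  expect_equal(kmer_counts(sh1, 1L), kmer_counts(s, 1L))
})

test_that("motif background flags degenerate nulls and detects planted enrichment", {
  s <- random_seq(300L)
  res <- motif_background(s, "N", n = 10L, k = 1L, seed = 5L)
  expect_true(res$flagged)
  expect_equal(res$null_sd, 0)
  expect_equal(res$observed, 300)

  # genome carrying many planted copies of a short word; the word is
  # short enough that letter shuffles also produce it, so the null has
  # positive variance while the planted genome still stands far out
  set.seed(51)
  bg <- random_seq(600L, prob = c(0.35, 0.3, 0.05, 0.3))
  word <- "CCACC"
  plant_at <- seq(1L, 571L, by = 30L)
  chars <- strsplit(bg, "")[[1L]]
  for (a in plant_at) {
    chars[a:(a + 4L)] <- strsplit(word, "")[[1L]]
  }
  gsyn <- paste(chars, collapse = "")
  res2 <- motif_background(gsyn, word, n = 30L, k = 1L, seed = 6L)
  expect_gt(res2$z, 3)
})

test_that("binned profile correlation recovers perfect and inverted rank agreement", {
  L <- 3000L
  mm <- structure(list(motif = "X", length = 3L,
                      starts = c(rep(100L, 1L), rep(600L, 2L), rep(1100L, 3L),
                                 rep(1600L, 4L), rep(2100L, 5L), rep(2600L, 6L)),
                      genome_length = L), class = "motif_matches")
  # breakpoints with identical per-bin counts -> rho = 1
  res <- binned_profile_correlation(mm$starts, mm, bin_size = 500L)
  expect_equal(res$rho, 1)
  # reversed ranks -> rho = -1
  rev_pos <- c(rep(100L, 6L), rep(600L, 5L), rep(1100L, 4L),
               rep(1600L, 3L), rep(2100L, 2L), rep(2600L, 1L))
  res2 <- binned_profile_correlation(rev_pos, mm, bin_size = 500L)
  expect_equal(res2$rho, -1)
  expect_error(binned_profile_correlation(1:10, mm, bin_size = 2000L),
               "fewer than 3")
})
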
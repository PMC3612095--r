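test_that("segment compositions are honored and reflected in GC-skew", {
  t <- generate_genome(length = 10000L, segments = list(
    list(start = 1L, end = 10000L,
         freq = c(A = 0.2, C = 0.5, G = 0.1, T = 0.2))), seed = 71L)
  expect_equal(t$genome$length, 10000L)
  prof <- window_profile(t$genome, window = 10000L)
  # expected skew (0.1 - 0.5) / 0.6 = -0.667
  expect_equal(prof$gc_skew, -2 / 3, tolerance = 0.05)
  expect_equal(prof$gc_content, 0.6, tolerance = 0.03)

  two <- generate_genome(length = 2000L, segments = list(
    list(start = 1L, end = 1000L, freq = c(A = 1, C = 0, G = 0, T = 0)),
    list(start = 1001L, end = 2000L, freq = c(A = 0, C = 0, G = 0, T = 1))),
    seed = 72L)
  expect_equal(substr(two$genome$sequence, 1, 1000), strrep("A", 1000L))
  expect_equal(substr(two$genome$sequence, 1001, 2000), strrep("T", 1000L))

  bad <- list(list(start = 1L, end = 600L, freq = c(A = 1, C = 0, G = 0, T = 0)),
              list(start = 500L, end = 1000L, freq = c(A = 1, C = 0, G = 0, T = 0)))
  expect_error(generate_genome(length = 1000L, segments = bad), "overlap")
})

test_that("planted features are recorded and recovered by the scanners", {
  t <- generate_genome(length = 3000L, plants = list(
    list(at = 500L, seq = "GGGTGGGTGGGTGGG", name = "Q1",
         class = "quadruplex_G"),
    list(at = 1500L, seq = "CCCCACCCC", name = "M1", class = "motif")),
    seed = 73L)
  expect_equal(nrow(t$planted), 2L)
  expect_equal(t$planted$end[1L], 514L)
  expect_equal(subsequence(t$genome, 500L, 514L), "GGGTGGGTGGGTGGG")

  q <- scan_quadruplex(t$genome)
  expect_true(any(q$start <= 500L & q$end >= 514L & q$class == "quadruplex_G"))
  m <- scan_motif(t$genome, "CCCCACCCC")
  expect_true(1500L %in% m$starts)

  expect_error(generate_genome(length = 1000L, plants = list(
    list(at = 10L, seq = "AAAA"), list(at = 12L, seq = "TTTT"))),
    "overlapping plants")
  # zero plants -> pure background
  t0 <- generate_genome(length = 500L, seed = 74L)
  expect_equal(nrow(t0$planted), 0L)
})

test_that("breakpoint mixture honors its extremes", {
  t <- generate_genome(length = 4000L, plants = list(
    list(at = 1000L, seq = "GGGTGGGTGGGTGGG", class = "quadruplex_G")),
    seed = 75L)
  t1 <- generate_breakpoints(t, n = 200L, enrichment_fraction = 1,
                             proximity = 0L, seed = 76L)
  expect_true(all(t1$breakpoints >= 1000L & t1$breakpoints <= 1014L))
  m <- structure(list(motif = "q", length = 15L, starts = 1000L,
                      genome_length = 4000L), class = "motif_matches")
  pct <- distance_percentages(t1$breakpoints, m)
  expect_equal(unname(pct[1L]), 100)

  t0 <- generate_breakpoints(t, n = 500L, enrichment_fraction = 0,
                             proximity = 10L, seed = 77L)
  est0 <- estimate_enrichment_fraction(t0$breakpoints, t0)
  expect_lt(abs(est0$pi_hat), 3 * est0$se + 1e-9)

  bare <- generate_genome(length = 1000L, seed = 78L)
  expect_error(generate_breakpoints(bare, n = 10L,
                                    enrichment_fraction = 0.5), "no planted")
})

test_that("the planted enrichment fraction is recovered within 3 standard errors", {
  for (seed in c(101L, 202L, 303L)) {
    t <- generate_genome(plants = list(
      list(at = 8000L, seq = "GGGTGGGTGGGTGGG", class = "quadruplex_G"),
      list(at = 15500L, seq = strrep("GGGA", 7L), class = "quadruplex_G"),
      list(at = 2000L, seq = "CCCCACCCC", class = "motif")), seed = seed)
    t <- generate_breakpoints(t, n = 1508L, enrichment_fraction = 0.5,
                              proximity = 10L, seed = seed + 1L)
    est <- estimate_enrichment_fraction(t$breakpoints, t)
    expect_lt(abs(est$pi_hat - 0.5), 3 * est$se)
  }
})

test_that("fixtures round-trip through the pipeline readers deterministically", {
  t <- generate_genome(length = 2500L, plants = list(
    list(at = 100L, seq = "GGGTGGGTGGGTGGG", class = "quadruplex_G")),
    seed = 81L)
  t <- generate_breakpoints(t, n = 100L, seed = 82L)
  dir <- tempfile("fixture")
  write_fixture(t, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genome.fasta", "breakpoints.tsv", "truth.json")))))

  back <- load_fixture(dir)
  expect_equal(back$genome$sequence, t$genome$sequence)
  expect_equal(back$genome$length, 2500L)
  expect_equal(back$deletions$five_prime, t$deletions$five_prime)
  expect_equal(back$deletions$three_prime, t$deletions$three_prime)
  expect_equal(back$truth$planted$start, t$planted$start)
  expect_equal(back$truth$enrichment_fraction, 0.5)

  # determinism under seed
  t2 <- generate_genome(length = 2500L, plants = list(
    list(at = 100L, seq = "GGGTGGGTGGGTGGG", class = "quadruplex_G")),
    seed = 81L)
  t2 <- generate_breakpoints(t2, n = 100L, seed = 82L)
  expect_identical(t2$genome$sequence, t$genome$sequence)
  expect_identical(t2$breakpoints, t$breakpoints)
})
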
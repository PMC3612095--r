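test_that("homogeneous circular repeats give flat curvature and bendability profiles", {
  pa <- paste(rep("A", 120L), collapse = "")
  cp <- curvature_profile(pa)
  expect_length(cp, 120L)
  expect_true(all(cp >= 0))
  expect_lt(diff(range(cp)), 1e-9)
  bp <- bendability_profile(pa)
  expect_lt(diff(range(bp)), 1e-9)
  expect_error(curvature_profile("ACGT"), "shorter")
})

test_that("phased A-tracts curve more than a composition-matched shuffle, per the 3D oracle", {
  set.seed(21)
  phased <- paste(replicate(20, paste0("AAAAA",
    paste(sample(c("A", "C", "G", "T"), 5L, TRUE), collapse = ""))),
    collapse = "")
  shuffled <- paste(sample(strsplit(phased, "")[[1L]]), collapse = "")
  expect_gt(max(curvature_profile(phased)), max(curvature_profile(shuffled)))
  # independent 3D path-reconstruction oracle agrees on the ordering
  expect_gt(max(oracle_curvature_3d(phased)), max(oracle_curvature_3d(shuffled)))
})

test_that("curvature profile is rotation-invariant on the circle", {
  set.seed(8)
  s <- random_seq(200L)
  p <- curvature_profile(s)
  for (k in c(1L, 13L, 101L)) {
    rot <- paste0(substr(s, 200L - k + 1L, 200L), substr(s, 1L, 200L - k))
    pr <- curvature_profile(rot)
    expect_equal(pr[(seq_len(200L) - 1L + k) %% 200L + 1L], p,
                 tolerance = 1e-9)
  }
})

test_that("doubling roll and tilt amplitudes does not decrease peak curvature", {
  set.seed(9)
  geo <- bend_geometry()
  geo2 <- geo
  geo2$dinucleotide$wedge <- geo2$dinucleotide$wedge * 2
  for (i in 1:5) {
    s <- random_seq(150L)
    expect_gte(max(curvature_profile(s, geometry = geo2)),
               max(curvature_profile(s, geometry = geo)))
  }
})

test_that("bendability window averages hand-computed trinucleotide means", {
  g <- bend_geometry()
  val <- function(tri) {
    b <- g$trinucleotide$bendability[match(tri, g$trinucleotide$triplet)]
    rng <- range(g$trinucleotide$bendability)
    (b - rng[1]) / (rng[2] - rng[1]) * 10
  }
  s <- "ACGTT"
  prof <- bendability_profile(s, window = 3L)
  # position 3 averages the triplets centered at 2, 3, 4
  expect_equal(prof[3L], mean(val(c("ACG", "CGT", "GTT"))), tolerance = 1e-12)
})

test_that("reverse-complement bendability is the reversed profile (complement-symmetric table)", {
  g <- bend_geometry()$trinucleotide
  rc <- vapply(g$triplet, function(t)
    chartr("ACGT", "TGCA", paste(rev(strsplit(t, "")[[1L]]), collapse = "")),
    character(1))
  expect_equal(g$bendability, g$bendability[match(rc, g$triplet)])
  set.seed(31)
  for (i in 1:5) {
    s <- random_seq(50L)
    fwd <- bendability_profile(s, window = 1L)
    rev_ <- bendability_profile(reverse_complement(s), window = 1L)
    # triplet centered on position p maps to the triplet centered on L+1-p
    expect_equal(rev_, fwd[50:1], tolerance = 1e-12)
  }
})

test_that("ratio profile masks low bendability and local maxima match a brute-force scan", {
  curv <- c(1, 2, 3, 4)
  expect_equal(ratio_profile(curv, curv), rep(1, 4))
  masked <- ratio_profile(curv, c(1, 0, 1, 1))
  expect_true(is.na(masked[2L]))
  expect_equal(genome_mean_ratio(masked), mean(curv[-2] / 1))
  expect_error(ratio_profile(curv, rep(0, 4)), "masked")

  # single planted peak
  prof <- c(rep(1, 40), 1.5, 2.5, 5, 2.5, 1.5, rep(1, 40))
  expect_equal(local_maxima(prof, min_separation = 10L), 43L)
  # plateau: leftmost reported
  plat <- c(rep(0, 30), 2, 2, 2, rep(0, 30))
  expect_equal(local_maxima(plat, min_separation = 10L, min_value = 0.5), 31L)

  set.seed(12)
  x <- runif(300)
  got <- sort(local_maxima(x, min_separation = 20L, min_value = -Inf))
  want <- integer(0)
  for (p in 1:300) {  # brute force over all positions, circular window
    idx <- ((p - 11L):(p + 9L)) %% 300L + 1L
    w <- x[idx]
    if (all(w <= x[p]) && all(w[1:10] < x[p])) want <- c(want, p)
  }
  expect_equal(got, sort(want))
})

test_that("peak bin density recovers planted counts in wrap-aware 0.1 kb bins", {
  L <- 1000L
  expect_equal(peak_bin_density(c(900L), 500L, L)$density, 0)
  d <- peak_bin_density(c(480L, 490L, 500L, 510L, 520L), 500L, L)
  expect_equal(d$density, 5 / 101 * 100)
  # bin wrapping the origin
  dw <- peak_bin_density(c(995L, 3L), 1000L, L)
  expect_equal(dw$start, 950L)
  expect_equal(dw$end, 50L)
  expect_equal(dw$density, 2 / 101 * 100)
})
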
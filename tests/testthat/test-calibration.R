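test_that("occupancy ratio evaluates the cross-species formula exactly", {
  expect_equal(occupancyRatio(1000, 400, 500, 200), 1.0)
  expect_equal(occupancyRatio(2000, 400, 500, 200), 2.0)
  ## depth invariance: scaling a fraction pair leaves OR unchanged
  expect_equal(occupancyRatio(1000 * 10, 400 * 10, 500, 200),
               occupancyRatio(1000, 400, 500, 200))
  expect_equal(occupancyRatio(1234, 567, 89 * 10, 321 * 10),
               occupancyRatio(1234, 567, 89, 321))
  expect_error(occupancyRatio(10, 0, 10, 10), "denominator")
  expect_error(occupancyRatio(10, 10, 0, 10), "denominator")
})

test_that("normalization factors are ratios of ORs and chain", {
  expect_equal(normalizationFactor(2, 1), 2)
  for (x in c(0.3, 1, 4.7)) expect_equal(normalizationFactor(x, x), 1)
  set.seed(1)
  for (k in 1:20) {
    ors <- stats::runif(3, 0.1, 5)
    expect_equal(normalizationFactor(ors[1], ors[3]),
                 normalizationFactor(ors[1], ors[2]) *
                   normalizationFactor(ors[2], ors[3]))
  }
  expect_error(normalizationFactor(-1, 2), "positive")
})

test_that("nFE tracks follow the scaled ChIP/input contract", {
  chip <- mkTrack(rep(10, 100), semantics = "raw")
  input <- mkTrack(rep(10, 100), semantics = "raw")
  t1 <- nfeTrack(chip, input, nf = 1)
  expect_equal(unname(trackValues(t1)$chrI), rep(1, 100))
  expect_equal(semantics(t1), "nFE")
  ## closed form for a single elevated ChIP bin: value c everywhere, 10c
  ## in one bin -> nFE = (10/109) / (1/100)
  v <- rep(3, 100); v[50] <- 30
  t2 <- nfeTrack(mkTrack(v, semantics = "raw"), input, nf = 1)
  expect_equal(trackValues(t2)$chrI[50], (30 / sum(v)) / (1 / 100))
  expect_equal(trackValues(t2)$chrI[1], (3 / sum(v)) / (1 / 100))
  ## exactly linear in NF
  t3 <- nfeTrack(mkTrack(v, semantics = "raw"), input, nf = 2)
  expect_equal(trackValues(t3)$chrI, trackValues(t2)$chrI * 2)
  ## invariant to uniform rescaling of raw vectors
  t4 <- nfeTrack(mkTrack(v * 7, semantics = "raw"),
                 mkTrack(rep(30, 100), semantics = "raw"), nf = 1)
  expect_equal(trackValues(t4)$chrI, trackValues(t2)$chrI)
  ## zero-input bins are masked, not smoothed
  iv <- rep(10, 100); iv[20] <- 0
  t5 <- nfeTrack(chip, mkTrack(iv, semantics = "raw"), nf = 1)
  expect_true(is.na(trackValues(t5)$chrI[20]))
  expect_error(nfeTrack(chip, mkTrack(rep(1, 50), semantics = "raw"), 1),
               "grids")
})

test_that("peak calling applies the run/merge/width rules", {
  tr <- mkTrack(c(1, 1, 3, 4, 1))
  pk <- callPeaks(tr, threshold = 2)
  expect_equal(length(pk), 1L)
  expect_equal(start(pk), 201)  # bins 3..4, 1-based bp
  expect_equal(end(pk), 400)
  expect_equal(mcols(pk)$summit, 350)  # center of the max-nFE bin
  expect_equal(mcols(pk)$maxNfe, 4)
  expect_equal(length(callPeaks(mkTrack(c(1.9, 0.5, 1)), 2)), 0L)
  expect_equal(length(callPeaks(mkTrack(c(3, 1, 3)), 2, mergeGapBins = 1)), 1L)
  expect_equal(length(callPeaks(mkTrack(c(3, 1, 3)), 2, mergeGapBins = 0)), 2L)
})

test_that("peak calling matches a direct-scan oracle on all 3-bin patterns", {
  vals <- expand.grid(b1 = c(0, 3), b2 = c(0, 3), b3 = c(0, 3))
  for (r in seq_len(nrow(vals))) {
    v <- as.numeric(vals[r, ])
    for (gap in 0:1) for (mw in 1:2) {
      pk <- callPeaks(mkTrack(v), threshold = 2, minWidthBins = mw,
                      mergeGapBins = gap)
      orc <- oraclePeaks(v, 2, gap, mw)
      expect_equal(length(pk), nrow(orc))
      if (nrow(orc)) {
        expect_equal(start(pk), (orc[, 1] - 1) * 100 + 1)
        expect_equal(end(pk), orc[, 2] * 100)
      }
    }
  }
})

test_that("lowering the peak threshold never loses peak territory", {
  set.seed(11)
  for (k in 1:5) {
    v <- stats::rlnorm(500, 0, 0.8)
    tHi <- callPeaks(mkTrack(v), threshold = 3)
    tLo <- callPeaks(mkTrack(v), threshold = 2)
    if (length(tHi)) {
      hits <- findOverlaps(tHi, tLo, type = "within")
      expect_equal(length(unique(queryHits(hits))), length(tHi))
    }
    expect_gte(sum(width(tLo)), sum(width(tHi)))
  }
})

test_that("peak overlap fraction agrees with an all-pairs oracle", {
  gr <- GRanges("chrI", IRanges(c(100, 500), width = 100))
  expect_equal(peakOverlapFraction(gr, gr), 1)
  expect_equal(peakOverlapFraction(gr, GenomicRanges::shift(gr, 10000)), 0)
  set.seed(4)
  mkRand <- function(n) {
    s <- sample(1e6 - 2000, n)
    GRanges("chrI", IRanges(s, width = sample(200:2000, n, replace = TRUE)))
  }
  a <- mkRand(50); b <- mkRand(50)
  brute <- mean(vapply(seq_along(a), function(i)
    any(start(a)[i] <= end(b) & end(a)[i] >= start(b)), TRUE))
  expect_equal(peakOverlapFraction(a, b), brute)
})

test_that("track correlation is Spearman's rho with average-rank ties", {
  v <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  expect_equal(trackCorrelation(mkTrack(v), mkTrack(v)), 1)
  mono <- 1:10
  expect_equal(trackCorrelation(mkTrack(as.numeric(mono)),
                                mkTrack(as.numeric(rev(mono)))), -1)
  set.seed(2)
  a <- sample(c(1, 1, 2, 3, 3, 3, 4, 5, 6, 6))
  b <- sample(c(2, 2, 2, 3, 4, 5, 5, 6, 7, 7))
  expect_equal(trackCorrelation(mkTrack(a), mkTrack(b)),
               stats::cor(rank(a), rank(b)))  # rank-then-Pearson oracle
  expect_error(trackCorrelation(mkTrack(c(1, NA, NA, 2)),
                                mkTrack(c(1, 2, 3, NA))), "fewer than 3")
})
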
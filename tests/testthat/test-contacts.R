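test_that("depth normalization thins or scales to the target total", {
  set.seed(1)
  M <- matrix(50, 40, 40)
  map <- mkMap(M)
  sc <- normalizeDepth(map, contactTotal(map), mode = "scale")
  expect_equal(as.matrix(contactCounts(sc)), M)
  sc2 <- normalizeDepth(map, 10000, mode = "scale")
  expect_equal(contactTotal(sc2), 10000)
  expect_error(normalizeDepth(map, contactTotal(map) * 2), "exceeds")
  ## thinning to half halves each pixel's expectation
  th <- vapply(1:40, function(k)
    as.matrix(contactCounts(normalizeDepth(map, contactTotal(map) / 2,
                                           seed = k)))[5, 9], 0)
  expect_lt(abs(mean(th) - 25) / 25, 0.05)
  ## two maps scaled to a common total match exactly
  mapB <- mkMap(matrix(30, 40, 40))
  both <- normalizeDepth(list(a = map, b = mapB), 5000, mode = "scale")
  expect_equal(contactTotal(both$a), contactTotal(both$b))
})

test_that("iterative correction equalizes row sums", {
  ## symmetric constant matrix is already balanced: equal weights
  bal <- balanceIterative(mkMap(matrix(1, 4, 4) + diag(4)))
  expect_equal(max(abs(diff(balancingWeights(bal)))), 0, tolerance = 1e-9)
  ## row/column scaling is inverted up to a global constant (2-bin case)
  B <- matrix(c(1, 2, 2, 1), 2)
  d <- c(2, 1)
  C <- diag(d) %*% B %*% diag(d)
  w <- balancingWeights(balanceIterative(mkMap(C), minMarginalFrac = 0))
  expect_equal(w[1] / w[2], d[2] / d[1], tolerance = 1e-7)
  ## simulated map: post-balance row-sum coefficient of variation < 1e-6
  map <- simulateContactMap(contactSimConfig("chrI", 300000, 1000,
                                             depth = 2e6, alpha = 1,
                                             seed = 12))
  mb <- balanceIterative(map)
  wb <- balancingWeights(mb)
  ok <- !is.na(wb)
  s <- (wb * as.numeric(contactCounts(mb) %*% ifelse(ok, wb, 0)))[ok]
  expect_lt(stats::sd(s) / mean(s), 1e-6)
  expect_error(balanceIterative(mkMap(matrix(0, 5, 5))), "empty")
})

test_that("the expected model reproduces a noiseless decay exactly", {
  cfg <- contactSimConfig("chrI", 100000, 1000, depth = 1e6, alpha = 1.2,
                          seed = 1)
  em <- simulateContactMap(cfg, noise = FALSE)
  em@weights <- rep(1, nBins(em))
  prof <- expectedCis(em)
  M <- as.matrix(contactCounts(em))
  lam <- vapply(0:20, function(s) M[1, 1 + s], 0)
  expect_equal(prof$expected[[1]][1:21], lam)
  ## observed/expected of the same map is exactly 1 everywhere off-mask
  ap <- pileup(em, data.frame(chrom = "chrI", pos1 = 30000, pos2 = 70000),
               flank = 5000)
  expect_equal(ap$centralScore, 1, tolerance = 1e-12)
  expect_true(all(abs(ap$matrix - 1) < 1e-12))
})

test_that("per-arm expected profiles separate arm-specific decays", {
  n <- 200; cb <- 100
  M <- matrix(1e-4, n, n)
  s <- abs(outer(1:n, 1:n, "-"))
  left <- 1:cb; right <- (cb + 1):n
  M[left, left] <- pmax(s[left, left], 1)^-1
  M[right, right] <- pmax(s[right, right], 1)^-1.5
  map <- mkMap(M, weights = rep(1, n))
  prof <- expectedCis(map, cenPos = 99500)  # midpoint of bin 100
  fitSlope <- function(e) {
    ss <- 2:60
    unname(stats::coef(stats::lm(log(e[ss + 1]) ~ log(ss)))[2])
  }
  expect_equal(fitSlope(prof$expected[[1]]), -1, tolerance = 1e-9)
  expect_equal(fitSlope(prof$expected[[2]]), -1.5, tolerance = 1e-9)
  ## a pooled (single-arm) expected recovers neither exponent
  pooled <- expectedCis(map)
  sPool <- fitSlope(pooled$expected[[1]])
  expect_gt(abs(sPool - -1), 0.02)
  expect_gt(abs(sPool - -1.5), 0.02)
  expect_error(expectedCis(mkMap(matrix(1, 3, 3), weights = rep(1, 3)),
                           cenPos = 1800), "shorter than 2 bins")
})

test_that("a distance-flat map has decay slope zero", {
  M <- matrix(7, 150, 150)
  curve <- decayCurve(mkMap(M))
  mid <- curve$distance > 4000 & curve$distance < 100000
  expect_true(all(abs(curve$slope[mid]) < 1e-9, na.rm = TRUE))
})

test_that("insulation scores are zero on a uniform map and find boundaries", {
  uni <- mkMap(matrix(3, 100, 100), weights = rep(1, 100))
  ins <- insulationScore(uni, windows = c(5000, 10000))
  expect_true(all(abs(ins$scores$minScore) < 1e-12, na.rm = TRUE))
  expect_equal(nrow(ins$boundaries), 0L)
  ## two dense blocks with sparse cross contacts: minimum at the junction
  n <- 60
  M <- matrix(0.05, n, n)
  M[1:30, 1:30] <- 1; M[31:60, 31:60] <- 1
  blocks <- mkMap(M, weights = rep(1, n))
  ins2 <- insulationScore(blocks, windows = 5000, delta = 0.01,
                          fdrThreshold = 1)
  minBin <- ins2$scores$bin[which.min(ins2$scores$minScore)]
  expect_lte(abs(minBin - 30.5), 1.5)
  expect_true(any(abs(ins2$boundaries$bin - 30.5) <= 1.5))
  ## invariant to global scaling of the matrix
  ins3 <- insulationScore(mkMap(M * 17, weights = rep(1, n)), windows = 5000)
  expect_equal(ins3$scores$minScore, ins2$scores$minScore)
})

test_that("pile-ups respect the distance filter and window bounds", {
  cfg <- contactSimConfig("chrI", 100000, 1000, depth = 1e6, alpha = 1,
                          seed = 2)
  em <- simulateContactMap(cfg, noise = FALSE)
  em@weights <- rep(1, nBins(em))
  near <- data.frame(chrom = "chrI", pos1 = c(20000, 40000),
                     pos2 = c(24000, 45000))
  expect_error(pileup(em, near, flank = 5000), "zero usable pairs")
  mix <- data.frame(chrom = "chrI", pos1 = c(20000, 30000, 2000),
                    pos2 = c(24000, 70000, 60000))
  ## first pair under minDist, third pair's window leaves the arm
  ap <- pileup(em, mix, flank = 5000)
  expect_equal(ap$nUsed, 1L)
  expect_equal(ap$nSkipped, 2L)
})

test_that("loop merge rule joins pixels below 2500 bp and splits above", {
  n <- 400
  s <- abs(outer(1:n, 1:n, "-"))
  lam <- 2000 * pmax(s, 1)^-1
  base <- lam
  mkDots <- function(pix) {
    M <- base
    for (p in pix) M[p[1], p[2]] <- M[p[2], p[1]] <- M[p[1], p[2]] * 30
    mkMap(M, weights = rep(1, n))
  }
  merged <- callLoops(mkDots(list(c(100, 200), c(102, 200))),
                      minDist = 5000)
  expect_equal(nrow(merged), 1L)
  split2 <- callLoops(mkDots(list(c(100, 200), c(103, 200))),
                      minDist = 5000)
  expect_equal(nrow(split2), 2L)
  expect_error(callLoops(mkMap(base)), "balanced")
})

test_that("loop classification follows centromere and cohesin rules", {
  ann <- toyAnnotation()
  peaks <- GRanges("chrI", IRanges(c(50001, 80001), width = 1000))
  loops <- data.frame(chrom = "chrI",
                      start1 = c(149500, 50200, 10000),
                      end1 = c(150500, 51200, 11000),
                      start2 = c(250000, 80200, 120000),
                      end2 = c(251000, 81200, 121000))
  loops$length <- (loops$start2 - loops$start1)
  cl <- classifyLoops(loops, ann, peaks)
  expect_equal(cl$category, c("centromere-originated", "cohesin-anchored",
                              "other"))
  sm <- attr(cl, "summary")
  expect_equal(sort(sm$category),
               sort(c("centromere-originated", "cohesin-anchored", "other")))
})

test_that("anchor-site flags equal a brute-force intersection oracle", {
  ann <- toyAnnotation()
  expect_equal(anchorSiteClassification(
    GRanges("chrI", IRanges(c(1000, 2000), width = 100)),
    data.frame(chrom = character(0), start1 = numeric(0), end1 = numeric(0),
               start2 = numeric(0), end2 = numeric(0),
               category = character(0)),
    ann)$anchorCount, 0)
  set.seed(6)
  sites <- GRanges("chrI", IRanges(sort(sample(280000, 40)), width = 600))
  a2 <- sort(sample(seq(10000, 280000, by = 100), 15))
  loops <- data.frame(chrom = "chrI", start1 = 149000, end1 = 151000,
                      start2 = a2, end2 = a2 + 1000)
  loops$length <- loops$start2 - loops$start1
  loops <- classifyLoops(loops, ann, GRanges())
  res <- anchorSiteClassification(sites, loops, ann, tolerance = 0)
  brute <- vapply(seq_along(sites), function(i) {
    s0 <- start(sites)[i] - 1; e0 <- end(sites)[i]
    any(s0 < loops$end2 & e0 > loops$start2)
  }, TRUE)
  expect_equal(unname(mcols(res$sites)$anchor), brute)
  expect_equal(res$anchorCount + res$nonAnchorCount, length(sites))
})

test_that("centromere-site distance bins are left-closed right-open", {
  ann <- GenomeAnnotation(c(chrI = 200000), c(chrI = 100000))
  map <- simulateContactMap(contactSimConfig("chrI", 200000, 1000,
                                             depth = 2e6, alpha = 1,
                                             cenPos = 100000,
                                             cenInsulation = 0.9, seed = 4))
  map <- balanceIterative(map)
  ## site summit exactly 25 kb from the centromere
  sites <- GRanges("chrI", IRanges(c(124701, 139701, 159701), width = 600))
  res <- cenContactByDistance(list(chrI = map), sites, ann,
                              distanceBins = c(0, 25000, 50000, 100000),
                              flank = 3000)
  expect_equal(res$n, c(0L, 2L, 1L))
})
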
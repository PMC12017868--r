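annSmall <- GenomeAnnotation(c(chrI = 100000), c(chrI = 50000))

test_that("fixed seeds give bit-identical synthetic outputs", {
  cfg <- chipSimConfig(annSmall, 1e5, 2, 1e5, boundFraction = 0.5, seed = 7)
  s1 <- simulateChipCounts(cfg)
  s2 <- simulateChipCounts(cfg)
  expect_identical(trackValues(s1$chip), trackValues(s2$chip))
  expect_identical(s1$spikeTotals, s2$spikeTotals)
  cc <- contactSimConfig("chrI", 100000, 1000, 1e5, alpha = 1, seed = 7)
  expect_identical(as.matrix(contactCounts(simulateContactMap(cc))),
                   as.matrix(contactCounts(simulateContactMap(cc))))
})

test_that("halving the bound ChIP mass halves the expected occupancy ratio", {
  cfgA <- chipSimConfig(annSmall, 1e5, 2, 1e5, boundFraction = 0.5, seed = 1)
  cfgB <- chipSimConfig(annSmall, 1e5, 2, 1e5, boundFraction = 0.25, seed = 1)
  expect_equal(cfgB$seed, cfgA$seed)
  expect_equal(simulateChipCounts(cfgB)$trueOR / simulateChipCounts(cfgA)$trueOR,
               0.5)
  ## estimated ORs across replicates agree with the construction
  est <- vapply(1:30, function(k) {
    sA <- simulateChipCounts(chipSimConfig(annSmall, 1e5, 2, 2e5,
                                           boundFraction = 0.5,
                                           seed = 100 + k))
    sB <- simulateChipCounts(chipSimConfig(annSmall, 1e5, 2, 2e5,
                                           boundFraction = 0.25,
                                           seed = 500 + k))
    orOf <- function(s) occupancyRatio(s$targetTotals[["chip"]],
                                       s$spikeTotals[["chip"]],
                                       s$targetTotals[["input"]],
                                       s$spikeTotals[["input"]])
    orOf(sB) / orOf(sA)
  }, 0)
  expect_lt(abs(mean(est) - 0.5) / 0.5, 0.05)
})

test_that("a single enriched site concentrates ChIP density as configured", {
  sites <- GRanges("chrI", IRanges(40001, 40600))
  mcols(sites)$enrichment <- 10
  cfg <- chipSimConfig(annSmall, 1e5, 2, 1e6, siteEnrichments = sites,
                       boundFraction = 0.5, seed = 3)
  sim <- simulateChipCounts(cfg)
  v <- trackValues(sim$chip)$chrI
  siteBins <- 401:406  # bins fully inside the site
  bgBins <- setdiff(seq_along(v), 399:409)
  perBinBg <- mean(v[bgBins])
  for (b in siteBins) {
    expectCount <- 10 * perBinBg
    expect_lt(abs(v[b] - expectCount), 3 * sqrt(expectCount) + 3 * sqrt(perBinBg) * 10)
  }
})

test_that("contact generator conserves depth and honors the dot model", {
  cfg <- contactSimConfig("chrI", 300000, 1000, depth = 1e6, alpha = 1,
                          seed = 5)
  map <- simulateContactMap(cfg)
  expect_lt(abs(contactTotal(map) - 1e6), 4 * sqrt(1e6))
  ## insulation factor 1.0 leaves the expectation untouched
  noCen <- simulateContactMap(contactSimConfig("chrI", 100000, 1000, 1e5,
                                               alpha = 1, seed = 2),
                              noise = FALSE)
  cenOne <- simulateContactMap(contactSimConfig("chrI", 100000, 1000, 1e5,
                                                alpha = 1, cenPos = 50000,
                                                cenInsulation = 1, seed = 2),
                               noise = FALSE)
  expect_equal(as.matrix(contactCounts(noCen)), as.matrix(contactCounts(cenOne)))
  ## dot pixel intensity is E times the same-distance background
  lp <- data.frame(anchor1 = 100000, anchor2 = 200000, enrichment = 5,
                   width = 300)
  dm <- simulateContactMap(contactSimConfig("chrI", 300000, 1000, 1e6,
                                            alpha = 1, loops = lp, seed = 2),
                           noise = FALSE)
  M <- as.matrix(contactCounts(dm))
  a1 <- 101; a2 <- 201  # anchor bins
  bg <- M[31, 131]      # same bin distance, away from the dot
  expect_equal(M[a1, a2] / bg, 5, tolerance = 1e-6)
  ## simulated mean over replicates matches the analytic intensity
  sims <- vapply(1:30, function(k) {
    m <- simulateContactMap(contactSimConfig("chrI", 300000, 1000, 1e6,
                                             alpha = 1, loops = lp,
                                             seed = 1000 + k))
    as.matrix(contactCounts(m))[a1, a2]
  }, 0)
  expect_lt(abs(mean(sims) - M[a1, a2]) / M[a1, a2], 0.1)
})

test_that("generator input validation catches impossible configurations", {
  expect_error(contactSimConfig("chrI", 1e5, 1000, 1e5, alpha = 0), "alpha")
  expect_error(contactSimConfig("chrI", 1e5, 1000, 1e5, alpha = 1,
                                loops = data.frame(anchor1 = 500,
                                                   anchor2 = 500,
                                                   enrichment = 2,
                                                   width = 100)),
               "anchors equal")
  badSite <- GRanges("chrI", IRanges(99000, 101000))
  mcols(badSite)$enrichment <- 2
  expect_error(chipSimConfig(annSmall, 1e5, 2, 1e5,
                             siteEnrichments = badSite), "outside")
})

test_that("scenario presets encode the intended loop architecture", {
  wt <- scenarioPreset("wt_like", seed = 1)
  mut <- scenarioPreset("wpl1_eco1_like", seed = 1)
  expect_error(scenarioPreset("unknown"), "arg")
  expect_true(all(wt$groundTruth$loops$length < 50000))
  cen <- centromeres(mut$annotation)
  dCen <- pmin(abs(mut$groundTruth$loops$anchor1 - cen[mut$groundTruth$loops$chrom]),
               abs(mut$groundTruth$loops$anchor2 - cen[mut$groundTruth$loops$chrom]))
  expect_true(all(dCen < 5000))
  expect_gt(mean(mut$groundTruth$loops$length) /
              mean(wt$groundTruth$loops$length), 3)
  expect_equal(mut$groundTruth$ratioFold, 2.53)
})
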
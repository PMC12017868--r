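test_that("site quantification is the window mean around the summit", {
  tr <- mkTrack(rep(2.5, 100))
  sites <- GRanges("chrI", IRanges(c(1001, 5001), width = 600))
  expect_equal(quantifyAtSites(tr, sites), c(2.5, 2.5))
  ## hand-computed mean over the 4 bins of a 400-bp window
  v <- rep(1, 100); v[21:24] <- c(2, 4, 6, 8)
  tr2 <- mkTrack(v)
  site <- GRanges("chrI", IRanges(1901, 2500))  # summit at 2200 bp
  expect_equal(quantifyAtSites(tr2, site, window = 400), mean(c(2, 4, 6, 8)))
  ## all-masked window gives NA
  v[21:24] <- NA
  expect_true(is.na(quantifyAtSites(mkTrack(v), site, window = 400)))
})

test_that("quartile grouping splits sorted sites with remainders low", {
  vals <- c(8, 1, 5, 3, 7, 2, 6, 4)
  q <- quartileGroups(vals)
  expect_equal(as.character(q[vals >= 7]), c("Q4", "Q4"))
  expect_equal(as.character(q[vals <= 2]), c("Q1", "Q1"))
  q10 <- quartileGroups(as.numeric(1:10))
  expect_equal(unname(table(q10)), array(c(3L, 3L, 2L, 2L)))
  expect_error(quartileGroups(c(1, 2, 3)), "at least 4")
  ## ties at the boundary follow the documented sort-then-split rule
  vals2 <- c(1, 2, 2, 2, 3, 4, 5, 6)
  coord <- c(10, 20, 30, 40, 50, 60, 70, 80)
  q2 <- quartileGroups(vals2, tieBreak = coord)
  ord <- order(vals2, coord)
  labels <- rep(paste0("Q", 1:4), each = 2)
  expect_equal(as.character(q2)[ord], labels)
  ## permutation invariance
  set.seed(3)
  vals3 <- stats::runif(23)
  q3 <- quartileGroups(vals3, tieBreak = seq_along(vals3))
  perm <- sample(23)
  q3p <- quartileGroups(vals3[perm], tieBreak = seq_along(vals3)[perm])
  expect_equal(as.character(q3p), as.character(q3)[perm])
})

test_that("ratio analysis normalizes to the control median", {
  ctrl <- c(1.2, 0.8, 1.0, 1.5, 0.9)
  same <- ratioAnalysis(ctrl * 2, rep(2, 5), ctrl)
  expect_equal(same$medianFold, 1)
  doubled <- ratioAnalysis(ctrl * 4, rep(2, 5), ctrl)
  expect_equal(doubled$medianFold, 2)
  ## invariant to common rescaling of numerator and denominator tracks
  a <- c(2, 3, 4); b <- c(1, 2, 2)
  r1 <- ratioAnalysis(a, b, ctrl)
  r2 <- ratioAnalysis(a * 11, b * 11, ctrl)
  expect_equal(r1$normalized, r2$normalized)
  ## zero denominators mask the site
  r3 <- ratioAnalysis(c(1, 2), c(0, 2), ctrl)
  expect_true(is.na(r3$ratios[1]))
  expect_error(ratioAnalysis(a, b, numeric(0)), "empty")
})

test_that("aggregate profiles report mean and a normal-theory 95% band", {
  tr <- mkTrack(rep(4, 200))
  sites <- GRanges("chrI", IRanges(c(5001, 10001), width = 200))
  pr <- aggregateProfile(tr, sites, flank = 1000)
  expect_true(all(pr$mean == 4))
  expect_true(all(pr$upper - pr$lower == 0))
  expect_equal(nrow(pr), 2 * 10 + 1)
  expect_error(aggregateProfile(tr, sites[1], 1000), "at least 2")
  ## duplicated single site: aggregate equals that site's own profile row
  v <- stats::rnorm(200)^2
  tr2 <- mkTrack(v)
  two <- c(sites[1], sites[1])
  pr2 <- aggregateProfile(tr2, two, flank = 500)
  b0 <- 52  # summit bin of site 1 (summit at 5100 bp)
  expect_equal(pr2$mean, v[(b0 - 5):(b0 + 5)])
})

test_that("normal-theory band width is close to a bootstrap band", {
  set.seed(8)
  v <- stats::rlnorm(3000, 0, 0.5)
  tr <- mkTrack(v)
  starts <- seq(2001, 290001, length.out = 50)
  sites <- GRanges("chrI", IRanges(as.integer(starts), width = 200))
  pr <- aggregateProfile(tr, sites, flank = 500)
  center <- (nrow(pr) + 1) / 2
  ## bootstrap the 50 per-site center values
  b0 <- floor((start(sites) - 1 + 100) / 100) + 1
  centerVals <- v[b0]
  boots <- vapply(1:10000, function(k)
    mean(sample(centerVals, replace = TRUE)), 0)
  bootWidth <- diff(stats::quantile(boots, c(0.025, 0.975)))
  normWidth <- pr$upper[center] - pr$lower[center]
  expect_lt(abs(normWidth - bootWidth) / bootWidth, 0.15)
})

test_that("profile heatmaps order rows by the sort key, stably", {
  v <- stats::runif(300)
  tr <- mkTrack(v)
  sites <- GRanges("chrI", IRanges(seq(2001, 26001, by = 3000), width = 200))
  key <- c(3, 1, 3, 2, 5, 4, 3, 2, 1)
  hm <- profileHeatmap(tr, sites, flank = 500, sortKey = key)
  expect_equal(attr(hm, "siteOrder"), order(-key))  # argsort oracle
  ## equal keys preserve original order
  hmEq <- profileHeatmap(tr, sites, flank = 500,
                         sortKey = rep(1, length(sites)))
  expect_equal(attr(hmEq, "siteOrder"), seq_along(sites))
  ## key = row max puts the global maximum in the first row
  rowMax <- apply(profileHeatmap(tr, sites, flank = 500), 1, max, na.rm = TRUE)
  hm2 <- profileHeatmap(tr, sites, flank = 500, sortKey = rowMax)
  expect_equal(max(hm2[1, ], na.rm = TRUE), max(rowMax))
})

test_that("centromere distance annotation applies the strict exclusion rule", {
  ann <- toyAnnotation()
  sites <- GRanges("chrI", IRanges(c(149701, 144701, 49701), width = 600))
  # summits at 150000 (on CEN), 145000 (5 kb), 50000 (100 kb)
  out <- annotateCentromereDistance(sites, ann, exclusion = 5000)
  expect_equal(mcols(out)$distanceToCen, c(0, 5000, 100000))
  expect_equal(mcols(out)$isCentromeric, c(TRUE, FALSE, FALSE))
  orphan <- GRanges("chrX", IRanges(1, 100))
  expect_error(annotateCentromereDistance(orphan, ann), "without centromere")
  ## Q4-within-100-kb fraction matches direct counting
  set.seed(5)
  n <- 40
  d <- stats::runif(n, 0, 140000)
  scc2 <- stats::runif(n) + 2 * (d < 100000)
  starts <- as.integer(150000 - d - 300 + 1)
  gr <- annotateCentromereDistance(
    GRanges("chrI", IRanges(pmax(1L, starts), width = 600)), ann)
  q <- quartileGroups(scc2)
  frac <- mean(mcols(gr)$distanceToCen[q == "Q4"] < 100000)
  brute <- sum(q == "Q4" & mcols(gr)$distanceToCen < 100000) / sum(q == "Q4")
  expect_equal(frac, brute)
})
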
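## Synthetic dual-genome ChIP read counts and cis contact maps with known
## ground truth.  ChIP reads are multinomial over genome bins plus one
## abstract spike-in compartment; contacts are Poisson around a power-law
## distance decay with injected loop dots, domain blocks and centromere
## attenuation.

#' ChIP simulation configuration
#'
#' Emulates a calibrated ChIP-seq experiment in which target-species cells
#' are mixed with spike-in cells at a fixed cell-equivalent ratio.  The
#' input fraction samples both genomes proportionally to DNA amount; the
#' ChIP fraction concentrates target reads at binding sites proportionally
#' to per-site enrichment factors and a global chromatin-bound fraction.
#'
#' @param annotation `GenomeAnnotation` of the target genome.
#' @param spikeGenomeSize spike-in genome size in bp (modeled as a single
#'   uniformly covered compartment).
#' @param mixingRatio target:spike cell-equivalent ratio (e.g. 2 or 5).
#' @param depth total reads per fraction.
#' @param siteEnrichments `GRanges` of binding sites with an `enrichment`
#'   metadata column (factors >= 1).
#' @param boundFraction global chromatin-bound fraction of the target ChIP
#'   material; the quantity the occupancy ratio estimates (relative to the
#'   spike).
#' @param spikeBoundFraction same for the spike genome (default 1).
#' @param inputNoise coefficient of variation of multiplicative bin-level
#'   noise on the input sampling weights (0 = perfectly uniform input).
#' @param binSize track bin size in bp (default 100).
#' @param seed integer RNG seed.
#' @return validated config list of class `ChipSimConfig`.
#' @export
chipSimConfig <- function(annotation, spikeGenomeSize, mixingRatio, depth,
                          siteEnrichments = GRanges(), boundFraction = 1,
                          spikeBoundFraction = 1, inputNoise = 0,
                          binSize = 100, seed = 1) {
  stopifnot(is(annotation, "GenomeAnnotation"),
            spikeGenomeSize > 0, mixingRatio > 0, depth > 0,
            boundFraction > 0, spikeBoundFraction > 0, inputNoise >= 0)
  e <- mcols(siteEnrichments)$enrichment
  if (length(siteEnrichments) > 0) {
    if (is.null(e)) stop("siteEnrichments needs an 'enrichment' column")
    if (any(e < 1)) stop("site enrichment factors must be >= 1")
    sl <- chromLengths(annotation)
    sn <- as.character(seqnames(siteEnrichments))
    if (!all(sn %in% names(sl)) || any(end(siteEnrichments) > sl[sn]))
      stop("site outside genome")
  }
  structure(list(annotation = annotation, spikeGenomeSize = spikeGenomeSize,
                 mixingRatio = mixingRatio, depth = depth,
                 siteEnrichments = siteEnrichments,
                 boundFraction = boundFraction,
                 spikeBoundFraction = spikeBoundFraction,
                 inputNoise = inputNoise, binSize = as.integer(binSize),
                 seed = as.integer(seed)),
            class = "ChipSimConfig")
}

## per-bin enrichment multiplier: 1 + sum over overlapping sites of
## (e - 1) * fraction of the bin covered by the site
.binEnrichment <- function(config) {
  ann <- config$annotation
  sl <- chromLengths(ann)
  bs <- config$binSize
  out <- lapply(names(sl), function(nm) {
    n <- ceiling(sl[[nm]] / bs)
    mult <- rep(1, n)
    sites <- config$siteEnrichments
    sites <- sites[as.character(seqnames(sites)) == nm]
    for (k in seq_along(sites)) {
      s0 <- start(sites)[k] - 1; e0 <- end(sites)[k]
      b <- binsOfInterval(s0, e0, bs, n)
      binLo <- (b - 1) * bs; binHi <- pmin(b * bs, sl[[nm]])
      cov <- (pmin(e0, binHi) - pmax(s0, binLo)) / (binHi - binLo)
      mult[b] <- mult[b] + (mcols(sites)$enrichment[k] - 1) * cov
    }
    mult
  })
  names(out) <- names(sl)
  out
}

#' Simulate calibrated ChIP-seq read counts
#'
#' Draws `depth` reads per fraction multinomially over the target-genome
#' bins plus one spike-in compartment.  Input sampling weights are
#' proportional to DNA amount (mixing ratio x bp), optionally perturbed by
#' gamma-distributed bin noise; ChIP weights additionally carry the bound
#' fraction and per-site enrichment.  The expected spike share of input
#' reads is `S / (mixingRatio * T + S)` for target genome size `T` and
#' spike size `S`.
#'
#' @param config `ChipSimConfig`.
#' @return list with `chip` and `input` raw `BinnedTrack`s (target genome),
#'   `targetTotals` / `spikeTotals` (named `c(chip=, input=)` read counts)
#'   and `trueOR`, the analytic expectation of the occupancy ratio under
#'   the sampling weights.
#' @export
simulateChipCounts <- function(config) {
  stopifnot(inherits(config, "ChipSimConfig"))
  ann <- config$annotation
  sl <- chromLengths(ann)
  bs <- config$binSize
  nb <- vapply(names(sl), function(nm) ceiling(sl[[nm]] / bs), 0)
  binBp <- lapply(names(sl), function(nm) {
    n <- nb[[nm]]
    w <- rep(bs, n); w[n] <- sl[[nm]] - (n - 1) * bs
    w
  })
  names(binBp) <- names(sl)
  enr <- .binEnrichment(config)
  withr::with_seed(config$seed, {
    noise <- lapply(binBp, function(w) {
      if (config$inputNoise > 0) {
        shp <- 1 / config$inputNoise^2
        stats::rgamma(length(w), shape = shp, rate = shp)
      } else rep(1, length(w))
    })
    inW <- unlist(lapply(names(sl), function(nm)
      config$mixingRatio * binBp[[nm]] * noise[[nm]]), use.names = FALSE)
    chW <- unlist(lapply(names(sl), function(nm)
      config$mixingRatio * config$boundFraction * binBp[[nm]] *
        noise[[nm]] * enr[[nm]]), use.names = FALSE)
    inSpike <- config$spikeGenomeSize
    chSpike <- config$spikeBoundFraction * config$spikeGenomeSize
    inputDraw <- stats::rmultinom(1, config$depth, c(inW, inSpike))[, 1]
    chipDraw <- stats::rmultinom(1, config$depth, c(chW, chSpike))[, 1]
  })
  split2 <- function(draw) {
    tgt <- draw[-length(draw)]
    idx <- rep(names(sl), nb)
    vals <- split(unname(tgt), factor(idx, levels = names(sl)))
    list(values = vals, spike = draw[length(draw)])
  }
  inp <- split2(inputDraw); chp <- split2(chipDraw)
  trueOR <- (sum(unlist(lapply(names(sl), function(nm)
    config$mixingRatio * config$boundFraction * binBp[[nm]] * enr[[nm]]))) /
      chSpike) /
    (config$mixingRatio * sum(sl) / inSpike)
  list(chip = BinnedTrack(bs, chp$values, sl, "raw"),
       input = BinnedTrack(bs, inp$values, sl, "raw"),
       targetTotals = c(chip = sum(unlist(chp$values)),
                        input = sum(unlist(inp$values))),
       spikeTotals = c(chip = unname(chp$spike),
                       input = unname(inp$spike)),
       trueOR = trueOR)
}

#' Contact-map simulation configuration
#'
#' @param chrom chromosome name.
#' @param chromLength chromosome length in bp.
#' @param binSize matrix bin size in bp.
#' @param depth expected total contacts (off-diagonal pairs counted twice).
#' @param alpha power-law decay exponent (> 0); background intensity is
#'   proportional to `s^-alpha` at bin distance `s`.
#' @param loops `data.frame` with columns `anchor1`, `anchor2` (bp),
#'   `enrichment` (>= 1) and `width` (Gaussian sigma in bp, truncated at
#'   3 sigma, or the plateau radius for `dotShape = "plateau"`); may be
#'   empty.
#' @param domains `data.frame` with columns `start`, `end` (bp), `boost`;
#'   pairs with both ends inside a domain are multiplied by `boost`.
#' @param cenPos centromere midpoint in bp (`NA` = none).
#' @param cenInsulation multiplier in (0, 1] applied to pairs spanning the
#'   centromere (1 = no attenuation).
#' @param dotShape `"gaussian"` (default) or `"plateau"`: a plateau dot
#'   multiplies all pixels within `width` bp (Chebyshev) of the anchor
#'   pixel by exactly `enrichment`, carrying far less total mass than a
#'   Gaussian of comparable footprint — useful when the injected
#'   enrichment itself must be read back from small maps without biasing
#'   the distance-expected model.
#' @param seed integer RNG seed.
#' @return validated config list of class `ContactSimConfig`.
#' @export
contactSimConfig <- function(chrom, chromLength, binSize, depth, alpha = 1,
                             loops = NULL, domains = NULL, cenPos = NA,
                             cenInsulation = 1,
                             dotShape = c("gaussian", "plateau"), seed = 1) {
  dotShape <- match.arg(dotShape)
  if (alpha <= 0) stop("alpha must be > 0")
  stopifnot(depth > 0, cenInsulation > 0, cenInsulation <= 1)
  if (is.null(loops))
    loops <- data.frame(anchor1 = numeric(0), anchor2 = numeric(0),
                        enrichment = numeric(0), width = numeric(0))
  if (is.null(domains))
    domains <- data.frame(start = numeric(0), end = numeric(0),
                          boost = numeric(0))
  if (nrow(loops)) {
    if (any(loops$anchor1 == loops$anchor2)) stop("loop anchors equal")
    if (any(loops$enrichment < 1)) stop("loop enrichment must be >= 1")
    if (any(pmax(loops$anchor1, loops$anchor2) > chromLength) ||
        any(pmin(loops$anchor1, loops$anchor2) < 0))
      stop("loop anchor outside chromosome")
    flip <- loops$anchor1 > loops$anchor2
    tmp <- loops$anchor1[flip]
    loops$anchor1[flip] <- loops$anchor2[flip]
    loops$anchor2[flip] <- tmp
  }
  structure(list(chrom = chrom, chromLength = chromLength,
                 binSize = as.integer(binSize), depth = depth, alpha = alpha,
                 loops = loops, domains = domains, cenPos = cenPos,
                 cenInsulation = cenInsulation, dotShape = dotShape,
                 seed = as.integer(seed)),
            class = "ContactSimConfig")
}

## expected intensity over the upper triangle (matrix), scaled to depth
.contactLambda <- function(config) {
  n <- as.integer(ceiling(config$chromLength / config$binSize))
  bs <- config$binSize
  ## (i, j) upper triangle including diagonal
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  s <- j - i
  lam <- pmax(s, 1)^(-config$alpha)
  if (nrow(config$domains)) {
    ci <- binCenter(i, bs); cj <- binCenter(j, bs)
    for (k in seq_len(nrow(config$domains))) {
      d <- config$domains[k, ]
      inside <- ci >= d$start & ci < d$end & cj >= d$start & cj < d$end
      lam[inside] <- lam[inside] * d$boost
    }
  }
  if (!is.na(config$cenPos) && config$cenInsulation < 1) {
    cb <- binOf(config$cenPos, bs)
    span <- i < cb & j > cb
    lam[span] <- lam[span] * config$cenInsulation
  }
  if (nrow(config$loops)) {
    plateau <- identical(config$dotShape, "plateau")
    for (k in seq_len(nrow(config$loops))) {
      lp <- config$loops[k, ]
      a1 <- binOf(lp$anchor1, bs); a2 <- binOf(lp$anchor2, bs)
      sig <- lp$width / bs
      r <- max(0L, ceiling(if (plateau) sig else 3 * sig))
      hit <- abs(i - a1) <= r & abs(j - a2) <= r
      if (!any(hit)) next
      boost <- if (plateau) {
        lp$enrichment
      } else {
        d2 <- (i[hit] - a1)^2 + (j[hit] - a2)^2
        1 + (lp$enrichment - 1) *
          (if (sig > 0) exp(-d2 / (2 * sig^2)) else as.numeric(d2 == 0))
      }
      lam[hit] <- lam[hit] * boost
    }
  }
  ## scale so the symmetric total (off-diagonal twice) matches depth
  tot <- sum(lam[s > 0]) * 2 + sum(lam[s == 0])
  lam <- lam * config$depth / tot
  list(n = n, i = i, j = j, lambda = lam)
}

#' Simulate a cis contact map
#'
#' Expected intensity `lambda(i, j) = C * |i-j|^-alpha` times domain
#' boosts, loop-dot boosts (2-D Gaussian truncated at 3 sigma) and the
#' centromere attenuation for pairs spanning the centromere; `C` is set so
#' the symmetric total matches `depth`.  Counts are Poisson draws over the
#' upper triangle, mirrored to a symmetric matrix.  With `noise = FALSE`
#' the expectation itself is returned as the map (useful for exactness
#' checks).
#'
#' @param config `ContactSimConfig`.
#' @param noise draw Poisson counts (default) or return the expectation.
#' @return `ContactMap`; the injected loop table (with anchor bins) is
#'   attached as `attr(map, "groundTruth")`.
#' @export
simulateContactMap <- function(config, noise = TRUE) {
  stopifnot(inherits(config, "ContactSimConfig"))
  lam <- .contactLambda(config)
  x <- if (noise) {
    withr::with_seed(config$seed, stats::rpois(length(lam$lambda), lam$lambda))
  } else lam$lambda
  keep <- x != 0
  m <- sparseMatrix(i = lam$i[keep], j = lam$j[keep], x = x[keep],
                    dims = c(lam$n, lam$n))
  map <- ContactMap(config$chrom, config$binSize, config$chromLength, m)
  gt <- config$loops
  if (nrow(gt)) {
    gt$bin1 <- binOf(gt$anchor1, config$binSize)
    gt$bin2 <- binOf(gt$anchor2, config$binSize)
    gt$length <- abs(gt$anchor2 - gt$anchor1)
  }
  attr(map, "groundTruth") <- gt
  map
}
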
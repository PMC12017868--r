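## Contact-map analytics: depth normalization, iterative-correction
## balancing, per-arm expected model, contact-versus-distance decay,
## insulation scores, simplified HICCUPS-style loop calling with four
## local backgrounds, observed/expected pile-ups (APA), loop
## classification and anchor-site labeling.

#' Normalize contact maps to a common depth
#'
#' Default mode is seeded binomial thinning of the stored counts to the
#' target total (each pixel's expectation scales by `target/total`);
#' `"scale"` multiplies counts so totals match exactly.
#'
#' @param maps a `ContactMap` or list of them.
#' @param targetTotal target symmetric total.
#' @param mode `"subsample"` (binomial thinning) or `"scale"`.
#' @param seed RNG seed for thinning.
#' @return same shape as `maps`.
#' @export
normalizeDepth <- function(maps, targetTotal, mode = c("subsample", "scale"),
                           seed = 1) {
  mode <- match.arg(mode)
  one <- function(map, sd1) {
    tot <- contactTotal(map)
    if (mode == "scale") {
      map@counts <- map@counts * (targetTotal / tot)
      return(map)
    }
    if (targetTotal > tot)
      stop("target total exceeds map total in subsampling mode")
    p <- targetTotal / tot
    x <- map@counts@x
    map@counts@x <- withr::with_seed(sd1,
      as.numeric(stats::rbinom(length(x), size = as.integer(round(x)),
                               prob = p)))
    map
  }
  if (is(maps, "ContactMap")) return(one(maps, as.integer(seed)))
  out <- lapply(seq_along(maps), function(k)
    one(maps[[k]], as.integer(seed) + k - 1L))
  names(out) <- names(maps)
  out
}

#' Balance a contact map by iterative correction
#'
#' Finds per-bin weights `w` such that the balanced matrix
#' `w_i * c_ij * w_j` has equal row sums on unmasked bins.  Bins whose
#' raw marginal falls below `minMarginalFrac` times the median non-zero
#' marginal are masked first (weight `NA`).  Weights are scaled so the
#' mean balanced row sum is 1.  Deterministic given inputs.
#'
#' @param map `ContactMap`.
#' @param tol convergence tolerance on the max relative row-sum deviation
#'   (default 1e-8).
#' @param maxIter maximum iterations (default 500).
#' @param minMarginalFrac coverage floor as a fraction of the median
#'   non-zero marginal (default 0.1).
#' @return `ContactMap` with `weights` filled in.
#' @export
balanceIterative <- function(map, tol = 1e-8, maxIter = 500,
                             minMarginalFrac = 0.1) {
  C <- map@counts
  n <- nBins(map)
  marg <- Matrix::rowSums(C)
  if (all(marg == 0)) stop("cannot balance an empty map")
  floorVal <- minMarginalFrac * stats::median(marg[marg > 0])
  unmasked <- marg >= floorVal & marg > 0
  if (sum(unmasked) < 2) stop("fewer than 2 unmasked bins")
  w <- ifelse(unmasked, 1, 0)
  res <- Inf
  for (it in seq_len(maxIter)) {
    s <- w * as.numeric(C %*% w)
    su <- s[unmasked]
    res <- max(abs(su / mean(su) - 1))
    if (res < tol) break
    w[unmasked] <- w[unmasked] / (su / mean(su))
  }
  if (res >= tol)
    stop(sprintf("iterative correction did not converge in %d iterations (residual %.3g)",
                 maxIter, res))
  s <- w * as.numeric(C %*% w)
  w <- w / sqrt(mean(s[unmasked]))
  w[!unmasked] <- NA_real_
  map@weights <- w
  map
}

## dense balanced matrix; masked bins give NA rows/columns
balancedDense <- function(map) {
  if (!length(map@weights)) stop("map is not balanced")
  w <- map@weights
  M <- as.matrix(map@counts) * outer(w, w)
  M
}

## arm index ranges split at the centromere bin (assigned to the left arm)
armRanges <- function(n, binSize, cenPos = NA) {
  if (is.na(cenPos)) return(list(seq_len(n)))
  cb <- binOf(cenPos, binSize)
  if (cb >= n) return(list(seq_len(n)))
  list(seq_len(cb), (cb + 1L):n)
}

#' Per-arm expected contact profile
#'
#' For each chromosome arm (split at the centromere), the expected value
#' at bin distance `s` is the mean balanced contact over all unmasked
#' pairs at that distance within the arm.
#'
#' @param map balanced `ContactMap`.
#' @param cenPos centromere midpoint in bp, or `NA` to treat the whole
#'   chromosome as one arm.
#' @return object of class `ExpectedProfile`: list with `arms` (bin index
#'   vectors) and `expected` (numeric vectors indexed by distance + 1).
#' @export
expectedCis <- function(map, cenPos = NA) {
  B <- balancedDense(map)
  arms <- armRanges(nBins(map), map@binSize, cenPos)
  expected <- lapply(arms, function(idx) {
    m <- length(idx)
    if (m < 2) stop("arm shorter than 2 bins")
    sub <- B[idx, idx, drop = FALSE]
    vapply(0:(m - 1), function(s) {
      v <- sub[cbind(1:(m - s), (1 + s):m)]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, 0)
  })
  structure(list(chrom = map@chrom, binSize = map@binSize, cenPos = cenPos,
                 arms = arms, expected = expected),
            class = "ExpectedProfile")
}

## dense observed/expected matrix; NA across arms and on masked bins
obsExpDense <- function(map, expProfile) {
  B <- balancedDense(map)
  n <- nBins(map)
  OE <- matrix(NA_real_, n, n)
  for (a in seq_along(expProfile$arms)) {
    idx <- expProfile$arms[[a]]
    ex <- expProfile$expected[[a]]
    m <- length(idx)
    s <- abs(outer(seq_len(m), seq_len(m), "-"))
    E <- matrix(ex[s + 1L], m, m)
    OE[idx, idx] <- B[idx, idx] / E
  }
  OE
}

#' Contact-versus-distance decay curve
#'
#' `P(s)` is the mean contact (balanced if weights are present, raw
#' otherwise) over all pairs at bin distance `s`, pooled over the supplied
#' maps, then aggregated into geometric distance bins; the first
#' derivative of `log P` versus `log s` is computed by central
#' differences on the binned curve.
#'
#' @param maps `ContactMap` or list of maps (same bin size).
#' @param logBase geometric bin ratio (default 1.15; 1 = no binning).
#' @return data.frame with `distance` (bp), `p`, `slope`.
#' @export
decayCurve <- function(maps, logBase = 1.15) {
  if (is(maps, "ContactMap")) maps <- list(maps)
  bs <- maps[[1]]@binSize
  maxS <- max(vapply(maps, nBins, 0L)) - 1L
  sums <- cnts <- rep(0, maxS)
  for (map in maps) {
    n <- nBins(map)
    bal <- length(map@weights) > 0
    tm <- methods::as(methods::as(map@counts, "generalMatrix"),
                      "TsparseMatrix")
    keep <- tm@i < tm@j
    i <- tm@i[keep] + 1L; j <- tm@j[keep] + 1L; x <- tm@x[keep]
    u <- rep(TRUE, n)
    if (bal) {
      w <- map@weights
      u <- !is.na(w)
      ok <- u[i] & u[j]
      i <- i[ok]; j <- j[ok]; x <- x[ok] * w[i] * w[j]
    }
    d <- j - i
    add <- tapply(x, factor(d, levels = 1:(n - 1)), sum, default = 0)
    sums[1:(n - 1)] <- sums[1:(n - 1)] + as.numeric(add)
    ui <- as.numeric(u)
    pairCnt <- vapply(1:(n - 1), function(s) sum(ui[1:(n - s)] * ui[(1 + s):n]), 0)
    cnts[1:(n - 1)] <- cnts[1:(n - 1)] + pairCnt
  }
  ok <- cnts > 0 & sums > 0
  if (sum(ok) < 10) stop("need data at >= 10 distinct distances")
  s <- which(ok)
  p <- sums[ok] / cnts[ok]
  wgt <- cnts[ok]
  if (logBase > 1) {
    edges <- unique(ceiling(logBase^(0:ceiling(log(maxS) / log(logBase)))))
    grp <- findInterval(s, edges)
    p <- as.numeric(tapply(p * wgt, grp, sum) / tapply(wgt, grp, sum))
    s <- as.numeric(exp(tapply(log(s) * wgt, grp, sum) / tapply(wgt, grp, sum)))
  }
  ls <- log(s); lp <- log(p)
  k <- length(s)
  slope <- rep(NA_real_, k)
  if (k >= 3)
    slope[2:(k - 1)] <- (lp[3:k] - lp[1:(k - 2)]) / (ls[3:k] - ls[1:(k - 2)])
  data.frame(distance = s * bs, p = p, slope = slope)
}

#' Fitted decay slope over a distance range
#'
#' Weighted least-squares slope of `log P` versus `log s` over the given
#' distance range of a `decayCurve` result.
#'
#' @param curve result of [decayCurve()].
#' @param range numeric length-2 distance range in bp (inclusive).
#' @return slope (the decay exponent is its negative).
#' @export
decaySlope <- function(curve, range) {
  sel <- curve$distance >= range[1] & curve$distance <= range[2] &
    is.finite(curve$p) & curve$p > 0
  if (sum(sel) < 3) stop("fewer than 3 curve points in range")
  fit <- stats::lm(log(p) ~ log(distance), data = curve[sel, ])
  unname(stats::coef(fit)[2])
}

#' Insulation score and boundary calls
#'
#' Per-bin score = `log2` of the summed balanced contacts in the
#' `window x window` square crossing the bin (rows `bin-w..bin-1`, columns
#' `bin+1..bin+w`), relative to the arm-wide mean of that sum.  Scores
#' are defined only where the full window fits inside the arm.  With
#' several windows the per-bin minimum over windows is used for boundary
#' detection: boundaries are strict local minima whose drop below the
#' surrounding mean exceeds `delta`, filtered by a rank-based
#' Benjamini-Hochberg q-value threshold.
#'
#' @param map balanced `ContactMap`.
#' @param windows window sizes in bp (default `c(5000, 10000)`).
#' @param cenPos centromere midpoint (bp) splitting arms, or `NA`.
#' @param delta minimum drop below the local mean score (default 0.01).
#' @param fdrThreshold boundary q-value threshold (default 0.01).
#' @return list with `scores` (data.frame: `bin`, `pos`, one `score_<w>`
#'   column per window, `minScore`) and `boundaries` (data.frame: `bin`,
#'   `pos`, `score`, `strength`, `qValue`).
#' @export
insulationScore <- function(map, windows = c(5000, 10000), cenPos = NA,
                            delta = 0.01, fdrThreshold = 0.01) {
  B <- balancedDense(map)
  n <- nBins(map)
  bs <- map@binSize
  arms <- armRanges(n, bs, cenPos)
  if (any(vapply(arms, length, 0L) <= max(windows) / bs * 2))
    stop("window larger than arm")
  B0 <- ifelse(is.na(B), 0, B)
  sat <- .sat2d(B0)  # (n+1) x (n+1) summed-area table
  rectSum <- function(r1, r2, c1, c2)
    sat[r2 + 1, c2 + 1] - sat[r1, c2 + 1] - sat[r2 + 1, c1] + sat[r1, c1]
  scores <- matrix(NA_real_, n, length(windows))
  for (wi in seq_along(windows)) {
    w <- as.integer(windows[wi] / bs)
    if (w < 1) stop("window must be at least 2 bins wide")
    for (idx in arms) {
      lo <- min(idx); hi <- max(idx)
      b <- idx[idx - w >= lo & idx + w <= hi]
      if (!length(b)) next
      S <- vapply(b, function(bb) rectSum(bb - w, bb - 1, bb + 1, bb + w), 0)
      mu <- mean(S[S >= 0], na.rm = TRUE)
      scores[b, wi] <- log2(S / mu)
    }
  }
  colnames(scores) <- paste0("score_", windows)
  minScore <- apply(scores, 1, function(z)
    if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE))
  ## boundary detection on the combined score
  cand <- data.frame(bin = integer(0), strength = numeric(0), p = numeric(0))
  wmax <- as.integer(max(windows) / bs)
  defined <- which(!is.na(minScore))
  rk <- rank(minScore[defined], ties.method = "average")
  pAll <- stats::setNames(rk / length(defined), defined)
  for (b in defined) {
    if (b <= 1 || b >= n) next
    sL <- minScore[b - 1]; sR <- minScore[b + 1]
    if (is.na(sL) || is.na(sR)) next
    ## local minimum; on plateaus only the leftmost bin is called
    if (!(minScore[b] < sL && minScore[b] <= sR)) next
    if (minScore[b] == sR) {
      run <- b + 1
      while (run < n && !is.na(minScore[run + 1]) &&
             minScore[run + 1] == minScore[b]) run <- run + 1
      if (run >= n || is.na(minScore[run + 1]) ||
          minScore[run + 1] <= minScore[b]) next
    }
    nb <- max(1, b - wmax):min(n, b + wmax)
    strength <- mean(minScore[nb], na.rm = TRUE) - minScore[b]
    if (is.na(strength) || strength < delta) next
    cand <- rbind(cand, data.frame(bin = b, strength = strength,
                                   p = unname(pAll[as.character(b)])))
  }
  if (nrow(cand)) {
    cand$qValue <- stats::p.adjust(cand$p, method = "BH")
    cand <- cand[cand$qValue <= fdrThreshold, , drop = FALSE]
  } else cand$qValue <- numeric(0)
  boundaries <- data.frame(bin = cand$bin,
                           pos = binCenter(cand$bin, bs),
                           score = minScore[cand$bin],
                           strength = cand$strength,
                           qValue = cand$qValue)
  scoresDf <- data.frame(bin = seq_len(n), pos = binCenter(seq_len(n), bs),
                         scores, minScore = minScore)
  list(scores = scoresDf, boundaries = boundaries)
}

#' Averaged insulation profile around loci
#'
#' Averages an insulation score column around a set of positions (e.g.
#' centromeres across chromosomes), with a 95% normal-theory band.
#'
#' @param insulations list of [insulationScore()] results, one per
#'   chromosome.
#' @param positions named numeric positions (bp, 0-based) per chromosome.
#' @param flank flank in bp.
#' @param column score column to average (default the first window's).
#' @return data.frame with `offset`, `mean`, `lower`, `upper`, `n`.
#' @export
insulationAroundLoci <- function(insulations, positions, flank,
                                 column = NULL) {
  stopifnot(length(insulations) > 0)
  sc1 <- insulations[[1]]$scores
  if (is.null(column))
    column <- grep("^score_", names(sc1), value = TRUE)[1]
  bs <- diff(sc1$pos[1:2])
  k <- as.integer(flank / bs)
  rows <- lapply(names(positions), function(nm) {
    sc <- insulations[[nm]]$scores
    b0 <- binOf(positions[[nm]], bs)
    b <- b0 + (-k:k)
    v <- rep(NA_real_, 2 * k + 1)
    inside <- b >= 1 & b <= nrow(sc)
    v[inside] <- sc[[column]][b[inside]]
    v
  })
  m <- do.call(rbind, rows)
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  sem <- apply(m, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1))
  data.frame(offset = (-k:k) * bs, mean = mu,
             lower = mu - 1.96 * sem, upper = mu + 1.96 * sem, n = n,
             row.names = NULL)
}

## clipped rectangle sums over a summed-area table, vectorized over pixels
.rect <- function(sat, m, r1, r2, c1, c2) {
  r1 <- pmax(r1, 1L); c1 <- pmax(c1, 1L)
  r2 <- pmin(r2, m); c2 <- pmin(c2, m)
  empty <- r1 > r2 | c1 > c2
  r1 <- pmin(r1, m); c1 <- pmin(c1, m)
  r2 <- pmax(r2, 1L); c2 <- pmax(c2, 1L)
  out <- sat[cbind(r2 + 1L, c2 + 1L)] - sat[cbind(r1, c2 + 1L)] -
    sat[cbind(r2 + 1L, c1)] + sat[cbind(r1, c1)]
  out[empty] <- 0
  out
}

.sat2d <- function(M) {
  n <- nrow(M)
  s <- apply(M, 2, cumsum)
  s <- cbind(0, t(apply(s, 1, cumsum)))
  rbind(0, s)
}

#' Call loops with a simplified donut-background detector
#'
#' HICCUPS-style detection on a balanced map: every pixel in the tested
#' distance band is compared against four local backgrounds (donut,
#' lower-left, horizontal and vertical neighborhoods with outer radius
#' `windowPx` and inner exclusion `peakPx`, each rescaled by the per-arm
#' expected profile); the pixel's raw count is tested against each local
#' expectation with a Poisson upper-tail p-value, Benjamini-Hochberg
#' adjusted per filter across all tested pixels.  A pixel is significant
#' if it exceeds all four local expectations with all four q-values at or
#' below `fdr`.  Significant pixels closer than `mergeDist` (Euclidean,
#' bp) are clustered (single linkage) and each cluster is reported as one
#' loop at its centroid pixel, with anchors as bin-width intervals.
#' Following the established donut-caller practice of distrusting
#' unclustered pixels, single-pixel clusters are kept only when their
#' q-value also passes the stricter `singletonQ` threshold.
#'
#' @param map balanced `ContactMap`.
#' @param cenPos centromere midpoint (bp) or `NA`.
#' @param windowPx outer neighborhood radius in pixels (default 16).
#' @param peakPx inner exclusion radius in pixels (default 8).
#' @param fdr false discovery rate (default 0.1).
#' @param mergeDist pixel merge distance in bp (default 2500; strictly
#'   less than).
#' @param minDist minimum anchor separation in bp (default 5000; strictly
#'   greater than).
#' @param maxDist optional maximum anchor separation in bp.
#' @param singletonQ q-value threshold for single-pixel clusters
#'   (default `fdr / 10`).
#' @return `data.frame` of loops: `chrom`, `start1`, `end1`, `start2`,
#'   `end2` (0-based half-open bin intervals), `bin1`, `bin2`, `length`,
#'   `obsExp`, `qValue`, `nPixels`.
#' @export
callLoops <- function(map, cenPos = NA, windowPx = 16, peakPx = 8,
                      fdr = 0.1, mergeDist = 2500, minDist = 5000,
                      maxDist = NA, singletonQ = fdr / 10) {
  if (!length(map@weights)) stop("callLoops requires a balanced map")
  bs <- map@binSize
  n <- nBins(map)
  expProf <- expectedCis(map, cenPos)
  w <- map@weights
  O <- as.matrix(map@counts)
  dmin <- as.integer(floor(minDist / bs)) + 1L
  dmin <- max(dmin, 2L)
  dmax <- if (is.na(maxDist)) n - 1L else as.integer(maxDist / bs)
  cand <- list()
  for (a in seq_along(expProf$arms)) {
    idx <- expProf$arms[[a]]
    m <- length(idx)
    if (m <= dmin) next
    ex <- expProf$expected[[a]]
    wa <- w[idx]
    masked <- is.na(wa)
    Oa <- O[idx, idx, drop = FALSE]
    s <- abs(outer(seq_len(m), seq_len(m), "-"))
    Eraw <- matrix(ex[s + 1L], m, m) / outer(wa, wa)
    Oa[masked, ] <- 0; Oa[, masked] <- 0
    Eraw[masked, ] <- 0; Eraw[, masked] <- 0
    Eraw[is.na(Eraw)] <- 0
    satO <- .sat2d(Oa)
    satE <- .sat2d(Eraw)
    ut <- which(upper.tri(Oa), arr.ind = TRUE)
    d <- ut[, 2] - ut[, 1]
    keep <- d >= dmin & d <= dmax & !masked[ut[, 1]] & !masked[ut[, 2]]
    if (!any(keep)) next
    i <- ut[keep, 1]; j <- ut[keep, 2]
    obs <- Oa[cbind(i, j)]
    eRaw <- Eraw[cbind(i, j)]
    W <- as.integer(windowPx); P <- as.integer(peakPx)
    regions <- function(sat) {
      outer_ <- .rect(sat, m, i - W, i + W, j - W, j + W)
      inner_ <- .rect(sat, m, i - P, i + P, j - P, j + P)
      rowS <- .rect(sat, m, i, i, j - W, j + W) - .rect(sat, m, i, i, j - P, j + P)
      colS <- .rect(sat, m, i - W, i + W, j, j) - .rect(sat, m, i - P, i + P, j, j)
      cbind(donut = outer_ - inner_ - rowS - colS,
            lowleft = .rect(sat, m, i + 1, i + W, j - W, j - 1) -
              .rect(sat, m, i + 1, i + P, j - P, j - 1),
            horiz = .rect(sat, m, i - 1, i + 1, j - W, j + W) -
              .rect(sat, m, i - 1, i + 1, j - P, j + P),
            vert = .rect(sat, m, i - W, i + W, j - 1, j + 1) -
              .rect(sat, m, i - P, i + P, j - 1, j + 1))
    }
    RO <- regions(satO); RE <- regions(satE)
    mu <- RO / pmax(RE, .Machine$double.eps) * eRaw
    pv <- matrix(1, nrow = length(i), ncol = 4)
    for (f in 1:4)
      pv[, f] <- stats::ppois(obs - 1, mu[, f], lower.tail = FALSE)
    cand[[a]] <- data.frame(i = idx[i], j = idx[j], obs = obs,
                            eRaw = eRaw,
                            mu1 = mu[, 1], mu2 = mu[, 2],
                            mu3 = mu[, 3], mu4 = mu[, 4],
                            p1 = pv[, 1], p2 = pv[, 2],
                            p3 = pv[, 3], p4 = pv[, 4])
  }
  emptyLoops <- data.frame(chrom = character(0), start1 = numeric(0),
                           end1 = numeric(0), start2 = numeric(0),
                           end2 = numeric(0), bin1 = integer(0),
                           bin2 = integer(0), length = numeric(0),
                           obsExp = numeric(0), qValue = numeric(0),
                           nPixels = integer(0))
  if (!length(cand)) return(emptyLoops)
  cand <- do.call(rbind, cand)
  q <- sapply(paste0("p", 1:4), function(cn)
    stats::p.adjust(cand[[cn]], method = "BH"))
  qMax <- apply(q, 1, max)
  sig <- qMax <= fdr &
    cand$obs > cand$mu1 & cand$obs > cand$mu2 &
    cand$obs > cand$mu3 & cand$obs > cand$mu4
  if (!any(sig)) return(emptyLoops)
  px <- cand[sig, , drop = FALSE]
  px$qMax <- qMax[sig]
  ## single-linkage clustering of pixels within mergeDist (Euclidean bp)
  np <- nrow(px)
  comp <- seq_len(np)
  if (np > 1) {
    pr <- utils::combn(np, 2)
    dd <- sqrt((px$i[pr[1, ]] - px$i[pr[2, ]])^2 +
                 (px$j[pr[1, ]] - px$j[pr[2, ]])^2) * bs
    for (k in which(dd < mergeDist)) {
      a <- comp[pr[1, k]]; b <- comp[pr[2, k]]
      if (a != b) comp[comp == b] <- a
    }
  }
  loops <- do.call(rbind, lapply(unique(comp), function(cc) {
    sub <- px[comp == cc, , drop = FALSE]
    ci <- as.integer(round(mean(sub$i)))
    cj <- as.integer(round(mean(sub$j)))
    oe <- sub$obs / pmax(sub$eRaw, .Machine$double.eps)
    best <- which.max(oe)
    data.frame(chrom = map@chrom,
               start1 = (ci - 1) * bs, end1 = ci * bs,
               start2 = (cj - 1) * bs, end2 = cj * bs,
               bin1 = ci, bin2 = cj,
               length = (cj - ci) * bs,
               obsExp = oe[best],
               qValue = sub$qMax[best],
               nPixels = nrow(sub))
  }))
  loops <- loops[!(loops$nPixels == 1L & loops$qValue > singletonQ), ,
                 drop = FALSE]
  loops[order(loops$start1, loops$start2), , drop = FALSE]
}

## accumulate observed/expected windows for position pairs on one map
.pileupAccum <- function(map, pairs, flank, minDist, mode, cenPos, acc) {
  expProf <- expectedCis(map, cenPos)
  OE <- obsExpDense(map, expProf)
  bs <- map@binSize
  k <- as.integer(flank / bs)
  armOf <- integer(nBins(map))
  for (a in seq_along(expProf$arms)) armOf[expProf$arms[[a]]] <- a
  for (r in seq_len(nrow(pairs))) {
    b1 <- binOf(pairs$pos1[r], bs)
    b2 <- binOf(pairs$pos2[r], bs)
    if (mode == "off" && abs(pairs$pos2[r] - pairs$pos1[r]) <= minDist) {
      acc$nSkipped <- acc$nSkipped + 1L; next
    }
    a1 <- armOf[b1]; a2 <- armOf[b2]
    lo1 <- b1 - k; hi1 <- b1 + k; lo2 <- b2 - k; hi2 <- b2 + k
    armIdx1 <- expProf$arms[[a1]]
    armIdx2 <- expProf$arms[[a2]]
    if (a1 != a2 || lo1 < min(armIdx1) || hi1 > max(armIdx1) ||
        lo2 < min(armIdx2) || hi2 > max(armIdx2)) {
      acc$nSkipped <- acc$nSkipped + 1L; next
    }
    Wnd <- OE[lo1:hi1, lo2:hi2]
    ok <- !is.na(Wnd)
    acc$sum[ok] <- acc$sum[ok] + Wnd[ok]
    acc$cnt <- acc$cnt + ok
    acc$nUsed <- acc$nUsed + 1L
  }
  acc
}

#' Aggregate observed/expected pile-up (APA)
#'
#' Averages observed/expected submatrices in a window of `flank` bp
#' around locus pairs (off-diagonal mode) or single loci on the diagonal
#' (on-diagonal mode).  Pairs closer than `minDist` (off-diagonal) and
#' pairs whose window extends beyond the chromosome arm are skipped and
#' counted.  The central score is the mean of the central 3x3 pixels.
#'
#' @param maps `ContactMap` or named list of maps (names = chromosomes).
#' @param loci data.frame with `chrom` and either `pos1`, `pos2`
#'   (off-diagonal) or `pos` (on-diagonal); positions are 0-based bp.
#' @param flank window flank in bp (default 10000).
#' @param minDist minimum pair separation in bp (default 5000; strictly
#'   greater than).
#' @param mode `"off"` or `"on"` diagonal.
#' @param cenPositions named centromere midpoints per chromosome (arms
#'   split there), or `NULL`.
#' @return list of class `PileupResult`: `matrix` (averaged
#'   observed/expected), `centralScore`, `nUsed`, `nSkipped`.
#' @export
pileup <- function(maps, loci, flank = 10000, minDist = 5000,
                   mode = c("off", "on"), cenPositions = NULL) {
  mode <- match.arg(mode)
  if (is(maps, "ContactMap")) {
    maps <- stats::setNames(list(maps), maps@chrom)
  }
  if (mode == "on") {
    loci <- data.frame(chrom = loci$chrom, pos1 = loci$pos, pos2 = loci$pos)
  }
  bs <- maps[[1]]@binSize
  k <- as.integer(flank / bs)
  side <- 2L * k + 1L
  acc <- list(sum = matrix(0, side, side), cnt = matrix(0L, side, side),
              nUsed = 0L, nSkipped = 0L)
  for (nm in names(maps)) {
    sub <- loci[loci$chrom == nm, , drop = FALSE]
    if (!nrow(sub)) next
    cp <- if (is.null(cenPositions)) NA else cenPositions[[nm]]
    acc <- .pileupAccum(maps[[nm]], sub, flank, minDist, mode, cp, acc)
  }
  if (acc$nUsed == 0L) stop("zero usable pairs")
  avg <- acc$sum / pmax(acc$cnt, 1L)
  avg[acc$cnt == 0L] <- NA_real_
  ctr <- k + 1L
  central <- mean(avg[(ctr - 1):(ctr + 1), (ctr - 1):(ctr + 1)], na.rm = TRUE)
  structure(list(matrix = avg, centralScore = central,
                 nUsed = acc$nUsed, nSkipped = acc$nSkipped),
            class = "PileupResult")
}

#' Classify loops by anchor context
#'
#' A loop is `centromere-originated` if either anchor midpoint lies
#' within `cenRadius` of a centromere on its chromosome;
#' `cohesin-anchored` if (not centromere-originated and) both anchors
#' intersect a cohesin peak; `other` otherwise.
#'
#' @param loops loop `data.frame` (from [callLoops()]).
#' @param annotation `GenomeAnnotation`.
#' @param cohesinPeaks `GRanges` of cohesin peaks/sites.
#' @param cenRadius centromere radius in bp (default 5000).
#' @return `loops` with a `category` column; the per-category summary
#'   (count and length statistics) is attached as
#'   `attr(loops, "summary")`.
#' @export
classifyLoops <- function(loops, annotation, cohesinPeaks,
                          cenRadius = 5000) {
  cen <- centromeres(annotation)
  if (!nrow(loops)) {
    loops$category <- character(0)
    attr(loops, "summary") <- data.frame()
    return(loops)
  }
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  cenD1 <- abs(mid1 - cen[loops$chrom])
  cenD2 <- abs(mid2 - cen[loops$chrom])
  isCen <- cenD1 < cenRadius | cenD2 < cenRadius
  a1 <- GRanges(loops$chrom, IRanges(loops$start1 + 1, loops$end1))
  a2 <- GRanges(loops$chrom, IRanges(loops$start2 + 1, loops$end2))
  onPeak <- countOverlaps(a1, cohesinPeaks) > 0 &
    countOverlaps(a2, cohesinPeaks) > 0
  loops$category <- ifelse(isCen, "centromere-originated",
                           ifelse(onPeak, "cohesin-anchored", "other"))
  sm <- do.call(rbind, lapply(split(loops, loops$category), function(sub)
    data.frame(category = sub$category[1], n = nrow(sub),
               meanLength = mean(sub$length),
               medianLength = stats::median(sub$length),
               q1Length = unname(stats::quantile(sub$length, 0.25)),
               q3Length = unname(stats::quantile(sub$length, 0.75)))))
  rownames(sm) <- NULL
  attr(loops, "summary") <- sm
  loops
}

#' Flag cohesin sites that anchor centromere-originated loops
#'
#' A site is an anchor site iff its interval (extended by `tolerance` bp)
#' intersects a non-centromeric anchor of a centromere-originated loop.
#'
#' @param sites `GRanges` of cohesin sites.
#' @param loops classified loop `data.frame` (with `category`).
#' @param annotation `GenomeAnnotation`.
#' @param cenRadius radius defining the centromeric anchor (default 5000).
#' @param tolerance interval extension in bp (default 0).
#' @return list with `sites` (input plus logical `anchor` column),
#'   `anchorCount`, `nonAnchorCount`.
#' @export
anchorSiteClassification <- function(sites, loops, annotation,
                                     cenRadius = 5000, tolerance = 0) {
  cen <- centromeres(annotation)
  cl <- loops[loops$category == "centromere-originated", , drop = FALSE]
  anchors <- GRanges()
  if (nrow(cl)) {
    mid1 <- (cl$start1 + cl$end1) / 2
    mid2 <- (cl$start2 + cl$end2) / 2
    d1 <- abs(mid1 - cen[cl$chrom]); d2 <- abs(mid2 - cen[cl$chrom])
    grs <- list(GRanges(cl$chrom[d1 >= cenRadius],
                        IRanges(cl$start1[d1 >= cenRadius] + 1,
                                cl$end1[d1 >= cenRadius])),
                GRanges(cl$chrom[d2 >= cenRadius],
                        IRanges(cl$start2[d2 >= cenRadius] + 1,
                                cl$end2[d2 >= cenRadius])))
    anchors <- suppressWarnings(c(grs[[1]], grs[[2]]))
  }
  ext <- sites
  if (tolerance > 0) {
    sl <- chromLengths(annotation)[as.character(seqnames(sites))]
    ext <- GRanges(seqnames(sites),
                   IRanges(pmax(1, start(sites) - tolerance),
                           pmin(sl, end(sites) + tolerance)))
  }
  flag <- countOverlaps(ext, anchors) > 0
  mcols(sites)$anchor <- flag
  list(sites = sites, anchorCount = sum(flag),
       nonAnchorCount = sum(!flag))
}

#' Centromere-site contact strength by distance bin
#'
#' Pairs each arm cohesin site with the centromere of its chromosome,
#' groups the pairs by separation into left-closed right-open distance
#' bins, and computes the off-diagonal observed/expected pile-up central
#' score per bin.
#'
#' @param maps named list of balanced `ContactMap`s.
#' @param sites `GRanges` of cohesin sites.
#' @param annotation `GenomeAnnotation`.
#' @param distanceBins numeric bin edges in bp (sorted; pairs at exactly
#'   an edge fall in the upper bin).
#' @param flank,minDist passed to [pileup()].
#' @return data.frame with `binStart`, `binEnd`, `n`, `centralScore`
#'   (`NA` when a bin has no usable pairs).
#' @export
cenContactByDistance <- function(maps, sites, annotation, distanceBins,
                                 flank = 10000, minDist = 5000) {
  if (is.unsorted(distanceBins)) stop("distance bins must be sorted")
  cen <- centromeres(annotation)
  sn <- as.character(seqnames(sites))
  s <- summitOf(sites)
  d <- abs(s - cen[sn])
  grp <- findInterval(d, distanceBins)
  out <- lapply(seq_len(length(distanceBins) - 1), function(g) {
    sel <- grp == g
    row <- data.frame(binStart = distanceBins[g],
                      binEnd = distanceBins[g + 1],
                      n = sum(sel), centralScore = NA_real_)
    if (!any(sel)) return(row)
    pairs <- data.frame(chrom = sn[sel],
                        pos1 = pmin(cen[sn[sel]], s[sel]),
                        pos2 = pmax(cen[sn[sel]], s[sel]))
    ## centromere-site pairs span the centromere by construction, so the
    ## chromosome-wide expected is used (a per-arm expected is undefined
    ## for cross-arm pixels)
    ps <- tryCatch(pileup(maps, pairs, flank = flank, minDist = minDist,
                          mode = "off", cenPositions = NULL),
                   error = function(e) NULL)
    if (!is.null(ps)) {
      row$centralScore <- ps$centralScore
      row$n <- ps$nUsed
    } else row$n <- 0L
    row
  })
  do.call(rbind, out)
}
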
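suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Matrix)
})

## two-chromosome toy genome
toyAnnotation <- function(len = c(chrI = 300000, chrII = 500000),
                          cen = c(chrI = 150000, chrII = 100000),
                          genes = GRanges(), sites = list()) {
  GenomeAnnotation(len, cen, genes, sites)
}

## BinnedTrack from named list of numeric vectors (chromosome lengths
## inferred from vector lengths)
mkTrack <- function(values, binSize = 100, semantics = "nFE") {
  if (!is.list(values)) values <- list(chrI = values)
  sl <- vapply(values, length, 0L) * binSize
  BinnedTrack(binSize, values, sl, semantics)
}

## ContactMap from a dense symmetric matrix
mkMap <- function(mat, binSize = 1000, chrom = "chrI", weights = numeric(0)) {
  ContactMap(chrom, binSize, nrow(mat) * binSize,
             as(mat, "CsparseMatrix"), weights = weights)
}

writeTmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

## independent run/merge/width peak-calling oracle (direct scan)
oraclePeaks <- function(v, threshold, mergeGap = 0, minWidth = 1) {
  above <- !is.na(v) & v >= threshold
  runs <- list()
  k <- 1
  while (k <= length(v)) {
    if (above[k]) {
      s <- k
      while (k < length(v) && above[k + 1]) k <- k + 1
      runs[[length(runs) + 1]] <- c(s, k)
    }
    k <- k + 1
  }
  if (!length(runs)) return(matrix(numeric(0), ncol = 2))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 <= mergeGap) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else merged[[length(merged) + 1]] <- r
  }
  keep <- vapply(merged, function(r) r[2] - r[1] + 1 >= minWidth, TRUE)
  if (!any(keep)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, merged[keep])
}

## exact two-sided Mann-Whitney p by full enumeration of labelings
oracleMannWhitney <- function(a, b) {
  n <- length(a); m <- length(b)
  pool <- c(a, b)
  combos <- utils::combn(n + m, n)
  r <- rank(pool)
  uAll <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  pLo <- mean(uAll <= u); pHi <- mean(uAll >= u)
  min(1, 2 * min(pLo, pHi))
}
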
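## Spike-in calibrated ChIP-seq quantification: occupancy ratio,
## normalization factor, nFE track construction, threshold peak calling
## and track/peak comparison statistics.

#' Occupancy ratio from cross-species read counts
#'
#' `OR = (ChIP_target x input_spike) / (input_target x ChIP_spike)`, the
#' spike-in calibrated measure of relative target-genome occupancy.  The
#' ratio is invariant to the sequencing depth of either fraction.
#'
#' @param chipTarget,chipSpike non-redundant ChIP-fraction read counts
#'   mapped to the target and spike genomes.
#' @param inputTarget,inputSpike same for the input fraction.
#' @return positive numeric occupancy ratio.
#' @export
occupancyRatio <- function(chipTarget, chipSpike, inputTarget, inputSpike) {
  chipTarget <- as.numeric(chipTarget); chipSpike <- as.numeric(chipSpike)
  inputTarget <- as.numeric(inputTarget); inputSpike <- as.numeric(inputSpike)
  counts <- c(chipTarget, chipSpike, inputTarget, inputSpike)
  if (any(counts < 0)) stop("read counts must be non-negative")
  if (inputTarget == 0 || chipSpike == 0)
    stop("zero denominator count (inputTarget or chipSpike)")
  (chipTarget * inputSpike) / (inputTarget * chipSpike)
}

#' Normalization factor between two samples
#'
#' `NF = OR_treated / OR_control`; NF of a sample against itself is 1, and
#' NF chains multiplicatively across samples.
#'
#' @param orTreated occupancy ratio of the sample of interest.
#' @param orControl occupancy ratio of the declared control.
#' @return positive numeric normalization factor.
#' @export
normalizationFactor <- function(orTreated, orControl) {
  if (orTreated <= 0 || orControl <= 0)
    stop("occupancy ratios must be positive")
  orTreated / orControl
}

#' Build a calibrated normalized fold-enrichment (nFE) track
#'
#' The raw ChIP track is rescaled so its genome-wide total equals
#' `1,500,000 x NF`; the input track is rescaled to a total of 1,500,000.
#' The nFE of a bin is the scaled ChIP value over the scaled input value.
#' Bins whose raw input count is below `minInputReads` are masked rather
#' than smoothed (no pseudocount).  Output is exactly linear in `nf` and
#' invariant to uniform rescaling of either raw track.
#'
#' @param chip,input raw `BinnedTrack`s on the same bin grid.
#' @param nf normalization factor of the ChIP sample.
#' @param minInputReads mask bins with fewer raw input reads (default 1).
#' @param scaleTotal scaled genome-wide input total (default 1,500,000).
#' @param smoothBins odd number of bins for an optional running-mean
#'   smoothing of the nFE values (default 0 = off).
#' @return `BinnedTrack` with semantics `"nFE"`.
#' @export
nfeTrack <- function(chip, input, nf, minInputReads = 1,
                     scaleTotal = 1500000, smoothBins = 0) {
  stopifnot(is(chip, "BinnedTrack"), is(input, "BinnedTrack"), nf > 0)
  if (chip@binSize != input@binSize ||
      !identical(chip@seqlengths, input@seqlengths))
    stop("chip and input tracks are on different bin grids")
  chipTot <- sum(unlist(chip@values), na.rm = TRUE)
  inTot <- sum(unlist(input@values), na.rm = TRUE)
  if (chipTot <= 0 || inTot <= 0) stop("empty track")
  vals <- lapply(names(chip@values), function(nm) {
    cv <- chip@values[[nm]] * (scaleTotal * nf / chipTot)
    iv <- input@values[[nm]] * (scaleTotal / inTot)
    raw <- input@values[[nm]]
    nfe <- cv / iv
    nfe[is.na(raw) | raw < minInputReads] <- NA_real_
    if (smoothBins > 1) {
      k <- as.integer(smoothBins)
      sm <- stats::filter(ifelse(is.na(nfe), 0, nfe), rep(1, k), sides = 2)
      cnt <- stats::filter(as.numeric(!is.na(nfe)), rep(1, k), sides = 2)
      out <- as.numeric(sm / cnt)
      out[is.na(nfe)] <- NA_real_
      nfe <- out
    }
    nfe
  })
  names(vals) <- names(chip@values)
  BinnedTrack(chip@binSize, vals, chip@seqlengths, "nFE")
}

#' Call enrichment peaks on an nFE track
#'
#' Peaks are maximal runs of unmasked bins with nFE at or above
#' `threshold`; runs separated by at most `mergeGapBins` bins are merged,
#' and merged runs shorter than `minWidthBins` bins are dropped.  The
#' summit is the center of the maximum-nFE bin (leftmost on ties).
#'
#' @param track nFE `BinnedTrack`.
#' @param threshold fold-enrichment threshold (default 2.0).
#' @param minWidthBins minimum peak width in bins (default 1).
#' @param mergeGapBins maximum gap merged across (default 0).
#' @return `GRanges` of peaks with `summit` (0-based bp), `maxNfe` and
#'   `meanNfe` metadata columns.
#' @export
callPeaks <- function(track, threshold = 2, minWidthBins = 1,
                      mergeGapBins = 0) {
  stopifnot(is(track, "BinnedTrack"), threshold > 0)
  bs <- track@binSize
  res <- list()
  for (nm in names(track@values)) {
    v <- track@values[[nm]]
    above <- !is.na(v) & v >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    if (mergeGapBins > 0 && nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (k in 2:nrow(runs)) {
        gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
        if (gap <= mergeGapBins) {
          merged$end[nrow(merged)] <- runs$end[k]
        } else merged <- rbind(merged, runs[k, ])
      }
      runs <- merged
    }
    runs <- runs[runs$end - runs$start + 1L >= minWidthBins, , drop = FALSE]
    if (!nrow(runs)) next
    summitBin <- maxN <- meanN <- numeric(nrow(runs))
    for (k in seq_len(nrow(runs))) {
      b <- runs$start[k]:runs$end[k]
      vv <- v[b]
      maxN[k] <- max(vv, na.rm = TRUE)
      meanN[k] <- mean(vv, na.rm = TRUE)
      summitBin[k] <- b[which.max(ifelse(is.na(vv), -Inf, vv))]
    }
    gr <- GRanges(nm, IRanges((runs$start - 1L) * bs + 1L,
                              pmin(runs$end * bs, track@seqlengths[[nm]])),
                  seqlengths = track@seqlengths)
    mcols(gr)$summit <- binCenter(summitBin, bs)
    mcols(gr)$maxNfe <- maxN
    mcols(gr)$meanNfe <- meanN
    res[[nm]] <- gr
  }
  if (!length(res)) {
    gr <- GRanges()
    mcols(gr)$summit <- numeric(0)
    mcols(gr)$maxNfe <- numeric(0)
    mcols(gr)$meanNfe <- numeric(0)
    return(gr)
  }
  unname(do.call(c, unname(res)))
}

#' Fraction of peaks in A overlapping any peak in B
#'
#' Asymmetric by design: the fraction of intervals in `peaksA` that
#' intersect at least one bp of any interval in `peaksB`.
#'
#' @param peaksA,peaksB `GRanges` on the same genome.
#' @return numeric in `[0, 1]` (`NaN` for an empty `peaksA`).
#' @export
peakOverlapFraction <- function(peaksA, peaksB) {
  if (length(peaksA) == 0L) return(NaN)
  mean(countOverlaps(peaksA, peaksB) > 0)
}

#' Spearman correlation between two tracks
#'
#' Rank correlation (average ranks on ties) over jointly unmasked bins,
#' or over per-site window means when a site list is given.
#'
#' @param trackA,trackB `BinnedTrack`s on the same grid.
#' @param sites optional `GRanges`; correlate per-site values
#'   (`quantifyAtSites`) instead of per-bin values.
#' @param window site quantification window in bp (used with `sites`).
#' @return Spearman's rho.
#' @export
trackCorrelation <- function(trackA, trackB, sites = NULL, window = 400) {
  if (is.null(sites)) {
    a <- unlist(trackA@values, use.names = FALSE)
    b <- unlist(trackB@values, use.names = FALSE)
  } else {
    a <- quantifyAtSites(trackA, sites, window)
    b <- quantifyAtSites(trackB, sites, window)
  }
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("fewer than 3 jointly unmasked values")
  stats::cor(a[ok], b[ok], method = "spearman")
}
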
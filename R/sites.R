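## Site-level statistics: window quantification of tracks at binding
## sites, quartile grouping by enrichment, ratio analysis against a
## control median, aggregate profiles with confidence bands, profile
## heatmap matrices, and centromere-distance annotation.

#' Quantify a track at binding sites
#'
#' Per-site value = mean nFE over unmasked bins within `window/2` bp of
#' the site summit (interval midpoint).  Sites whose window is entirely
#' masked get `NA`.
#'
#' @param track `BinnedTrack` (typically nFE).
#' @param sites `GRanges`.
#' @param window window width in bp centered at the summit (default 400).
#' @return numeric vector, one value per site.
#' @export
quantifyAtSites <- function(track, sites, window = 400) {
  stopifnot(is(track, "BinnedTrack"), window >= track@binSize)
  bs <- track@binSize
  vapply(seq_along(sites), function(k) {
    nm <- as.character(seqnames(sites))[k]
    v <- track@values[[nm]]
    if (is.null(v)) stop("site on unknown chromosome: ", nm)
    s <- summitOf(sites[k])
    b <- binsOfInterval(s - window / 2, s + window / 2, bs, length(v))
    if (!length(b) || all(is.na(v[b]))) NA_real_ else mean(v[b], na.rm = TRUE)
  }, 0)
}

## mean track value over unmasked bins overlapping a 0-based interval
meanOverInterval <- function(track, chrom, s0, e0) {
  v <- track@values[[chrom]]
  b <- binsOfInterval(s0, e0, track@binSize, length(v))
  if (!length(b) || all(is.na(v[b]))) NA_real_ else mean(v[b], na.rm = TRUE)
}

#' Split sites into quartile groups by value
#'
#' Sites are sorted ascending by value (ties broken by `tieBreak`, by
#' default input order, for determinism) and split into four contiguous
#' groups of near-equal size; when the count is not divisible by four the
#' remainders go to the lower quartiles (10 values give sizes 3,3,2,2).
#' Q4 holds the highest values.  `NA` values get label `NA`.
#'
#' @param values numeric per-site values.
#' @param tieBreak secondary sort key (e.g. genomic coordinate).
#' @return factor with levels `Q1`..`Q4`.
#' @export
quartileGroups <- function(values, tieBreak = seq_along(values)) {
  ok <- which(!is.na(values))
  if (length(ok) < 4L) stop("need at least 4 unmasked values")
  ord <- ok[order(values[ok], tieBreak[ok])]
  n <- length(ord)
  q <- n %/% 4L; r <- n %% 4L
  sizes <- rep(q, 4L) + as.integer(seq_len(4L) <= r)
  labels <- rep(paste0("Q", 1:4), times = sizes)
  out <- rep(NA_character_, length(values))
  out[ord] <- labels
  factor(out, levels = paste0("Q", 1:4))
}

#' Per-site ratio analysis normalized to a control median
#'
#' Computes `ratio_i = numerator_i / denominator_i`, divides all ratios by
#' the median of the control ratios, and reports the median of the
#' normalized ratios in linear scale.  Sites with a non-positive or
#' masked denominator are masked.  The result is invariant to any common
#' rescaling of the numerator and denominator tracks.
#'
#' @param numerator,denominator paired per-site nFE values.
#' @param controlRatios per-site ratios of the control condition (the
#'   control's own `ratios` component).
#' @return list with `ratios`, `normalized` and `medianFold`.
#' @export
ratioAnalysis <- function(numerator, denominator, controlRatios) {
  if (length(numerator) != length(denominator))
    stop("numerator and denominator must be paired")
  if (!length(controlRatios) || all(is.na(controlRatios)))
    stop("control ratio set is empty")
  den <- ifelse(is.na(denominator) | denominator <= 0, NA_real_, denominator)
  ratios <- numerator / den
  ctrlMed <- stats::median(controlRatios, na.rm = TRUE)
  normalized <- ratios / ctrlMed
  list(ratios = ratios, normalized = normalized,
       medianFold = stats::median(normalized, na.rm = TRUE))
}

## rows = sites, cols = offsets (-flank..flank in binSize steps), values
## sampled at the summit bin plus offset; NA outside the chromosome
.profileRows <- function(track, sites, flank) {
  bs <- track@binSize
  k <- as.integer(flank / bs)
  off <- -k:k
  m <- matrix(NA_real_, nrow = length(sites), ncol = length(off))
  for (r in seq_along(sites)) {
    nm <- as.character(seqnames(sites))[r]
    v <- track@values[[nm]]
    b0 <- binOf(summitOf(sites[r]), bs)
    b <- b0 + off
    inside <- b >= 1L & b <= length(v)
    m[r, inside] <- v[b[inside]]
  }
  colnames(m) <- off * bs
  m
}

#' Aggregate profile around site summits
#'
#' Mean nFE per offset bin over sites, with a normal-theory 95% confidence
#' band (`mean +/- 1.96 * sd / sqrt(n)` over unmasked rows per offset).
#'
#' @param track `BinnedTrack`.
#' @param sites `GRanges` (at least 2).
#' @param flank flank in bp, a multiple of the track bin size.
#' @return data.frame with `offset` (bp), `mean`, `lower`, `upper`, `n`.
#' @export
aggregateProfile <- function(track, sites, flank) {
  stopifnot(is(track, "BinnedTrack"))
  if (flank %% track@binSize != 0) stop("flank must be a multiple of binSize")
  if (length(sites) < 2L) stop("need at least 2 sites for a confidence band")
  m <- .profileRows(track, sites, flank)
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  sem <- sdv / sqrt(pmax(n, 1))
  data.frame(offset = as.numeric(colnames(m)), mean = mu,
             lower = mu - 1.96 * sem, upper = mu + 1.96 * sem, n = n,
             row.names = NULL)
}

#' Profile heatmap matrix
#'
#' Per-site profile rows around summits, ordered by descending sort key
#' (stable: equal keys preserve input order).
#'
#' @param track `BinnedTrack`.
#' @param sites `GRanges`.
#' @param flank flank in bp.
#' @param sortKey numeric key per site (e.g. Scc2 nFE); `NULL` keeps the
#'   input order.
#' @return numeric matrix (rows sites, cols offsets in bp) with a
#'   `"siteOrder"` attribute giving the original site index per row.
#' @export
profileHeatmap <- function(track, sites, flank, sortKey = NULL) {
  m <- .profileRows(track, sites, flank)
  ord <- if (is.null(sortKey)) seq_len(nrow(m)) else
    order(-sortKey)  # radix order is stable
  out <- m[ord, , drop = FALSE]
  attr(out, "siteOrder") <- ord
  out
}

#' Annotate sites with distance to the centromere
#'
#' Distance = `|site summit - centromere midpoint|` on the same
#' chromosome.  Sites closer than `exclusion` (strictly less than) are
#' flagged centromeric and should be excluded from arm-site analyses.
#'
#' @param sites `GRanges`.
#' @param annotation `GenomeAnnotation` (with centromeres).
#' @param exclusion exclusion radius in bp (default 5000).
#' @return `sites` with `distanceToCen` and `isCentromeric` columns.
#' @export
annotateCentromereDistance <- function(sites, annotation, exclusion = 5000) {
  cen <- centromeres(annotation)
  sn <- as.character(seqnames(sites))
  if (!all(sn %in% names(cen)))
    stop("site on a chromosome without centromere")
  d <- abs(summitOf(sites) - cen[sn])
  mcols(sites)$distanceToCen <- unname(d)
  mcols(sites)$isCentromeric <- unname(d < exclusion)
  sites
}
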
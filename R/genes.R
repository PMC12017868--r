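## Gene-orientation analysis around cohesin sites: nearest flanking genes,
## CEN-/TEL-oriented labels relative to the centromere, convergence of
## the flanking pair, per-gene transcriptional activity from an RNA
## polymerase II (Rpo21) track, and two-group Mann-Whitney comparisons.

#' Nearest flanking genes of cohesin sites with orientation labels
#'
#' For each site the nearest non-containing gene on each side is found.
#' The pair is convergent when the two genes' 3' ends face the site
#' (left gene on `+`, right gene on `-`).  Relative to the centromere of
#' the chromosome, the CEN-oriented gene is the gene on the
#' centromere-distal side of the site transcribed toward the centromere;
#' the TEL-oriented gene is on the centromere-proximal side and
#' transcribed away from it.  A flanking gene that does not satisfy the
#' corresponding rule yields `NA` for that label.  Sites lacking a flank
#' on either side are dropped (reported in the `"dropped"` attribute).
#'
#' @param sites `GRanges` of cohesin sites.
#' @param genesGr `GRanges` of genes with strand and `name` column.
#' @param annotation `GenomeAnnotation` (for centromeres).
#' @return data.frame, one row per retained site: site coordinates,
#'   left/right gene name, strand and length, `convergent`,
#'   `cenOrientedGene`, `telOrientedGene` (+ their lengths).
#' @export
flankingGenes <- function(sites, genesGr, annotation) {
  cen <- centromeres(annotation)
  sn <- as.character(seqnames(sites))
  if (!all(sn %in% names(cen)))
    stop("site on a chromosome without centromere")
  rows <- list(); dropped <- character(0)
  for (k in seq_along(sites)) {
    nm <- sn[k]
    g <- genesGr[as.character(seqnames(genesGr)) == nm]
    s0 <- start(sites)[k] - 1; e0 <- end(sites)[k]
    summit <- (s0 + e0) / 2
    gs0 <- start(g) - 1; ge0 <- end(g)
    leftIdx <- which(ge0 <= s0)
    rightIdx <- which(gs0 >= e0)
    if (!length(leftIdx) || !length(rightIdx)) {
      dropped <- c(dropped, sprintf("%s:%d-%d (missing flank)", nm, s0, e0))
      next
    }
    li <- leftIdx[which.max(ge0[leftIdx])]
    ri <- rightIdx[which.min(gs0[rightIdx])]
    lStrand <- as.character(strand(g))[li]
    rStrand <- as.character(strand(g))[ri]
    convergent <- lStrand == "+" && rStrand == "-"
    onLeftArm <- summit < cen[[nm]]
    ## distal side: away from the centromere; toward CEN means "+" on the
    ## left arm (rightward) and "-" on the right arm (leftward)
    if (onLeftArm) {
      cenGene <- if (lStrand == "+") li else NA_integer_
      telGene <- if (rStrand == "-") ri else NA_integer_
    } else {
      cenGene <- if (rStrand == "-") ri else NA_integer_
      telGene <- if (lStrand == "+") li else NA_integer_
    }
    gname <- function(i) if (is.na(i)) NA_character_ else
      as.character(mcols(g)$name[i])
    glen <- function(i) if (is.na(i)) NA_real_ else width(g)[i]
    rows[[length(rows) + 1L]] <- data.frame(
      site = k, chrom = nm, summit = summit,
      leftGene = gname(li), leftStrand = lStrand, leftLength = glen(li),
      rightGene = gname(ri), rightStrand = rStrand, rightLength = glen(ri),
      convergent = convergent,
      cenOrientedGene = gname(cenGene), cenOrientedLength = glen(cenGene),
      telOrientedGene = gname(telGene), telOrientedLength = glen(telGene),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(0))
  attr(out, "dropped") <- dropped
  out
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney U test: exact enumeration when the smaller
#' group has at most `exactMax` observations and there are no ties,
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exactMax maximum smaller-group size for the exact test
#'   (default 8).
#' @return list with `U` (statistic, for group `a`), `p` (two-sided),
#'   `n` (group sizes), `method`.
#' @export
compareGeneGroups <- function(a, b, exactMax = 8) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty group")
  hasTies <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= exactMax && !hasTies
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(wt$p.value, 1),
       n = c(length(a), length(b)),
       method = if (exact) "exact" else "normal approximation")
}

#' Per-gene transcriptional activity from an Rpo21-type track
#'
#' Mean nFE over the unmasked bins overlapping each gene body
#' (strand-agnostic).
#'
#' @param genesGr `GRanges` of genes.
#' @param track nFE `BinnedTrack`.
#' @return numeric vector of per-gene values (`NA` for fully masked
#'   genes).
#' @export
geneActivity <- function(genesGr, track) {
  vapply(seq_along(genesGr), function(k) {
    nm <- as.character(seqnames(genesGr))[k]
    meanOverInterval(track, nm, start(genesGr)[k] - 1, end(genesGr)[k])
  }, 0)
}
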
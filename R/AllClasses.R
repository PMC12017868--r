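#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end strand width mcols
#'   mcols<- findOverlaps countOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom Matrix sparseMatrix rowSums colSums forceSymmetric Diagonal
NULL

#' Genome annotation container
#'
#' Holds the chromosome sizes, centromere midpoints, gene models and named
#' binding-site collections used throughout the package.  All intervals are
#' stored as `GRanges` (1-based closed, the Bioconductor convention);
#' file readers convert from BED (0-based half-open) and GFF3 (1-based
#' closed) on the way in.  Centromeres are stored as midpoints in 0-based
#' bp, one per chromosome.
#'
#' @slot seqlengths named numeric, chromosome lengths in bp.
#' @slot centromeres named numeric, centromere midpoints (0-based bp),
#'   exactly one per chromosome.
#' @slot genes `GRanges` with strand and a `name` metadata column.
#' @slot sites named list of `GRanges`, e.g. `cohesin`, `scc2`.
#'
#' @export
setClass("GenomeAnnotation",
  slots = c(
    seqlengths  = "numeric",
    centromeres = "numeric",
    genes       = "GRanges",
    sites       = "list"
  )
)

setValidity("GenomeAnnotation", function(object) {
  sl <- object@seqlengths
  if (length(sl) == 0L) return("no chromosomes")
  if (is.null(names(sl)) || anyNA(names(sl)) || any(names(sl) == ""))
    return("chromosomes must be named")
  if (anyDuplicated(names(sl))) return("duplicate chromosome names")
  if (any(!is.finite(sl)) || any(sl <= 0)) return("chromosome lengths must be positive")
  cen <- object@centromeres
  if (!setequal(names(cen), names(sl)))
    return("exactly one centromere per chromosome required")
  if (any(cen < 0 | cen >= sl[names(cen)]))
    return("centromere midpoint outside its chromosome")
  chk <- function(gr, what) {
    if (length(gr) == 0L) return(NULL)
    sn <- as.character(seqnames(gr))
    if (!all(sn %in% names(sl)))
      return(sprintf("%s on unknown chromosome", what))
    if (any(start(gr) < 1L) || any(end(gr) > sl[sn]))
      return(sprintf("%s interval beyond chromosome end", what))
    NULL
  }
  msg <- chk(object@genes, "gene")
  if (!is.null(msg)) return(msg)
  for (nm in names(object@sites)) {
    msg <- chk(object@sites[[nm]], paste0("site[", nm, "]"))
    if (!is.null(msg)) return(msg)
  }
  TRUE
})

#' Fixed-bin-size genomic track
#'
#' Per-chromosome vectors of non-negative values on a fixed bin grid.  A
#' position `p` (0-based bp) belongs to bin `floor(p / binSize) + 1`.
#' Masked (unquantifiable) bins are stored as `NA` and are excluded from
#' every downstream statistic.  `semantics` records what the values mean:
#' `"raw"` read counts, `"scaled"` counts, or `"nFE"` (spike-in calibrated
#' normalized fold-enrichment).
#'
#' @slot binSize integer bin size in bp.
#' @slot values named list of numeric vectors, one per chromosome;
#'   `NA` = masked bin.
#' @slot semantics one of `"raw"`, `"scaled"`, `"nFE"`.
#' @slot seqlengths named numeric chromosome lengths.
#'
#' @export
setClass("BinnedTrack",
  slots = c(
    binSize    = "integer",
    values     = "list",
    semantics  = "character",
    seqlengths = "numeric"
  )
)

setValidity("BinnedTrack", function(object) {
  if (length(object@binSize) != 1L || object@binSize < 1L)
    return("binSize must be a single positive integer")
  if (!object@semantics %in% c("raw", "scaled", "nFE"))
    return("semantics must be one of raw/scaled/nFE")
  sl <- object@seqlengths
  if (!setequal(names(object@values), names(sl)))
    return("values and seqlengths must cover the same chromosomes")
  for (nm in names(object@values)) {
    v <- object@values[[nm]]
    n <- ceiling(sl[[nm]] / object@binSize)
    if (length(v) != n)
      return(sprintf("chromosome %s: expected %d bins, got %d", nm, n, length(v)))
    if (any(v < 0, na.rm = TRUE))
      return("track values must be non-negative")
  }
  TRUE
})

#' Cis contact map
#'
#' A symmetric binned raw-count matrix for one chromosome, with optional
#' per-bin balancing weights (`NA` = masked bin; empty vector = not yet
#' balanced).  The map total counts off-diagonal entries twice and the
#' diagonal once, i.e. `sum()` of the symmetric matrix.
#'
#' @slot chrom chromosome name.
#' @slot binSize integer bin size in bp.
#' @slot chromLength chromosome length in bp.
#' @slot counts symmetric sparse matrix (`dsCMatrix`) of raw counts.
#' @slot weights numeric balancing weights (length 0 if unbalanced).
#'
#' @export
setClass("ContactMap",
  slots = c(
    chrom       = "character",
    binSize     = "integer",
    chromLength = "numeric",
    counts      = "Matrix",
    weights     = "numeric"
  )
)

setValidity("ContactMap", function(object) {
  n <- ceiling(object@chromLength / object@binSize)
  if (!Matrix::isSymmetric(object@counts))
    return("counts must be symmetric")
  if (nrow(object@counts) != n)
    return(sprintf("counts must be %d x %d for this chromosome/bin size", n, n))
  if (any(object@counts@x < 0))
    return("counts must be non-negative")
  if (length(object@weights) > 0L) {
    if (length(object@weights) != n)
      return("weights length must equal the number of bins")
    if (any(object@weights <= 0, na.rm = TRUE))
      return("weights must be positive on unmasked bins")
  }
  TRUE
})

## ---- constructors ----

#' @rdname GenomeAnnotation-class
#' @param seqlengths named numeric chromosome lengths (bp).
#' @param centromeres named numeric centromere midpoints (0-based bp).
#' @param genes `GRanges` of genes (strand set, `name` mcol).
#' @param sites named list of `GRanges` site collections.
#' @export
GenomeAnnotation <- function(seqlengths, centromeres,
                             genes = GRanges(), sites = list()) {
  new("GenomeAnnotation",
      seqlengths = seqlengths, centromeres = centromeres,
      genes = genes, sites = sites)
}

#' @rdname BinnedTrack-class
#' @param binSize bin size in bp.
#' @param values named list of per-chromosome numeric vectors.
#' @param seqlengths named numeric chromosome lengths.
#' @param semantics `"raw"`, `"scaled"` or `"nFE"`.
#' @export
BinnedTrack <- function(binSize, values, seqlengths, semantics = "raw") {
  new("BinnedTrack", binSize = as.integer(binSize), values = values,
      seqlengths = seqlengths, semantics = semantics)
}

#' @rdname ContactMap-class
#' @param chrom chromosome name.
#' @param binSize bin size in bp.
#' @param chromLength chromosome length in bp.
#' @param counts symmetric sparse (or coercible) count matrix.
#' @param weights optional balancing weights.
#' @export
ContactMap <- function(chrom, binSize, chromLength, counts,
                       weights = numeric(0)) {
  counts <- forceSymmetric(methods::as(methods::as(counts, "CsparseMatrix"),
                                       "generalMatrix"), uplo = "U")
  new("ContactMap", chrom = chrom, binSize = as.integer(binSize),
      chromLength = chromLength, counts = counts, weights = weights)
}

## ---- accessors ----

#' Accessors for the core classes
#'
#' @param x object.
#' @return the corresponding slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeAnnotation", function(x) x@seqlengths)
#' @rdname accessors
#' @export
setMethod("chromLengths", "BinnedTrack", function(x) x@seqlengths)

#' @rdname accessors
#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))
#' @rdname accessors
#' @export
setMethod("centromeres", "GenomeAnnotation", function(x) x@centromeres)

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname accessors
#' @param name site-collection name.
#' @export
setGeneric("siteSet", function(x, name) standardGeneric("siteSet"))
#' @rdname accessors
#' @export
setMethod("siteSet", "GenomeAnnotation", function(x, name) {
  if (!name %in% names(x@sites))
    stop("no site collection named '", name, "'")
  x@sites[[name]]
})

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setMethod("binSize", "BinnedTrack", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "ContactMap", function(x) x@binSize)

#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setMethod("trackValues", "BinnedTrack", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("semantics", function(x) standardGeneric("semantics"))
#' @rdname accessors
#' @export
setMethod("semantics", "BinnedTrack", function(x) x@semantics)

#' @rdname accessors
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))
#' @rdname accessors
#' @export
setMethod("contactCounts", "ContactMap", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("contactTotal", function(x) standardGeneric("contactTotal"))
#' @rdname accessors
#' @export
setMethod("contactTotal", "ContactMap", function(x) sum(x@counts))

#' @rdname accessors
#' @export
setGeneric("balancingWeights", function(x) standardGeneric("balancingWeights"))
#' @rdname accessors
#' @export
setMethod("balancingWeights", "ContactMap", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setMethod("nBins", "ContactMap",
          function(x) as.integer(ceiling(x@chromLength / x@binSize)))

#' @rdname accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @rdname accessors
#' @export
setMethod("chromName", "ContactMap", function(x) x@chrom)

## ---- show ----

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", length(object@seqlengths), "chromosome(s):",
      paste0(names(object@seqlengths), " (",
             format(object@seqlengths, big.mark = ","), " bp)",
             collapse = ", "), "\n")
  cat("  genes:", length(object@genes), "\n")
  cat("  site sets:",
      if (length(object@sites))
        paste0(names(object@sites), " (", vapply(object@sites, length, 0L),
               ")", collapse = ", ")
      else "none", "\n")
})

setMethod("show", "BinnedTrack", function(object) {
  nb <- sum(vapply(object@values, length, 0L))
  nm <- sum(vapply(object@values, function(v) sum(is.na(v)), 0L))
  cat("BinnedTrack [", object@semantics, "] bin size ", object@binSize,
      " bp, ", length(object@values), " chromosome(s), ", nb, " bins (",
      nm, " masked)\n", sep = "")
})

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap ", object@chrom, ": ", nBins(object), " x ", nBins(object),
      " bins of ", object@binSize, " bp, total ",
      format(contactTotal(object), big.mark = ","), " contacts, ",
      if (length(object@weights)) "balanced" else "unbalanced", "\n",
      sep = "")
})

## ---- small shared helpers ----

## 0-based bp position -> 1-based bin index
binOf <- function(pos, binSize) as.integer(floor(pos / binSize)) + 1L

## 1-based bin index -> 0-based bp center
binCenter <- function(bin, binSize) (bin - 1) * binSize + binSize / 2

## summit (0-based bp midpoint) of GRanges intervals
summitOf <- function(gr) (start(gr) - 1 + end(gr)) / 2

## bins overlapped by the 0-based half-open interval [s0, e0)
binsOfInterval <- function(s0, e0, binSize, nbins) {
  lo <- max(1L, binOf(s0, binSize))
  hi <- min(nbins, as.integer(ceiling(e0 / binSize)))
  if (lo > hi) integer(0) else lo:hi
}
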
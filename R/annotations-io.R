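## Readers and writers for the plain-text formats the pipeline consumes:
## chrom.sizes, BED4/6, GFF3 (genes), bedGraph (tracks), COO triplet text
## (contact matrices) and BEDPE (loop lists).  BED/bedGraph/BEDPE are
## 0-based half-open on disk; GRanges are 1-based closed in memory.

#' Read a two-column chromosome sizes file
#'
#' @param path path to a `chrom.sizes`-style TSV (name, length).
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome names in ", path)
  stats::setNames(as.numeric(df$length), df$chrom)
}

#' Read a BED file of intervals into GRanges
#'
#' BED coordinates (0-based half-open) are converted to 1-based closed.
#' Columns beyond the third are interpreted as name, score, strand when
#' present.  Intervals extending beyond the chromosome end are an error,
#' never clipped.
#'
#' @param path BED3/4/5/6 file path.
#' @param seqlengths named numeric chromosome lengths used for validation.
#' @return `GRanges` with `name` (and `score`) metadata columns when present.
#' @export
readBed <- function(path, seqlengths) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  chrom <- as.character(df[[1L]])
  s0 <- as.numeric(df[[2L]]); e0 <- as.numeric(df[[3L]])
  if (!all(chrom %in% names(seqlengths)))
    stop("BED interval on unknown chromosome in ", path)
  if (any(s0 < 0) || any(e0 <= s0))
    stop("invalid BED interval (need 0 <= start < end) in ", path)
  if (any(e0 > seqlengths[chrom]))
    stop("BED interval beyond chromosome end in ", path)
  strand <- if (ncol(df) >= 6L) as.character(df[[6L]]) else "*"
  gr <- GRanges(chrom, IRanges(s0 + 1, e0), strand = strand)
  if (ncol(df) >= 4L) mcols(gr)$name <- as.character(df[[4L]])
  if (ncol(df) >= 5L) mcols(gr)$score <- as.numeric(df[[5L]])
  gr
}

#' Write GRanges as BED (0-based half-open)
#'
#' @param gr `GRanges`; `name` and `score` metadata columns are written
#'   when present.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1, end = end(gr),
                   stringsAsFactors = FALSE)
  hasName <- "name" %in% names(mcols(gr))
  hasScore <- "score" %in% names(mcols(gr))
  if (hasName || hasScore) {
    df$name <- if (hasName) mcols(gr)$name else "."
    if (hasScore) {
      df$score <- mcols(gr)$score
      df$strand <- as.character(strand(gr))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 input keeps only `gene` feature rows (all rows if none are typed
#' `gene`) and converts nothing: GFF3 is already 1-based closed.  The gene
#' name is taken from the `Name=` or `ID=` attribute.  BED input is
#' converted from 0-based half-open.
#'
#' @param path gene file; format chosen by extension (`.gff`/`.gff3` vs
#'   anything else treated as BED).
#' @param seqlengths named numeric chromosome lengths.
#' @return stranded `GRanges` with a `name` column.
#' @export
readGenes <- function(path, seqlengths) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#",
                            quote = "")
    if (ncol(df) < 9L) stop("malformed GFF3: ", path)
    keep <- df[[3L]] == "gene"
    if (!any(keep)) keep <- rep(TRUE, nrow(df))
    df <- df[keep, , drop = FALSE]
    chrom <- as.character(df[[1L]])
    if (!all(chrom %in% names(seqlengths)))
      stop("gene on unknown chromosome in ", path)
    if (any(df[[4L]] < 1) || any(df[[5L]] > seqlengths[chrom]))
      stop("gene interval beyond chromosome end in ", path)
    nm <- sub(".*(?:Name|ID)=([^;]+).*", "\\1", df[[9L]])
    gr <- GRanges(chrom, IRanges(df[[4L]], df[[5L]]), strand = df[[7L]])
    mcols(gr)$name <- nm
    gr
  } else {
    gr <- readBed(path, seqlengths)
    if (is.null(mcols(gr)$name))
      mcols(gr)$name <- paste0("gene", seq_along(gr))
    gr
  }
}

#' Assemble a validated GenomeAnnotation from files
#'
#' @param chromSizes path to a chrom.sizes file.
#' @param centromereBed BED of centromere intervals (one per chromosome);
#'   midpoints are stored.
#' @param geneFile optional GFF3/BED of genes.
#' @param siteBeds optional named list of BED paths with binding-site
#'   collections (e.g. `list(cohesin = "...", scc2 = "...")`).
#' @return `GenomeAnnotation`.
#' @export
readAnnotation <- function(chromSizes, centromereBed, geneFile = NULL,
                           siteBeds = list()) {
  sl <- readChromSizes(chromSizes)
  cengr <- readBed(centromereBed, sl)
  cn <- as.character(seqnames(cengr))
  if (anyDuplicated(cn)) stop("more than one centromere for a chromosome")
  if (!setequal(cn, names(sl))) stop("missing centromere for a chromosome")
  cen <- stats::setNames(summitOf(cengr), cn)[names(sl)]
  genes <- if (is.null(geneFile)) GRanges() else readGenes(geneFile, sl)
  sites <- lapply(siteBeds, readBed, seqlengths = sl)
  GenomeAnnotation(sl, cen, genes, sites)
}

## ---- bedGraph tracks ----

#' Read a bedGraph file into a BinnedTrack
#'
#' Records must be aligned to the bin grid (start and end multiples of
#' `binSize`, up to a final partial bin at the chromosome end) and must
#' not overlap.  Bins without a record are masked (`NA`).
#'
#' @param path bedGraph path.
#' @param binSize bin size in bp.
#' @param seqlengths named numeric chromosome lengths.
#' @param semantics value semantics of the track (default `"raw"`).
#' @return `BinnedTrack`.
#' @export
readTrack <- function(path, binSize, seqlengths, semantics = "raw") {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = c("chrom", "start", "end", "value"))
  if (!all(df$chrom %in% names(seqlengths)))
    stop("bedGraph record on unknown chromosome in ", path)
  vals <- lapply(names(seqlengths), function(nm) {
    n <- ceiling(seqlengths[[nm]] / binSize)
    v <- rep(NA_real_, n)
    sub <- df[df$chrom == nm, , drop = FALSE]
    if (nrow(sub) == 0L) return(v)
    endOk <- sub$end %% binSize == 0 | sub$end == seqlengths[[nm]]
    if (any(sub$start %% binSize != 0) || !all(endOk))
      stop("off-grid bedGraph record in ", path)
    seen <- rep(FALSE, n)
    for (k in seq_len(nrow(sub))) {
      b <- binsOfInterval(sub$start[k], sub$end[k], binSize, n)
      if (any(seen[b])) stop("overlapping bedGraph records in ", path)
      seen[b] <- TRUE
      v[b] <- sub$value[k]
    }
    v
  })
  names(vals) <- names(seqlengths)
  BinnedTrack(binSize, vals, seqlengths, semantics)
}

#' Write a BinnedTrack as bedGraph
#'
#' Masked bins are written as absent records; runs of equal-valued bins
#' are merged into one record (grid-aligned), so `readTrack(writeTrack(t))`
#' reproduces `t` on all unmasked bins.
#'
#' @param track `BinnedTrack`.
#' @param path output path.
#' @export
writeTrack <- function(track, path) {
  bs <- track@binSize
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(track@values)) {
    v <- track@values[[nm]]
    if (!length(v)) next
    r <- rle(ifelse(is.na(v), "NA", format(v, digits = 17)))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values != "NA"
    if (!any(keep)) next
    s0 <- (starts[keep] - 1) * bs
    e0 <- pmin(ends[keep] * bs, track@seqlengths[[nm]])
    writeLines(paste(nm, s0, e0, vapply(starts[keep], function(i)
      format(v[i], digits = 17), ""), sep = "\t"), con)
  }
  invisible(path)
}

## ---- COO contact matrices ----

#' Read a COO triplet text file into a ContactMap
#'
#' Triplets are `bin_i bin_j count` with 0-based bin indices; the upper
#' triangle is sufficient, and duplicated pixels are summed.  The matrix
#' is symmetrized on read.
#'
#' @param path triplet text path (may be empty: zero matrix).
#' @param chrom chromosome name.
#' @param binSize bin size in bp.
#' @param chromLength chromosome length in bp.
#' @return `ContactMap`.
#' @export
readContactMatrix <- function(path, chrom, binSize, chromLength) {
  n <- as.integer(ceiling(chromLength / binSize))
  empty <- !file.exists(path) || file.size(path) == 0
  if (!empty) {
    df <- utils::read.table(path, header = FALSE, sep = "",
                            stringsAsFactors = FALSE, comment.char = "#",
                            col.names = c("i", "j", "count"))
    empty <- nrow(df) == 0L
  }
  if (empty) {
    m <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                      dims = c(n, n))
    return(ContactMap(chrom, binSize, chromLength, m))
  }
  if (any(df$count < 0)) stop("negative counts in ", path)
  if (any(df$i < 0 | df$j < 0 | df$i >= n | df$j >= n))
    stop("bin index beyond grid in ", path)
  ii <- pmin(df$i, df$j) + 1L
  jj <- pmax(df$i, df$j) + 1L
  m <- sparseMatrix(i = ii, j = jj, x = df$count, dims = c(n, n))
  ContactMap(chrom, binSize, chromLength, m)
}

#' Write a ContactMap as COO triplet text (upper triangle)
#'
#' @param map `ContactMap`.
#' @param path output path.
#' @export
writeContactMatrix <- function(map, path) {
  tm <- methods::as(methods::as(map@counts, "generalMatrix"), "TsparseMatrix")
  keep <- tm@i <= tm@j & tm@x != 0
  df <- data.frame(i = tm@i[keep], j = tm@j[keep], x = tm@x[keep])
  df <- df[order(df$i, df$j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- BEDPE loop lists ----

#' Read/write loop lists as BEDPE
#'
#' Loops are represented as a `data.frame` with 0-based half-open anchor
#' coordinates (`chrom`, `start1`, `end1`, `start2`, `end2`) plus any
#' numeric/character annotation columns (`obsExp`, `qValue`, `category`,
#' `length`).
#'
#' @param path BEDPE path.
#' @return `data.frame` of loops.
#' @export
readLoops <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start1", "end1", "start2", "end2")
  if (!all(need %in% names(df))) stop("malformed loop BEDPE: ", path)
  df
}

#' @rdname readLoops
#' @param loops loop `data.frame`.
#' @export
writeLoops <- function(loops, path) {
  utils::write.table(loops, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
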
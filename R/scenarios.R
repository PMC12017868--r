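## Deterministic scenario presets encoding the two study conditions the
## package is validated against: a wild-type-like genome with dense short
## cohesin-cohesin loops and little Scc2 at arm sites, and a
## wpl1/eco1-loss-like condition with sparse, long centromere-anchored
## loops and an elevated Scc2/Scc1 ratio (injected median fold 2.53).

.SCENARIOS <- c("wt_like", "wpl1_eco1_like")

## toy two-chromosome genome shared by both scenarios
.scenarioAnnotation <- function() {
  sl <- c(chrI = 400000, chrII = 300000)
  cen <- c(chrI = 200000, chrII = 100000)
  siteStarts <- list(chrI = seq(12000, 392000, by = 20000),
                     chrII = seq(12000, 292000, by = 20000))
  mkSites <- function() {
    grs <- lapply(names(sl), function(nm) {
      p <- siteStarts[[nm]]
      gr <- GRanges(nm, IRanges(p + 1, p + 600), seqlengths = sl)
      mcols(gr)$name <- sprintf("site_%s_%02d", nm, seq_along(p))
      gr
    })
    do.call(c, grs)
  }
  armSites <- mkSites()
  cenSites <- GRanges(names(sl), IRanges(cen - 299, cen + 300),
                      seqlengths = sl)
  mcols(cenSites)$name <- paste0("cenSite_", names(sl))
  cohesin <- c(armSites, cenSites)
  ## convergent gene pair flanking every arm site: the centromere-distal
  ## gene transcribes toward the centromere (CEN-oriented), the proximal
  ## one away from it (TEL-oriented)
  anchorSummits <- .scenarioAnchorSummits()
  geneRows <- list()
  for (k in seq_along(armSites)) {
    nm <- as.character(seqnames(armSites))[k]
    p <- start(armSites)[k] - 1          # 0-based site start
    summit <- p + 300
    isAnchor <- any(abs(anchorSummits[[nm]] - summit) < 1)
    lenCen <- if (isAnchor) 3000 else 1200
    lenTel <- 1500
    onLeftArm <- summit < cen[[nm]]
    lenLeft <- if (onLeftArm) lenCen else lenTel
    lenRight <- if (onLeftArm) lenTel else lenCen
    geneRows[[length(geneRows) + 1L]] <- data.frame(
      chrom = nm,
      start0 = c(p - 300 - lenLeft, p + 900),
      end0   = c(p - 300, p + 900 + lenRight),
      strand = c("+", "-"),
      name = sprintf("g_%s_%02d_%s", nm, k, c("L", "R")),
      cenOriented = c(onLeftArm, !onLeftArm),
      anchorGene = c(onLeftArm && isAnchor, !onLeftArm && isAnchor),
      stringsAsFactors = FALSE)
  }
  gdf <- do.call(rbind, geneRows)
  genesGr <- GRanges(gdf$chrom, IRanges(gdf$start0 + 1, gdf$end0),
                     strand = gdf$strand, seqlengths = sl)
  mcols(genesGr)$name <- gdf$name
  mcols(genesGr)$cenOriented <- gdf$cenOriented
  mcols(genesGr)$anchorGene <- gdf$anchorGene
  GenomeAnnotation(sl, cen, genesGr,
                   sites = list(cohesin = cohesin, arm = armSites))
}

## summits (0-based bp) of the arm cohesin sites that anchor the long
## centromere-originated loops in the wpl1_eco1-like condition
.scenarioAnchorSummits <- function() {
  list(chrI = c(152300, 132300, 112300, 92300,     # left arm, CEN 200 kb
                252300, 272300, 292300, 312300),   # right arm
       chrII = c(52300, 32300,                     # left arm, CEN 100 kb
                 152300, 172300, 192300, 212300))  # right arm
}

## loop tables per chromosome for each condition
.scenarioLoops <- function(name, annotation) {
  sl <- chromLengths(annotation)
  cen <- centromeres(annotation)
  arm <- siteSet(annotation, "arm")
  out <- list()
  for (nm in names(sl)) {
    s <- sort(summitOf(arm[as.character(seqnames(arm)) == nm]))
    if (name == "wt_like") {
      left <- s[s < cen[[nm]]]; right <- s[s > cen[[nm]]]
      adj <- rbind(
        if (length(left) > 1)
          data.frame(anchor1 = left[-length(left)], anchor2 = left[-1]),
        if (length(right) > 1)
          data.frame(anchor1 = right[-length(right)], anchor2 = right[-1]))
      peri <- data.frame(anchor1 = c(max(left), cen[[nm]]),
                         anchor2 = c(cen[[nm]], min(right)))
      lp <- rbind(adj, peri)
      lp$enrichment <- 8; lp$width <- 800
      lp$cenOriginated <- c(rep(FALSE, nrow(adj)), TRUE, TRUE)
      lp$cohesinAnchored <- c(rep(TRUE, nrow(adj)), FALSE, FALSE)
    } else {
      a <- .scenarioAnchorSummits()[[nm]]
      lp <- data.frame(anchor1 = pmin(a, cen[[nm]]),
                       anchor2 = pmax(a, cen[[nm]]),
                       enrichment = 8, width = 800,
                       cenOriginated = TRUE, cohesinAnchored = FALSE)
    }
    lp$chrom <- nm
    out[[nm]] <- lp
  }
  out
}

#' Scenario presets with known ground truth
#'
#' Builds the full configuration bundle for one of the two study-condition
#' presets: `"wt_like"` (dense ~20-kb loops between adjacent cohesin
#' sites, ~10-kb pericentromeric loops, low Scc2 at arm sites) or
#' `"wpl1_eco1_like"` (sparse centromere-anchored loops of ~50-110 kb,
#' every loop anchored at a centromere, arm-site Scc2 raised so the true
#' Scc2/Scc1 median fold versus the wild-type-like preset is 2.53, cohesin
#' bound fraction reduced to 70%).
#'
#' @param name `"wt_like"` or `"wpl1_eco1_like"`.
#' @param seed integer; sample-specific sub-seeds are derived from it.
#' @return list with `annotation`, `chip` (named `ChipSimConfig`s for
#'   `scc1`, `scc2`, `rpo21`), `contacts` (named `ContactSimConfig`s, one
#'   per chromosome), and `groundTruth` (loop manifest, anchor summits,
#'   injected ratio fold).
#' @export
scenarioPreset <- function(name = .SCENARIOS, seed = 1) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  ann <- .scenarioAnnotation()
  sl <- chromLengths(ann)
  cohesin <- siteSet(ann, "cohesin")
  arm <- siteSet(ann, "arm")
  isCenSite <- grepl("^cenSite", mcols(cohesin)$name)
  spikeSize <- sum(sl)

  ## bound fractions; scc1 drops to 70% in the mutant-like condition while
  ## the scc2-bound amount is unchanged, and the arm-site scc2 enrichment
  ## is raised so the per-site ratio fold is exactly
  ## 2.53 = (bf1_wt / bf1_mut) * (e2_mut / e2_wt)
  bf1 <- c(wt_like = 0.30, wpl1_eco1_like = 0.21)
  bf2 <- c(wt_like = 0.10, wpl1_eco1_like = 0.10)
  e2wt <- 1.5
  ratioFold <- 2.53
  e2 <- c(wt_like = e2wt,
          wpl1_eco1_like = ratioFold * e2wt *
            (bf1[["wpl1_eco1_like"]] / bf1[["wt_like"]]) *
            (bf2[["wt_like"]] / bf2[["wpl1_eco1_like"]]))

  enrich <- function(values) {
    gr <- cohesin
    mcols(gr)$enrichment <- values
    gr
  }
  scc1Sites <- enrich(ifelse(isCenSite, 8, 6))
  scc2Sites <- enrich(ifelse(isCenSite, 8, e2[[name]]))
  rpoGenes <- genes(ann)
  mcols(rpoGenes)$enrichment <-
    ifelse(mcols(rpoGenes)$cenOriented,
           ifelse(mcols(rpoGenes)$anchorGene, 6, 2.5), 3)

  off <- match(name, .SCENARIOS) * 1000L
  chip <- list(
    scc1 = chipSimConfig(ann, spikeSize, mixingRatio = 2, depth = 1e6,
                         siteEnrichments = scc1Sites,
                         boundFraction = bf1[[name]], inputNoise = 0.05,
                         seed = seed + off + 1L),
    scc2 = chipSimConfig(ann, spikeSize, mixingRatio = 5, depth = 1e6,
                         siteEnrichments = scc2Sites,
                         boundFraction = bf2[[name]], inputNoise = 0.05,
                         seed = seed + off + 2L),
    rpo21 = chipSimConfig(ann, spikeSize, mixingRatio = 2, depth = 1e6,
                          siteEnrichments = rpoGenes,
                          boundFraction = 0.4, inputNoise = 0.05,
                          seed = seed + off + 3L))

  loops <- .scenarioLoops(name, ann)
  domains <- if (name == "wt_like") {
    lapply(centromeres(ann), function(cp)
      data.frame(start = c(cp - 12000, cp), end = c(cp, cp + 12000),
                 boost = 1.8))
  } else lapply(centromeres(ann), function(cp) NULL)
  cenIns <- if (name == "wt_like") 0.6 else 0.35
  contacts <- lapply(names(sl), function(nm) {
    contactSimConfig(chrom = nm, chromLength = sl[[nm]], binSize = 1000,
                     depth = 12.5 * sl[[nm]], alpha = 1.3,
                     loops = loops[[nm]][, c("anchor1", "anchor2",
                                             "enrichment", "width")],
                     domains = domains[[nm]],
                     cenPos = centromeres(ann)[[nm]],
                     cenInsulation = cenIns,
                     seed = seed + off + 10L + match(nm, names(sl)))
  })
  names(contacts) <- names(sl)

  manifest <- do.call(rbind, loops)
  manifest$length <- manifest$anchor2 - manifest$anchor1
  rownames(manifest) <- NULL
  list(name = name, annotation = ann, chip = chip, contacts = contacts,
       groundTruth = list(loops = manifest,
                          anchorSummits = .scenarioAnchorSummits(),
                          ratioFold = ratioFold,
                          scc1BoundFraction = bf1[[name]],
                          scc2BoundFraction = bf2[[name]]))
}
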
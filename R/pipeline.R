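## End-to-end orchestration of a scenario run: simulate -> calibrate ->
## site analytics -> contact analytics -> gene context -> report.

#' Default pipeline parameters
#'
#' All analysis defaults in one place: peak threshold 2.0, site window
#' 400 bp, centromere exclusion 5,000 bp, APA flank 10,000 bp and minimum
#' distance 5,000 bp, loop-caller FDR 0.1 with 2,500-bp merge and
#' 16/8-pixel neighborhoods, insulation windows 5,000 and 10,000 bp,
#' centromere radius 5,000 bp for loop classification, and an
#' anchor-matching tolerance of one matrix bin.
#'
#' @return named list of parameters.
#' @export
pipelineDefaults <- function() {
  list(threshold = 2.0, siteWindow = 400, exclusion = 5000,
       flank = 10000, minDist = 5000, fdr = 0.1, mergeDist = 2500,
       windowPx = 16, peakPx = 8, insulationWindows = c(5000, 10000),
       cenRadius = 5000, anchorToleranceBins = 1, minInputReads = 1)
}

.calibrateSample <- function(sim, simCtrl) {
  orS <- occupancyRatio(sim$targetTotals[["chip"]], sim$spikeTotals[["chip"]],
                        sim$targetTotals[["input"]], sim$spikeTotals[["input"]])
  orC <- occupancyRatio(simCtrl$targetTotals[["chip"]],
                        simCtrl$spikeTotals[["chip"]],
                        simCtrl$targetTotals[["input"]],
                        simCtrl$spikeTotals[["input"]])
  list(or = orS, orControl = orC, nf = normalizationFactor(orS, orC))
}

#' Run the full scenario pipeline
#'
#' Simulates the named scenario (plus a wild-type-like calibration
#' control), computes occupancy ratios and normalization factors, builds
#' nFE tracks, calls peaks, quantifies sites (quartiles, Scc2/Scc1 ratio
#' fold versus the control), analyzes the contact maps (balancing, decay,
#' insulation, loop calling, classification, anchor sites, APA), labels
#' flanking genes and runs the anchor/non-anchor gene comparisons.
#' Deterministic given `seed`.
#'
#' @param scenario `"wt_like"` or `"wpl1_eco1_like"`.
#' @param seed integer seed.
#' @param params parameter list (see [pipelineDefaults()]); partial lists
#'   are merged over the defaults.
#' @param outDir optional output directory; when given, the report JSON,
#'   nFE bedGraphs, peak BEDs and the loop BEDPE are written there.
#' @return report list (class `RunReport`).
#' @export
runPipeline <- function(scenario = c("wt_like", "wpl1_eco1_like"),
                        seed = 1, params = list(), outDir = NULL) {
  scenario <- match.arg(scenario)
  p <- utils::modifyList(pipelineDefaults(), params)
  preset <- scenarioPreset(scenario, seed)
  ctrl <- if (scenario == "wt_like") preset else scenarioPreset("wt_like", seed)
  ann <- preset$annotation
  cen <- centromeres(ann)

  ## --- calibration ---
  sims <- lapply(preset$chip, simulateChipCounts)
  simsCtrl <- if (scenario == "wt_like") sims else
    lapply(ctrl$chip, simulateChipCounts)
  calib <- lapply(names(sims), function(ab)
    .calibrateSample(sims[[ab]], simsCtrl[[ab]]))
  names(calib) <- names(sims)
  tracks <- lapply(names(sims), function(ab)
    nfeTrack(sims[[ab]]$chip, sims[[ab]]$input, calib[[ab]]$nf,
             minInputReads = p$minInputReads))
  names(tracks) <- names(sims)
  tracksCtrl <- if (scenario == "wt_like") tracks else
    lapply(names(simsCtrl), function(ab)
      nfeTrack(simsCtrl[[ab]]$chip, simsCtrl[[ab]]$input, 1,
               minInputReads = p$minInputReads))
  if (is.null(names(tracksCtrl))) names(tracksCtrl) <- names(simsCtrl)

  ## --- peaks ---
  peaks <- lapply(tracks[c("scc1", "scc2")], callPeaks,
                  threshold = p$threshold)
  overlapScc2InScc1 <- peakOverlapFraction(peaks$scc2, peaks$scc1)
  corr <- trackCorrelation(tracks$scc1, tracks$scc2)

  ## --- sites ---
  cohesin <- siteSet(ann, "cohesin")
  cohesin <- annotateCentromereDistance(cohesin, ann, p$exclusion)
  armSites <- cohesin[!mcols(cohesin)$isCentromeric]
  scc1At <- quantifyAtSites(tracks$scc1, armSites, p$siteWindow)
  scc2At <- quantifyAtSites(tracks$scc2, armSites, p$siteWindow)
  quart <- quartileGroups(scc2At, tieBreak = start(armSites))
  ctrlRatios <- quantifyAtSites(tracksCtrl$scc2, armSites, p$siteWindow) /
    quantifyAtSites(tracksCtrl$scc1, armSites, p$siteWindow)
  ratio <- ratioAnalysis(scc2At, scc1At, ctrlRatios)
  siteTable <- data.frame(chrom = as.character(seqnames(armSites)),
                          start = start(armSites) - 1, end = end(armSites),
                          name = mcols(armSites)$name,
                          scc1 = scc1At, scc2 = scc2At,
                          distanceToCen = mcols(armSites)$distanceToCen,
                          quartile = as.character(quart),
                          ratioNorm = ratio$normalized,
                          stringsAsFactors = FALSE)

  ## --- contacts ---
  maps <- lapply(preset$contacts, simulateContactMap)
  maps <- lapply(maps, balanceIterative)
  binSizeMap <- maps[[1]]@binSize
  ## loops, insulation and the report APA are computed chromosome-wide so
  ## that windows spanning the centromere (centromere-anchored loops) are
  ## testable; per-arm expected is still used by expectedCis()-based
  ## analyses such as cenContactByDistance()
  loops <- do.call(rbind, lapply(names(maps), function(nm)
    callLoops(maps[[nm]], windowPx = p$windowPx,
              peakPx = p$peakPx, fdr = p$fdr, mergeDist = p$mergeDist,
              minDist = p$minDist)))
  loops <- classifyLoops(loops, ann, cohesin, cenRadius = p$cenRadius)
  loopSummary <- attr(loops, "summary")
  anchorRes <- anchorSiteClassification(
    armSites, loops, ann, cenRadius = p$cenRadius,
    tolerance = p$anchorToleranceBins * binSizeMap)
  siteTable$anchor <- mcols(anchorRes$sites)$anchor
  decay <- decayCurve(unname(maps))
  ins <- lapply(names(maps), function(nm)
    insulationScore(maps[[nm]], windows = p$insulationWindows))
  names(ins) <- names(maps)
  cenProfile <- insulationAroundLoci(ins, cen, flank = 20000)
  apa <- if (nrow(loops)) {
    pileup(maps, data.frame(chrom = loops$chrom,
                            pos1 = (loops$start1 + loops$end1) / 2,
                            pos2 = (loops$start2 + loops$end2) / 2),
           flank = p$flank, minDist = p$minDist, cenPositions = NULL)
  } else NULL
  cenLoops <- loops[loops$category == "centromere-originated", , drop = FALSE]

  ## --- genes ---
  flanks <- flankingGenes(armSites, genes(ann), ann)
  act <- geneActivity(genes(ann), tracks$rpo21)
  gname <- as.character(mcols(genes(ann))$name)
  anchorOfSite <- siteTable$anchor[flanks$site]
  cenLen <- split(flanks$cenOrientedLength, anchorOfSite)
  cenAct <- split(act[match(flanks$cenOrientedGene, gname)], anchorOfSite)
  geneTests <- list()
  if (all(c("TRUE", "FALSE") %in% names(cenLen))) {
    geneTests$cenOrientedLength <-
      compareGeneGroups(cenLen[["TRUE"]], cenLen[["FALSE"]])
    geneTests$cenOrientedActivity <-
      compareGeneGroups(cenAct[["TRUE"]], cenAct[["FALSE"]])
  }

  report <- structure(list(
    scenario = scenario, seed = seed, params = p,
    calibration = lapply(calib, function(x)
      list(or = x$or, orControl = x$orControl, nf = x$nf)),
    peaks = list(scc1Count = length(peaks$scc1),
                 scc2Count = length(peaks$scc2),
                 scc2OverlapScc1 = overlapScc2InScc1,
                 scc1Scc2Spearman = corr),
    sites = list(n = length(armSites),
                 scc2MedianByQuartile = tapply(scc2At, quart, stats::median),
                 ratioMedianFold = ratio$medianFold),
    loops = list(count = nrow(loops),
                 meanLength = if (nrow(loops)) mean(loops$length) else NA,
                 cenOriginatedCount = nrow(cenLoops),
                 cenOriginatedMeanLength =
                   if (nrow(cenLoops)) mean(cenLoops$length) else NA,
                 summary = loopSummary,
                 table = loops),
    anchors = list(anchorCount = anchorRes$anchorCount,
                   nonAnchorCount = anchorRes$nonAnchorCount),
    apa = list(centralScore = if (is.null(apa)) NA else apa$centralScore,
               nUsed = if (is.null(apa)) 0L else apa$nUsed),
    insulation = list(cenProfile = cenProfile,
                      cenProfileMinOffset =
                        cenProfile$offset[which.min(cenProfile$mean)]),
    decay = list(slope5to100kb = decaySlope(decay, c(5000, 100000))),
    geneTests = geneTests,
    siteTable = siteTable,
    groundTruth = preset$groundTruth
  ), class = "RunReport")

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (ab in names(tracks))
      writeTrack(tracks[[ab]], file.path(outDir, paste0("nfe_", ab, ".bedGraph")))
    for (ab in names(peaks))
      writeBed(peaks[[ab]], file.path(outDir, paste0("peaks_", ab, ".bed")))
    writeLoops(loops, file.path(outDir, "loops.bedpe"))
    utils::write.table(siteTable, file.path(outDir, "site_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(reportMetrics(report),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Flatten a report to named numeric metrics
#'
#' @param report `RunReport`.
#' @return named list of scalar metrics.
#' @export
reportMetrics <- function(report) {
  m <- list(
    scc1_or = report$calibration$scc1$or,
    scc1_nf = report$calibration$scc1$nf,
    scc2_or = report$calibration$scc2$or,
    scc2_nf = report$calibration$scc2$nf,
    scc1_peak_count = report$peaks$scc1Count,
    scc2_peak_count = report$peaks$scc2Count,
    scc2_overlap_scc1 = report$peaks$scc2OverlapScc1,
    scc1_scc2_spearman = report$peaks$scc1Scc2Spearman,
    ratio_median_fold = report$sites$ratioMedianFold,
    loop_count = report$loops$count,
    loop_mean_length = report$loops$meanLength,
    cen_loop_count = report$loops$cenOriginatedCount,
    cen_loop_mean_length = report$loops$cenOriginatedMeanLength,
    anchor_count = report$anchors$anchorCount,
    non_anchor_count = report$anchors$nonAnchorCount,
    apa_central_score = report$apa$centralScore,
    insulation_min_offset = report$insulation$cenProfileMinOffset,
    decay_slope = report$decay$slope5to100kb)
  for (nm in names(report$geneTests)) {
    m[[paste0("gene_", nm, "_p")]] <- report$geneTests[[nm]]$p
  }
  m
}

#' Compare two scenario reports
#'
#' Side-by-side deltas and fold-changes of every shared scalar metric;
#' metrics absent from one report are kept with `NA` (marked absent, not
#' an error).
#'
#' @param reportA,reportB `RunReport`s from the same annotation.
#' @return data.frame with `metric`, `a`, `b`, `delta`, `fold`.
#' @export
compareConditions <- function(reportA, reportB) {
  ma <- reportMetrics(reportA); mb <- reportMetrics(reportB)
  keys <- union(names(ma), names(mb))
  getv <- function(m, k) if (is.null(m[[k]])) NA_real_ else as.numeric(m[[k]])
  a <- vapply(keys, getv, 0, m = ma)
  b <- vapply(keys, getv, 0, m = mb)
  data.frame(metric = keys, a = a, b = b, delta = b - a, fold = b / a,
             row.names = NULL)
}
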
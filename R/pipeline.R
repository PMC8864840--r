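#' @include AllClasses.R io.R readProcessing.R libraryMetrics.R xcor.R
#'   enrichment.R profiling.R rankDashboard.R
NULL

#' Default pipeline parameters
#'
#' @return Named list of the tunable parameters of \code{\link{runQC}}
#'   with their defaults: MAPQ threshold, cross-correlation shift grid,
#'   stitch gap, promoter/metagene geometry, fragment extension switch.
#' @export
qcDefaults <- function() {
  list(mapqMin = 10L,
       shiftLo = 0L, shiftHi = 500L, shiftStep = 5L,
       minTagsPerChrom = 200L, phantomHalfWidth = 10L,
       stitchGap = 12500,
       promoterHalf = 1000L, windowHalf = 10000L,
       profileHalfWindow = 2000L, profileBin = 50L,
       bodyBins = 100L, flank = 2000L, flankBin = 50L,
       extendFragments = TRUE,
       fastqMaxRecords = 1e6,
       chromSizes = NULL)
}

stageMsg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full quality-control pipeline
#'
#' Executes the stages in fixed order — read inputs, filter tags
#' (duplicates then blacklist), library metrics, strand cross-correlation,
#' peak/enrichment metrics with stitched-region calling, promoter and
#' metagene profiling with peak annotation, then the rank dashboard — and
#' writes every result into \code{outDir}: the metric panel as TSV and
#' color-flagged HTML, the stitched regions as BED6+, the
#' cross-correlation curve, coverage matrices and annotation tables as
#' TSV, and the resolved parameter set as JSON for provenance. All
#' outputs are deterministic: rerunning on identical inputs reproduces
#' them byte for byte.
#'
#' @param reads Path to SAM/BAM or 6-column tag BED, or a
#'   \code{\link{TagSet}}.
#' @param peaks Path to a peak BED, or a \code{GRanges}.
#' @param outDir Output directory.
#' @param genes Optional GTF path or gene \code{GRanges} (enables
#'   profiling and annotation).
#' @param normalizedPeaks Optional input-corrected peak BED/\code{GRanges}
#'   (the N metric is missing without it).
#' @param controlReads Optional control alignment for region-signal
#'   correction.
#' @param blacklist Optional blacklist BED/\code{GRanges}.
#' @param fastq Optional FASTQ path for the base-quality and diversity
#'   flags.
#' @param params Named list overriding entries of \code{\link{qcDefaults}}.
#' @param prefix Output file prefix (default "chromaqc").
#' @return Invisibly, a list with the \code{\link{MetricPanel}}, the
#'   \code{\link{XcorProfile}}, the \code{\link{StitchedRegionSet}}, the
#'   filter report and the output paths.
#' @export
runQC <- function(reads, peaks, outDir, genes = NULL,
                  normalizedPeaks = NULL, controlReads = NULL,
                  blacklist = NULL, fastq = NULL, params = list(),
                  prefix = "chromaqc") {
  p <- utils::modifyList(qcDefaults(), params)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir)

  stageMsg("read", "loading alignments")
  ts <- if (is(reads, "TagSet")) reads
        else readAlignments(reads, mapqMin = p$mapqMin,
                            chromSizes = p$chromSizes)
  pk <- if (is(peaks, "GRanges")) peaks else readPeaks(peaks)
  npk <- if (is.null(normalizedPeaks)) NULL
         else if (is(normalizedPeaks, "GRanges")) normalizedPeaks
         else readPeaks(normalizedPeaks)
  bl <- if (is.null(blacklist)) NULL
        else if (is(blacklist, "GRanges")) blacklist
        else readPeaks(blacklist)
  gn <- if (is.null(genes)) NULL
        else if (is(genes, "GRanges")) genes else readGenes(genes)
  ctl <- if (is.null(controlReads)) NULL
         else if (is(controlReads, "TagSet")) controlReads
         else readAlignments(controlReads, mapqMin = p$mapqMin,
                             chromSizes = p$chromSizes)
  fq <- if (is.null(fastq)) NULL
        else readFastqStats(fastq, maxRecords = p$fastqMaxRecords)
  stageMsg("read", length(tags(ts)), " tags, ", length(pk), " peaks")

  stageMsg("library", "computing library metrics (pre-filter)")
  lm <- libraryMetrics(ts, fq)

  stageMsg("filter", "removing duplicates then blacklisted tags")
  flt <- filterTags(ts, bl)
  tsF <- flt$tags
  ctlF <- if (is.null(ctl)) NULL else filterTags(ctl, bl)$tags
  stageMsg("filter", flt$report@duplicatesRemoved, " duplicates, ",
           flt$report@blacklistedRemoved, " blacklisted removed; ",
           flt$report@outputTags, " tags kept")
  pkF <- filterPeaksBlacklist(pk, if (is.null(bl)) GRanges() else bl)
  npkF <- if (is.null(npk)) NULL
          else filterPeaksBlacklist(npk, if (is.null(bl)) GRanges()
                                    else bl)

  stageMsg("xcor", "strand cross-correlation")
  prof <- strandCrossCorrelation(tsF,
                                 shiftRange = c(p$shiftLo, p$shiftHi),
                                 step = p$shiftStep,
                                 minTagsPerChrom = p$minTagsPerChrom,
                                 phantomHalfWidth = p$phantomHalfWidth)
  stageMsg("xcor", "fragment width ", estimateFragmentWidth(prof), " bp")

  stageMsg("enrichment", "FRiP, stitching, super-region calling")
  frip <- computeFRiP(tsF, pkF)
  srs <- stitchPeaks(pkF, stitchGap = p$stitchGap)
  srs <- scoreRegions(srs, tsF, ctlF)
  srs <- classifyRegions(srs)
  nSuper <- sum(regions(srs)$isSuper, na.rm = TRUE)
  stageMsg("enrichment", length(srs), " stitched regions, ",
           nSuper, " super")

  annot <- promMat <- metaMat <- NULL
  if (!is.null(gn) && length(gn)) {
    stageMsg("profiling", "promoter/metagene matrices and annotation")
    fragLen <- if (isTRUE(p$extendFragments))
      as.integer(estimateFragmentWidth(prof)) else NULL
    if (!is.null(fragLen) && fragLen < 1L) fragLen <- NULL
    promMat <- promoterMatrix(tsF, gn, halfWindow = p$profileHalfWindow,
                              bin = p$profileBin, fragLen = fragLen)
    metaMat <- tryCatch(
      metageneMatrix(tsF, gn, bodyBins = p$bodyBins, flank = p$flank,
                     flankBin = p$flankBin, fragLen = fragLen),
      error = function(e) {
        stageMsg("profiling", "metagene skipped: ",
                 conditionMessage(e))
        NULL
      })
    annot <- annotatePeaks(pkF, gn, promoterHalf = p$promoterHalf,
                           windowHalf = p$windowHalf)
  }

  stageMsg("dashboard", "ranking metrics")
  panel <- buildMetricPanel(list(
    A = lm$alignedPercent, B = lm$baseQuality,
    FragWidth = estimateFragmentWidth(prof),
    E = tagLengthDelta(prof),
    F = frip, L = length(srs), NRF = lm$nrf,
    N = countPeaks(npkF), NSC = computeNSC(prof),
    D = lm$diversity, C = lm$pbc, P = countPeaks(pkF),
    R = lm$rawReads, ReadLength = lm$meanReadLength,
    RSC = computeRSC(prof), SE = nSuper, S = sRatio(srs)))

  paths <- renderReport(panel, outDir, prefix)
  bedPath <- file.path(outDir, paste0(prefix, "-stitched.bed"))
  writeStitchedBED(srs, bedPath)
  xcPath <- file.path(outDir, paste0(prefix, "-xcor.tsv"))
  xt <- xcorTable(prof)
  writeLines(c("shift\tcc",
               sprintf("%d\t%.6f", xt$shift, xt$cc)), xcPath)
  if (!is.null(promMat))
    writeCoverageTSV(promMat,
                     file.path(outDir, paste0(prefix, "-promoter.tsv")))
  if (!is.null(metaMat))
    writeCoverageTSV(metaMat,
                     file.path(outDir, paste0(prefix, "-metagene.tsv")))
  if (!is.null(annot)) {
    at <- annotationTable(annot)
    writeLines(c("category\tcount\tfraction",
                 sprintf("%s\t%d\t%.4f", at$category, at$count,
                         at$fraction)),
               file.path(outDir, paste0(prefix, "-annotation.tsv")))
    pp <- annot@perPeak
    writeLines(c("peak\tcategory\tnearest_gene\tdistance",
                 sprintf("%s\t%s\t%s\t%s", pp$peak, pp$category,
                         ifelse(is.na(pp$nearestGene), "NA",
                                pp$nearestGene),
                         ifelse(is.na(pp$distance), "NA",
                                format(pp$distance, trim = TRUE,
                                       scientific = FALSE)))),
               file.path(outDir, paste0(prefix, "-nearest-genes.tsv")))
  }
  ## provenance: the exact resolved parameter set
  jsonlite::write_json(p, file.path(outDir,
                                    paste0(prefix, "-params.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  stageMsg("dashboard", sprintf("overall quality Q = %.3f (%s)",
                                panel@overallQ, panel@overallRank))
  invisible(list(panel = panel, profile = prof, stitched = srs,
                 filterReport = flt$report, paths = paths,
                 annotation = annot))
}
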
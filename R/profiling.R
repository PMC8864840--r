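#' @include AllClasses.R utils.R
NULL

## Shared bin-counting engine. tiles: GRanges with mcols row/col giving the
## matrix cell each tile fills; cells without a tile stay NA. Tag
## contribution is either the 5' point (fragLen NULL) or the fragment
## interval extended fragLen bp in the strand direction. Densities are
## per-bp, scaled to tags-per-million by the filtered tag total.
binDensityMatrix <- function(ts, tiles, nRow, nCol, fragLen, chromLens) {
  gr <- tags(ts)
  nTot <- length(gr)
  vals <- matrix(NA_real_, nRow, nCol)
  if (!length(tiles)) return(vals)
  ## effective width: part of each tile actually on the chromosome
  N <- chromLens[as.character(seqnames(tiles))]
  ew <- pmin(end(tiles), N) - pmax(start(tiles), 1) + 1
  ew[is.na(ew)] <- 0
  ew <- pmax(ew, 0)
  if (is.null(fragLen)) {
    hits <- countOverlaps(tiles, gr, ignore.strand = TRUE)
  } else {
    minus <- as.character(strand(gr)) == "-"
    a <- ifelse(minus, start(gr) - fragLen + 1L, start(gr))
    frag <- GRanges(seqnames(gr), IRanges(pmax(a, 1L),
                                          width = fragLen))
    ov <- findOverlaps(tiles, frag, ignore.strand = TRUE)
    w <- width(IRanges::pintersect(
      IRanges::ranges(tiles)[S4Vectors::queryHits(ov)],
      IRanges::ranges(frag)[S4Vectors::subjectHits(ov)]))
    hits <- numeric(length(tiles))
    if (length(ov)) {
      agg <- rowsum(w, S4Vectors::queryHits(ov))
      hits[as.integer(rownames(agg))] <- agg[, 1L]
    }
  }
  dens <- ifelse(ew > 0, hits / ew, NA_real_)
  if (nTot > 0) dens <- dens * 1e6 / nTot
  vals[cbind(tiles$row, tiles$col)] <- dens
  vals
}

#' Promoter-centred coverage matrix
#'
#' Tag density in fixed-width bins across \code{[tss - halfWindow,
#' tss + halfWindow)} for every gene, orientation-flipped so that column 1
#' is always the upstream (5') side. Values are tags-per-million per bp;
#' bins truncated off the chromosome use their truncated width, and bins
#' entirely off it are NA.
#'
#' @param ts Filtered \code{\link{TagSet}}.
#' @param genes \code{GRanges} of gene bodies with \code{gene_id} and
#'   strand.
#' @param halfWindow Half-width of the promoter window in bp (default
#'   2000); must be a multiple of \code{bin}.
#' @param bin Bin width in bp (default 50).
#' @param fragLen Optional fragment length (bp): when given, each tag is
#'   extended to a fragment-length interval in its strand direction and
#'   contributes its bp overlap with each bin; when NULL only the 5'
#'   position counts.
#' @return A \code{\link{CoverageMatrix}} with one row per gene.
#' @export
promoterMatrix <- function(ts, genes, halfWindow = 2000L, bin = 50L,
                           fragLen = NULL) {
  stopifnot(length(genes) > 0, halfWindow %% bin == 0)
  nBins <- as.integer(2L * halfWindow / bin)
  tss <- tssPositions(genes)
  nG <- length(genes)
  ## tiles are laid out in transcription order (col 1 = most upstream)
  ## and mapped to genomic coordinates by strand, so minus-strand
  ## windows are the exact mirror of plus-strand ones
  g <- rep(seq_len(nG), each = nBins)
  k <- rep(seq_len(nBins), nG)
  minus <- as.character(strand(genes))[g] == "-"
  st <- ifelse(minus,
               tss[g] + halfWindow - k * bin + 1L,
               tss[g] - halfWindow + (k - 1L) * bin)
  tiles <- GRanges(rep(as.character(seqnames(genes)), each = nBins),
                   IRanges(st, width = bin))
  tiles$row <- g
  tiles$col <- k
  vals <- binDensityMatrix(ts, tiles, nG, nBins, fragLen,
                           chromSizes(ts))
  ids <- if (!is.null(genes$gene_id)) genes$gene_id
         else as.character(seq_len(nG))
  rownames(vals) <- ids
  off <- seq(-halfWindow, halfWindow - bin, by = bin)
  bins <- data.frame(label = sprintf("tss%+d", off),
                     type = "window", width = bin)
  new("CoverageMatrix", values = vals, bins = bins)
}

#' Metagene coverage matrix
#'
#' Gene bodies are rescaled into \code{bodyBins} equal-fraction bins,
#' flanked by fixed-width bins of \code{flankBin} bp covering
#' \code{flank} bp on each side, in transcription orientation (column 1 is
#' the 5' flank). Densities are per-bp (tags-per-million per bp), so the
#' body rescaling is length-fair: a gene twice as long contributes the
#' same per-bp density under uniform coverage. Genes shorter than
#' \code{bodyBins} bp are skipped; the number skipped is recorded in a
#' warning and excluded from the matrix.
#'
#' @inheritParams promoterMatrix
#' @param bodyBins Number of equal-fraction bins across the gene body
#'   (default 100).
#' @param flank Flank width in bp (default 2000); must be a multiple of
#'   \code{flankBin}.
#' @param flankBin Flank bin width in bp (default 50).
#' @return A \code{\link{CoverageMatrix}}.
#' @export
metageneMatrix <- function(ts, genes, bodyBins = 100L, flank = 2000L,
                           flankBin = 50L, fragLen = NULL) {
  stopifnot(length(genes) > 0, flank %% flankBin == 0)
  tooShort <- width(genes) < bodyBins
  if (any(tooShort)) {
    warning(sum(tooShort), " gene(s) shorter than bodyBins skipped")
    genes <- genes[!tooShort]
  }
  if (!length(genes)) stop("no genes long enough for the metagene matrix")
  nF <- as.integer(flank / flankBin)
  nBins <- 2L * nF + as.integer(bodyBins)
  nG <- length(genes)
  rowL <- intL <- colL <- vector("list", nG)
  chs <- as.character(seqnames(genes))
  for (i in seq_len(nG)) {
    s1 <- start(genes)[i]; e1 <- end(genes)[i]
    L <- e1 - s1 + 1L
    ## bin edges as 0-based offsets in transcription order: 5' flank,
    ## body in floor-based equal fractions (monotone because
    ## L >= bodyBins), 3' flank; mapped to genomic coordinates by
    ## strand so minus-strand genes mirror plus-strand ones exactly
    bodyEdges <- as.integer(floor((0:bodyBins) * (L / bodyBins)))
    o1 <- c(-flank + (seq_len(nF) - 1L) * flankBin,
            bodyEdges[-(bodyBins + 1L)],
            L + (seq_len(nF) - 1L) * flankBin)
    o2 <- c(-flank + seq_len(nF) * flankBin - 1L,
            bodyEdges[-1L] - 1L,
            L + seq_len(nF) * flankBin - 1L)
    if (as.character(strand(genes))[i] == "-") {
      starts <- e1 - o2
      ends <- e1 - o1
    } else {
      starts <- s1 + o1
      ends <- s1 + o2
    }
    rowL[[i]] <- IRanges(starts, ends)
    intL[[i]] <- rep(i, nBins)
    colL[[i]] <- seq_len(nBins)
  }
  tiles <- GRanges(rep(chs, each = nBins),
                   do.call(c, rowL))
  tiles$row <- unlist(intL)
  tiles$col <- unlist(colL)
  vals <- binDensityMatrix(ts, tiles, nG, nBins, fragLen,
                           chromSizes(ts))
  ids <- if (!is.null(genes$gene_id)) genes$gene_id
         else as.character(seq_len(nG))
  rownames(vals) <- ids
  bins <- data.frame(
    label = c(sprintf("flank5_%d", seq_len(nF)),
              sprintf("body_%d", seq_len(bodyBins)),
              sprintf("flank3_%d", seq_len(nF))),
    type = c(rep("flank5", nF), rep("body", bodyBins),
             rep("flank3", nF)),
    width = c(rep(flankBin, nF), rep(NA_real_, bodyBins),
              rep(flankBin, nF)))
  new("CoverageMatrix", values = vals, bins = bins)
}

#' Column-wise average profile of a coverage matrix
#'
#' @param cm A \code{\link{CoverageMatrix}}.
#' @return Numeric vector of per-bin mean densities (NA bins, e.g. those
#'   truncated off a chromosome, are excluded from their column's mean).
#' @export
averageProfile <- function(cm) {
  v <- cm@values
  if (!nrow(v)) stop("empty coverage matrix")
  colMeans(v, na.rm = TRUE)
}

#' Write a coverage matrix as TSV
#'
#' @param cm A \code{\link{CoverageMatrix}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCoverageTSV <- function(cm, path) {
  df <- data.frame(gene = rownames(cm@values), cm@values,
                   check.names = FALSE)
  colnames(df) <- c("gene", cm@bins$label)
  utils::write.table(format(df, digits = 6), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genic annotation of peaks
#'
#' Assigns every peak exactly one category by precedence: promoter
#' (overlap with \code{[tss - promoterHalf, tss + promoterHalf)}), then
#' gene body, then gene-centric window (the gene body extended
#' \code{windowHalf} bp on both sides), else intergenic; overlap means at
#' least 1 bp. Each peak is also paired with its nearest gene: the gene
#' whose TSS is closest to the peak midpoint, with the signed distance
#' (midpoint minus TSS) set to 0 when the peak covers that TSS.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param genes \code{GRanges} of gene bodies with \code{gene_id} and
#'   strand.
#' @param promoterHalf Promoter half-width in bp (default 1000).
#' @param windowHalf Gene-centric window extension in bp (default 10000).
#' @return An \code{\link{AnnotationDistribution}}.
#' @export
annotatePeaks <- function(peaks, genes, promoterHalf = 1000L,
                          windowHalf = 10000L) {
  stopifnot(length(genes) > 0)
  tss <- tssPositions(genes)
  chs <- as.character(seqnames(genes))
  promoters <- GRanges(chs, IRanges(tss - promoterHalf,
                                    tss + promoterHalf - 1L))
  windows <- GRanges(chs, IRanges(start(genes) - windowHalf,
                                  end(genes) + windowHalf))
  isProm <- overlapsAny(peaks, promoters, ignore.strand = TRUE)
  isBody <- overlapsAny(peaks, genes, ignore.strand = TRUE)
  isWin <- overlapsAny(peaks, windows, ignore.strand = TRUE)
  category <- ifelse(isProm, "promoter",
              ifelse(isBody, "gene_body",
              ifelse(isWin, "gene_centric_window", "intergenic")))
  ## nearest gene by |peak midpoint - TSS| on the same chromosome
  mid0 <- (start(peaks) - 1L + end(peaks)) %/% 2L
  tss0 <- tss - 1L
  pch <- as.character(seqnames(peaks))
  nearestGene <- rep(NA_character_, length(peaks))
  distance <- rep(NA_real_, length(peaks))
  for (i in seq_along(peaks)) {
    onCh <- which(chs == pch[i])
    if (!length(onCh)) next
    d <- mid0[i] - tss0[onCh]
    j <- onCh[which.min(abs(d))]
    nearestGene[i] <- genes$gene_id[j]
    covered <- tss[j] >= start(peaks)[i] && tss[j] <= end(peaks)[i]
    distance[i] <- if (covered) 0 else mid0[i] - tss0[j]
  }
  cats <- c("promoter", "gene_body", "gene_centric_window", "intergenic")
  counts <- stats::setNames(
    vapply(cats, function(cc) sum(category == cc), 0L), cats)
  new("AnnotationDistribution", counts = counts,
      perPeak = DataFrame(peak = sprintf("%s:%d-%d", pch,
                                         start(peaks) - 1L, end(peaks)),
                          category = category,
                          nearestGene = nearestGene,
                          distance = distance))
}

#' Annotation distribution summary table
#'
#' @param ad An \code{\link{AnnotationDistribution}}.
#' @return data.frame with columns category, count, fraction.
#' @export
annotationTable <- function(ad) {
  tot <- sum(ad@counts)
  data.frame(category = names(ad@counts),
             count = as.integer(ad@counts),
             fraction = if (tot > 0) as.numeric(ad@counts) / tot
                        else rep(NA_real_, length(ad@counts)))
}
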
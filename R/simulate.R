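#' @include AllClasses.R utils.R io.R
NULL

#' Simulate single-end tags with exact ground truth
#'
#' Places \code{nFragments} fragments of length \code{fragmentLength} on a
#' toy genome: with probability \code{fripTarget} a fragment lands inside
#' a (width-weighted) peak, otherwise uniformly on the genome. Each
#' fragment is sequenced from both ends, emitting a plus-strand tag at its
#' first base and a minus-strand tag at its last base — the construction
#' that gives the strand cross-correlation a genuine fragment-length peak.
#' Each tag is then duplicated (one extra copy) with probability
#' \code{duplicateRate}. All ground-truth tallies (distinct keys,
#' singleton keys, in-peak tags after deduplication) are exact counts over
#' the emitted tags, so measured NRF/PBC/FRiP must match them exactly.
#'
#' @param chromSizes Named numeric vector of chromosome lengths; default
#'   two chromosomes of 1 Mb, which keeps a full QC run fast.
#' @param peaks \code{GRanges} of target regions (required when
#'   \code{fripTarget > 0}).
#' @param fripTarget Probability a fragment is placed in a peak.
#' @param fragmentLength Mean fragment length in bp (default 150).
#' @param fragmentSd Standard deviation of the fragment-length
#'   distribution in bp (default 15, a tight size selection; lengths are
#'   rounded and floored at \code{readLength}). Dispersion is what gives
#'   the cross-correlation a smooth fragment-length peak, as in real
#'   sonicated or nuclease-released libraries.
#' @param nFragments Number of fragments (default 10000).
#' @param duplicateRate Per-tag duplication probability.
#' @param readLength Sequenced read length in bp (default 50).
#' @param alignedFraction Fraction of raw reads that align; raw read count
#'   is scaled up accordingly (default 1).
#' @param seed Integer seed; the generator never touches global RNG state.
#' @return List with \code{tags} (a \code{\link{TagSet}}) and
#'   \code{truth} (list of exact tallies: \code{nTags},
#'   \code{distinctKeys}, \code{singletonKeys}, \code{inPeakDedupTags},
#'   \code{nrf}, \code{pbc}, \code{frip}, plus the generator parameters).
#' @examples
#' sim <- simulateTags(nFragments = 500, seed = 1)
#' computeNRF(sim$tags) == sim$truth$nrf
#' @export
simulateTags <- function(chromSizes = c(chr1 = 1e6, chr2 = 1e6),
                         peaks = NULL, fripTarget = 0,
                         fragmentLength = 150L, fragmentSd = 15,
                         nFragments = 10000L,
                         duplicateRate = 0, readLength = 50L,
                         alignedFraction = 1, seed = NULL) {
  stopifnot(fripTarget >= 0, fripTarget <= 1,
            duplicateRate >= 0, duplicateRate <= 1,
            fragmentLength >= readLength, fragmentSd >= 0)
  if (fripTarget > 0 && (is.null(peaks) || !length(peaks)))
    stop("fripTarget > 0 requires a non-empty peak set")
  withSeed(seed, {
    nC <- length(chromSizes)
    fragLens <- pmax(as.integer(round(stats::rnorm(nFragments,
                                                   fragmentLength,
                                                   fragmentSd))),
                     as.integer(readLength))
    inPeak <- stats::runif(nFragments) < fripTarget
    chrom <- character(nFragments)
    fs <- integer(nFragments)   # 0-based fragment start
    nIn <- sum(inPeak)
    if (nIn) {
      pk <- sample.int(length(peaks), nIn, replace = TRUE,
                       prob = width(peaks))
      fl <- fragLens[inPeak]
      lo <- start(peaks)[pk] - 1L                 # 0-based peak start
      hi <- pmax(lo, end(peaks)[pk] - fl)
      pos <- lo + floor(stats::runif(nIn) * (hi - lo + 1L))
      cs <- chromSizes[as.character(seqnames(peaks))[pk]]
      pos <- pmin(pos, cs - fl)
      chrom[inPeak] <- as.character(seqnames(peaks))[pk]
      fs[inPeak] <- as.integer(pos)
    }
    nOut <- nFragments - nIn
    if (nOut) {
      ci <- sample.int(nC, nOut, replace = TRUE, prob = chromSizes)
      lim <- chromSizes[ci] - fragLens[!inPeak]
      chrom[!inPeak] <- names(chromSizes)[ci]
      fs[!inPeak] <- as.integer(floor(stats::runif(nOut) * (lim + 1)))
    }
    ## both-end tag emission: + at fragment start, - at fragment end
    tagChrom <- c(chrom, chrom)
    tagPos0 <- c(fs, fs + fragLens - 1L)
    tagStrand <- rep(c("+", "-"), each = nFragments)
    dup <- stats::runif(length(tagPos0)) < duplicateRate
    tagChrom <- c(tagChrom, tagChrom[dup])
    tagPos0 <- c(tagPos0, tagPos0[dup])
    tagStrand <- c(tagStrand, tagStrand[dup])
    gr <- GRanges(tagChrom, IRanges(tagPos0 + 1L, width = 1L),
                  strand = tagStrand)
    gr$readLength <- as.integer(readLength)
    nTags <- length(gr)
    raw <- as.numeric(round(nTags / alignedFraction))
    ts <- TagSet(gr, totalRaw = raw, totalMapped = nTags,
                 chromSizes = chromSizes)
    ## exact truth tallies over the emitted tags
    keys <- tagKeys(gr)
    keyCounts <- table(keys)
    distinct <- length(keyCounts)
    singleton <- sum(keyCounts == 1L)
    dedup <- gr[!duplicated(keys)]
    inPk <- if (!is.null(peaks) && length(peaks))
      sum(overlapsAny(dedup, reduce(peaks, ignore.strand = TRUE),
                      ignore.strand = TRUE))
    else 0L
    truth <- list(seed = seed, nFragments = nFragments,
                  fragmentLength = fragmentLength,
                  fragmentSd = fragmentSd,
                  duplicateRate = duplicateRate,
                  fripTarget = fripTarget, readLength = readLength,
                  nTags = nTags, distinctKeys = distinct,
                  singletonKeys = singleton,
                  inPeakDedupTags = as.integer(inPk),
                  nrf = distinct / nTags,
                  pbc = singleton / distinct,
                  frip = as.integer(inPk) / distinct)
    list(tags = ts, truth = truth)
  })
}

#' Simulate strand-independent tags (null model)
#'
#' Places plus-strand and minus-strand tags independently and uniformly on
#' the genome: there is no fragment pairing, so the strand
#' cross-correlation has no fragment-length peak. Used as the null for
#' enrichment statistics.
#'
#' @inheritParams simulateTags
#' @param nTagsPerStrand Number of tags per strand.
#' @return A \code{\link{TagSet}}.
#' @export
simulateNullTags <- function(chromSizes = c(chr1 = 1e6, chr2 = 1e6),
                             nTagsPerStrand = 50000L, readLength = 50L,
                             seed = NULL) {
  withSeed(seed, {
    n <- 2L * nTagsPerStrand
    ci <- sample.int(length(chromSizes), n, replace = TRUE,
                     prob = chromSizes)
    pos0 <- floor(stats::runif(n) * (chromSizes[ci] - readLength + 1))
    gr <- GRanges(names(chromSizes)[ci],
                  IRanges(as.integer(pos0) + 1L, width = 1L),
                  strand = rep(c("+", "-"), each = nTagsPerStrand))
    gr$readLength <- as.integer(readLength)
    TagSet(gr, chromSizes = chromSizes)
  })
}

#' Simulate a non-overlapping gene annotation
#'
#' Divides the genome into \code{nGenes} equal slots and places one gene
#' uniformly inside each slot, with random strand, guaranteeing disjoint
#' gene bodies.
#'
#' @param nGenes Number of genes.
#' @param chromSizes Named numeric vector of chromosome lengths.
#' @param geneLength Two-element range of gene lengths in bp.
#' @param seed Integer seed.
#' @return \code{GRanges} of gene bodies with \code{gene_id}.
#' @export
simulateAnnotation <- function(nGenes, chromSizes = c(chr1 = 1e6,
                               chr2 = 1e6), geneLength = c(5000, 20000),
                               seed = NULL) {
  ## genes are apportioned to chromosomes by length, then each
  ## chromosome is divided into equal slots holding one gene apiece, so
  ## bodies are disjoint by construction and never straddle chromosomes
  total <- sum(chromSizes)
  perChrom <- diff(round(cumsum(c(0, chromSizes)) / total * nGenes))
  names(perChrom) <- names(chromSizes)
  maxLen <- max(geneLength)
  ok <- perChrom == 0 | chromSizes / pmax(perChrom, 1) >= maxLen + 2
  if (sum(perChrom) != nGenes || !all(ok))
    stop("genome too small for ", nGenes, " genes of length up to ",
         maxLen)
  withSeed(seed, {
    chrom <- character(0)
    start1 <- integer(0)
    len <- integer(0)
    for (ch in names(chromSizes)) {
      ni <- perChrom[[ch]]
      if (ni == 0) next
      slot <- floor(chromSizes[[ch]] / ni)
      li <- as.integer(round(stats::runif(ni, geneLength[1L],
                                          geneLength[2L])))
      off <- as.integer(floor(stats::runif(ni) * (slot - li)))
      chrom <- c(chrom, rep(ch, ni))
      start1 <- c(start1, (seq_len(ni) - 1L) * slot + off + 1L)
      len <- c(len, li)
    }
    genes <- GRanges(chrom, IRanges(start1, width = len),
                     strand = sample(c("+", "-"), length(chrom),
                                     replace = TRUE))
    genes$gene_id <- sprintf("gene%03d", seq_along(genes))
    genes
  })
}

#' Write gene models as GTF
#'
#' One \code{gene} feature line per gene, 1-based inclusive coordinates.
#'
#' @param genes \code{GRanges} with \code{gene_id}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGTF <- function(genes, path) {
  lines <- sprintf(
    "%s\tchromaQC\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    as.character(seqnames(genes)), start(genes), end(genes),
    as.character(strand(genes)), genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate region signals with designed outliers
#'
#' Draws \code{nRegions - nOutliers} background signals uniformly in
#' [0.8, 1.2] and adds \code{nOutliers} outliers at
#' \code{outlierFactor} to 1.5x \code{outlierFactor} times the
#' background mean, graded so that multiple outliers form the rising
#' continuum seen in real ranked super-enhancer curves rather than an
#' exact tie. With \code{outlierFactor = 1} there are no outliers and
#' the curve is near-degenerate.
#'
#' @param nRegions Total number of regions.
#' @param outlierFactor Multiple of the background level for outliers.
#' @param nOutliers Number of outliers (default 1).
#' @param seed Integer seed.
#' @return List with \code{signals} (length \code{nRegions}) and
#'   \code{outlierIdx} (indices of the designed outliers).
#' @export
simulateRegionSignals <- function(nRegions, outlierFactor = 50,
                                  nOutliers = 1L, seed = NULL) {
  stopifnot(nRegions > nOutliers)
  withSeed(seed, {
    base <- stats::runif(nRegions - nOutliers, 0.8, 1.2)
    out <- if (outlierFactor > 1)
      outlierFactor * mean(base) * seq(1, 1.5,
                                       length.out = nOutliers)
    else stats::runif(nOutliers, 0.8, 1.2)
    signals <- c(base, out)
    list(signals = signals,
         outlierIdx = if (outlierFactor > 1)
           seq.int(nRegions - nOutliers + 1L, nRegions)
         else integer())
  })
}

#' Write a TagSet as tag BED
#'
#' Six columns (chrom, start, end, name, score, strand) in 0-based
#' half-open coordinates, one record per tag spanning the read footprint
#' implied by the tag's 5' position, strand and read length.
#'
#' @param ts A \code{\link{TagSet}}.
#' @param path Output path (gzip if it ends in .gz).
#' @return Invisibly, \code{path}.
#' @export
writeTagBED <- function(ts, path) {
  gr <- tags(ts)
  rl <- gr$readLength
  minus <- as.character(strand(gr)) == "-"
  p0 <- tagPos5(gr)
  s0 <- ifelse(minus, pmax(p0 - rl + 1L, 0L), p0)
  e0 <- ifelse(minus, p0 + 1L, p0 + rl)
  lines <- sprintf("%s\t%d\t%d\ttag%d\t0\t%s",
                   as.character(seqnames(gr)), s0, e0, seq_along(gr),
                   as.character(strand(gr)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt")
         else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Simulate a FASTQ file with constant base quality
#'
#' Random-sequence reads at a fixed Phred quality, optionally spiking in
#' one overrepresented sequence at a given fraction (for exercising the
#' sequence-diversity flag).
#'
#' @param nReads Number of reads.
#' @param readLength Read length in bp.
#' @param path Output path (gzip if it ends in .gz).
#' @param qualityChar Phred+33 quality character for every base
#'   (default "I", Q40).
#' @param overrepFraction Fraction of reads that are copies of one fixed
#'   sequence (default 0).
#' @param seed Integer seed.
#' @return Invisibly, \code{path}.
#' @export
simulateFastq <- function(nReads, readLength = 50L, path,
                          qualityChar = "I", overrepFraction = 0,
                          seed = NULL) {
  withSeed(seed, {
    nOver <- round(nReads * overrepFraction)
    mk <- function(n) vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), readLength,
                   replace = TRUE), collapse = ""), "")
    seqs <- mk(nReads - nOver)
    if (nOver) seqs <- c(seqs, rep(mk(1L), nOver))
    qual <- strrep(qualityChar, readLength)
    recs <- sprintf("@read%d\n%s\n+\n%s", seq_along(seqs), seqs, qual)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt")
           else file(path, "wt")
    on.exit(close(con))
    writeLines(recs, con)
  })
  invisible(path)
}
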
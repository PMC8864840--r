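#' @include AllClasses.R utils.R
NULL

#' Read a BED file of peaks or blacklist regions
#'
#' Reads BED3/BED6 records into a \code{GRanges}. BED coordinates are
#' 0-based half-open; they are converted to the 1-based closed convention
#' of \code{GRanges} on read (start + 1), so a BED record
#' \code{chr1 100 200} becomes \code{chr1:101-200}. Column 4 is stored as
#' \code{name}, column 5 as \code{score} (NA when absent or "."), column 6
#' as strand. Record order is preserved.
#'
#' @param path Path to a BED file (plain text or gzip).
#' @param requireStrand Require a valid strand in column 6 (used for the
#'   tag-BED dialect); default FALSE.
#' @return \code{GRanges} with \code{name} and \code{score} metadata
#'   columns.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tp1\t50", bed)
#' readPeaks(bed)
#' @export
readPeaks <- function(path, requireStrand = FALSE) {
  if (!file.exists(path))
    stop("BED file not found: ", path)
  con <- openText(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines))
    return(GRanges(name = character(), score = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed BED record at line ", bad[1L],
         ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("malformed BED record at line ", bad[1L],
         ": non-integer coordinates")
  bad <- which(s < 0L | s >= e)
  if (length(bad))
    stop("malformed BED record at line ", bad[1L],
         ": requires 0 <= start < end")
  name <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  score <- rep(NA_real_, length(fields))
  has5 <- nf >= 5L
  if (any(has5)) {
    raw5 <- vapply(fields[has5], `[[`, "", 5L)
    score[has5] <- suppressWarnings(as.numeric(ifelse(raw5 == ".",
                                                      NA, raw5)))
  }
  std <- rep("*", length(fields))
  has6 <- nf >= 6L
  if (any(has6)) {
    raw6 <- vapply(fields[has6], `[[`, "", 6L)
    std[has6] <- ifelse(raw6 %in% c("+", "-"), raw6, "*")
  }
  if (requireStrand) {
    bad <- which(std == "*")
    if (length(bad))
      stop("tag BED requires +/- strand in column 6; missing at line ",
           bad[1L])
  }
  GRanges(chrom, IRanges(s + 1L, e), strand = std,
          name = name, score = score)
}

#' Write intervals to a BED file
#'
#' Inverse of \code{readPeaks}: converts the 1-based \code{GRanges} back to
#' 0-based half-open BED coordinates (start - 1). Extra metadata columns
#' named in \code{extraCols} are appended after the six standard columns.
#'
#' @param gr \code{GRanges} to write.
#' @param path Output path.
#' @param extraCols Character vector of metadata column names to append.
#' @return Invisibly, \code{path}.
#' @export
writeBED <- function(gr, path, extraCols = character()) {
  n <- length(gr)
  name <- if (!is.null(gr$name)) ifelse(is.na(gr$name), ".", gr$name)
          else rep(".", n)
  score <- if (!is.null(gr$score)) ifelse(is.na(gr$score), "0",
                                          format(gr$score, trim = TRUE,
                                                 scientific = FALSE))
           else rep("0", n)
  std <- as.character(strand(gr))
  std[std == "*"] <- "."
  cols <- list(as.character(seqnames(gr)),
               format(start(gr) - 1L, trim = TRUE, scientific = FALSE),
               format(end(gr), trim = TRUE, scientific = FALSE),
               name, score, std)
  for (ec in extraCols) {
    v <- mcols(gr)[[ec]]
    cols[[length(cols) + 1L]] <- if (is.numeric(v))
      format(v, trim = TRUE, scientific = FALSE, digits = 6)
    else as.character(v)
  }
  writeLines(if (n) do.call(paste, c(cols, sep = "\t")) else character(),
             path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Builds one gene model per distinct \code{gene_id} from the file's
#' \code{gene} features; when a gene has no \code{gene} feature its body is
#' the union span of its transcript/exon features. GTF coordinates
#' (1-based inclusive) map directly onto \code{GRanges}. Features with
#' unknown strand (".") are skipped; their number is returned in the
#' \code{skipped} metadata attribute. The TSS of a gene is its start for
#' plus-strand genes and its end for minus-strand genes
#' (see \code{\link{geneTSS}}).
#'
#' @param path Path to a GTF/GFF-style annotation.
#' @return \code{GRanges} of gene bodies with a \code{gene_id} metadata
#'   column, sorted in file order of first appearance.
#' @export
readGenes <- function(path) {
  if (!file.exists(path))
    stop("GTF file not found: ", path)
  gtf <- tryCatch(rtracklayer::import(path),
                  error = function(e) stop("cannot parse GTF ", path, ": ",
                                           conditionMessage(e)))
  if (!length(gtf))
    stop("no usable features in ", path)
  if (is.null(gtf$gene_id))
    stop("no gene_id attributes found in ", path)
  nstrandless <- sum(as.character(strand(gtf)) == "*")
  gtf <- gtf[as.character(strand(gtf)) != "*"]
  if (!length(gtf))
    stop("no stranded features in ", path)
  if (nstrandless)
    warning(nstrandless, " feature(s) with unknown strand skipped")
  type <- as.character(gtf$type)
  geneFeat <- gtf[type == "gene"]
  haveGene <- unique(geneFeat$gene_id)
  rest <- gtf[type != "gene" & !(gtf$gene_id %in% haveGene)]
  pieces <- geneFeat
  mcols(pieces) <- mcols(pieces)["gene_id"]
  if (length(rest)) {
    ## union span per gene_id over its transcript/exon features
    ids <- unique(rest$gene_id)
    first <- match(ids, rest$gene_id)
    spans <- GRanges(
      as.character(seqnames(rest))[first],
      IRanges(as.integer(tapply(start(rest), rest$gene_id, min)[ids]),
              as.integer(tapply(end(rest), rest$gene_id, max)[ids])),
      strand = as.character(strand(rest))[first])
    spans$gene_id <- ids
    pieces <- c(pieces, spans)
  }
  if (!length(pieces))
    stop("no usable features in ", path)
  ## keep first-appearance order of gene ids
  ord <- match(unique(pieces$gene_id), pieces$gene_id)
  genes <- pieces[ord]
  metadata(genes)$skipped <- nstrandless
  genes
}

#' Strand-aware transcription start sites
#'
#' @param genes \code{GRanges} of gene bodies with strand.
#' @return Integer vector of 1-based TSS positions (start of plus-strand
#'   genes, end of minus-strand genes).
#' @export
geneTSS <- function(genes) tssPositions(genes)

#' Read aligned reads into a TagSet
#'
#' Accepts a SAM/BAM alignment or a 6-column tag BED. Each retained record
#' contributes one tag at its 5' end: the leftmost aligned base for
#' plus-strand reads, the rightmost aligned base for minus-strand reads.
#' Unmapped, secondary and supplementary records are excluded from tags but
#' unmapped primaries still count toward \code{totalRaw}; records below the
#' MAPQ threshold are dropped. \code{totalMapped} is the number of retained
#' tags. Chromosome sizes come from the alignment header; if absent they
#' are inferred from the maximum coordinate (with a warning).
#'
#' @param path SAM, BAM or tag-BED file.
#' @param mapqMin Minimum mapping quality retained (SAM/BAM only);
#'   default 10.
#' @param format "auto" (by extension), "bam", "sam" or "bed".
#' @param chromSizes Optional named vector of chromosome lengths, required
#'   for BED input when sizes cannot be inferred reliably.
#' @return A \code{\link{TagSet}}.
#' @export
readAlignments <- function(path, mapqMin = 10L, format = c("auto", "bam",
                           "sam", "bed"), chromSizes = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, bam = "bam", sam = "sam", bed = "bed",
                     stop("cannot infer alignment format from ", path))
  }
  if (format == "bed")
    readTagBED(path, chromSizes)
  else
    readSamBam(path, isSam = format == "sam", mapqMin = mapqMin,
               chromSizes = chromSizes)
}

readTagBED <- function(path, chromSizes = NULL) {
  gr <- readPeaks(path, requireStrand = TRUE)
  if (is.null(chromSizes)) {
    if (length(gr)) {
      chromSizes <- tapply(end(gr), as.character(seqnames(gr)), max)
      chromSizes <- stats::setNames(as.numeric(chromSizes),
                                    names(chromSizes))
      warning("chromosome sizes inferred from maximum tag coordinate")
    } else chromSizes <- numeric()
  }
  minus <- as.character(strand(gr)) == "-"
  pos <- ifelse(minus, end(gr), start(gr))
  tagGR <- GRanges(seqnames(gr), IRanges(pos, width = 1L),
                   strand = strand(gr))
  tagGR$readLength <- width(gr)
  TagSet(tagGR, totalRaw = length(gr), totalMapped = length(gr),
         chromSizes = chromSizes)
}

readSamBam <- function(path, isSam, mapqMin, chromSizes = NULL) {
  bam <- path
  if (isSam)
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  ## count primary records (mapped or not) for totalRaw
  p0 <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = "flag")
  flags <- Rsamtools::scanBam(bam, param = p0)[[1L]]$flag
  nRaw <- length(flags)
  p1 <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    mapqFilter = mapqMin)
  gal <- GenomicAlignments::readGAlignments(bam, param = p1)
  minus <- as.character(strand(gal)) == "-"
  pos <- ifelse(minus, end(gal), start(gal))
  tagGR <- GRanges(seqnames(gal), IRanges(pos, width = 1L),
                   strand = strand(gal))
  tagGR$readLength <- GenomicAlignments::qwidth(gal)
  if (is.null(chromSizes)) {
    sl <- seqlengths(gal)
    if (all(is.na(sl))) {
      chromSizes <- tapply(end(gal), as.character(seqnames(gal)), max)
      chromSizes <- stats::setNames(as.numeric(chromSizes),
                                    names(chromSizes))
      warning("no sequence lengths in header; ",
              "chromosome sizes inferred from maximum coordinate")
    } else chromSizes <- stats::setNames(as.numeric(sl), names(sl))
  }
  used <- unique(as.character(seqnames(tagGR)))
  chromSizes <- chromSizes[names(chromSizes) %in%
                           union(used, names(chromSizes))]
  TagSet(tagGR, totalRaw = nRaw, totalMapped = length(tagGR),
         chromSizes = chromSizes)
}

#' Read-level FASTQ summary statistics
#'
#' Summarises up to \code{maxRecords} reads of a FASTQ file (Phred+33):
#' per-cycle mean, median and lower-quartile base quality, the
#' exact-sequence frequency table, and the mean read length. These feed the
#' base-quality and sequence-diversity flags.
#'
#' @param path FASTQ file (plain or gzip).
#' @param maxRecords Read at most this many records (default 1e6).
#' @return A list of class \code{fastqStats}: \code{perCycle} (data.frame
#'   with cycle, mean, median, q25), \code{seqFreq} (named fraction vector,
#'   decreasing), \code{meanReadLength}, \code{nRecords}.
#' @export
readFastqStats <- function(path, maxRecords = 1e6) {
  if (!file.exists(path))
    stop("FASTQ file not found: ", path)
  parse <- function() {
    reads <- Biostrings::readDNAStringSet(path, format = "fastq",
                                          with.qualities = TRUE,
                                          nrec = as.integer(maxRecords))
    quals <- as(Biostrings::PhredQuality(mcols(reads)$qualities),
                "IntegerList")
    if (!all(lengths(quals) == width(reads)))
      stop("sequence/quality length mismatch")
    list(reads = reads, quals = quals)
  }
  parsed <- tryCatch(parse(), error = function(e) {
    con <- openText(path)
    on.exit(close(con))
    nl <- length(readLines(con))
    if (nl %% 4L != 0L)
      stop("truncated FASTQ record at record ", nl %/% 4L + 1L)
    stop("cannot parse FASTQ ", path, ": ", conditionMessage(e))
  })
  reads <- parsed$reads
  quals <- parsed$quals
  n <- length(reads)
  if (!n)
    stop("no records in FASTQ ", path)
  lens <- width(reads)
  cyc <- sequence(lens)
  qv <- unlist(quals, use.names = FALSE)
  byCycle <- split(qv, cyc)
  perCycle <- data.frame(
    cycle = as.integer(names(byCycle)),
    mean = vapply(byCycle, mean, 0),
    median = vapply(byCycle, stats::median, 0),
    q25 = vapply(byCycle, function(v)
      unname(stats::quantile(v, 0.25, type = 7)), 0),
    row.names = NULL)
  freq <- sort(table(as.character(reads)), decreasing = TRUE) / n
  structure(list(perCycle = perCycle,
                 seqFreq = stats::setNames(as.numeric(freq), names(freq)),
                 meanReadLength = mean(lens),
                 nRecords = n),
            class = "fastqStats")
}
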
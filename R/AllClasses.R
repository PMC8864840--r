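#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand reduce
#'   countOverlaps findOverlaps
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels keepSeqlevels
NULL

#' TagSet: single-end read tags plus library-level counts
#'
#' A \code{TagSet} holds the 5'-end positions of aligned single-end reads
#' ("tags"), one width-1 \code{GRanges} entry per tag, together with the
#' library-level counts every read-based quality metric needs: the number of
#' raw sequencing reads and the number of mapped reads retained as tags.
#' The tag for a plus-strand read sits at its leftmost aligned base; the tag
#' for a minus-strand read sits at its rightmost aligned base. Per-tag read
#' lengths are kept in the \code{readLength} metadata column.
#'
#' @slot tags \code{GRanges} of width-1 tag positions with strand and a
#'   \code{readLength} metadata column (bp).
#' @slot totalRaw Number of input sequencing reads (mapped or not).
#' @slot totalMapped Number of mapped reads retained as tags at read time.
#' @slot chromSizes Named numeric vector of chromosome lengths (bp).
#'
#' @export
setClass("TagSet",
  representation(
    tags = "GRanges",
    totalRaw = "numeric",
    totalMapped = "numeric",
    chromSizes = "numeric"
  )
)

setValidity("TagSet", function(object) {
  msg <- NULL
  if (length(object@totalRaw) != 1L || length(object@totalMapped) != 1L)
    msg <- c(msg, "totalRaw and totalMapped must be single counts")
  if (object@totalMapped > object@totalRaw)
    msg <- c(msg, "totalMapped cannot exceed totalRaw")
  if (object@totalRaw < 0 || object@totalMapped < 0)
    msg <- c(msg, "read counts must be non-negative")
  if (length(object@tags)) {
    if (is.null(object@tags$readLength))
      msg <- c(msg, "tags must carry a readLength metadata column")
    cs <- object@chromSizes
    sq <- as.character(seqnames(object@tags))
    known <- sq %in% names(cs)
    if (!all(known))
      msg <- c(msg, "all tags must lie on chromosomes present in chromSizes")
    else if (any(start(object@tags) < 1L |
                 start(object@tags) > cs[sq]))
      msg <- c(msg, "tag positions must lie within chromosome bounds")
    if (any(width(object@tags) != 1L))
      msg <- c(msg, "tags must be width-1 5' positions")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a TagSet
#'
#' @param tags Width-1 \code{GRanges} of tag 5' positions (strand set,
#'   \code{readLength} metadata column in bp).
#' @param totalRaw Total number of sequencing reads in the library.
#' @param totalMapped Number of mapped reads retained as tags.
#' @param chromSizes Named numeric vector of chromosome lengths (bp).
#' @return A \code{TagSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 50), width = 1),
#'   strand = c("+", "-"), readLength = 36L)
#' TagSet(gr, totalRaw = 4, totalMapped = 2, chromSizes = c(chr1 = 1000))
#' @export
TagSet <- function(tags = GRanges(), totalRaw = length(tags),
                   totalMapped = length(tags), chromSizes = numeric()) {
  if (length(tags) && is.null(tags$readLength))
    tags$readLength <- NA_integer_
  new("TagSet", tags = tags, totalRaw = as.numeric(totalRaw),
      totalMapped = as.numeric(totalMapped),
      chromSizes = chromSizes)
}

#' FilterReport: bookkeeping for a read-filtering step
#'
#' Counts removed by the duplicate and blacklist filters. The counts always
#' reconcile: \code{outputTags = inputTags - duplicatesRemoved -
#' blacklistedRemoved}.
#'
#' @slot inputTags,duplicatesRemoved,blacklistedRemoved,outputTags counts.
#' @export
setClass("FilterReport",
  representation(
    inputTags = "numeric",
    duplicatesRemoved = "numeric",
    blacklistedRemoved = "numeric",
    outputTags = "numeric"
  )
)

setValidity("FilterReport", function(object) {
  with.slots <- c(object@inputTags, object@duplicatesRemoved,
                  object@blacklistedRemoved, object@outputTags)
  if (any(with.slots < 0))
    return("all counts must be non-negative")
  if (object@outputTags !=
      object@inputTags - object@duplicatesRemoved - object@blacklistedRemoved)
    return("outputTags must equal inputTags - duplicatesRemoved - blacklistedRemoved")
  TRUE
})

FilterReport <- function(inputTags, duplicatesRemoved = 0,
                         blacklistedRemoved = 0) {
  new("FilterReport", inputTags = as.numeric(inputTags),
      duplicatesRemoved = as.numeric(duplicatesRemoved),
      blacklistedRemoved = as.numeric(blacklistedRemoved),
      outputTags = as.numeric(inputTags - duplicatesRemoved -
                              blacklistedRemoved))
}

#' XcorProfile: strand cross-correlation as a function of shift
#'
#' Holds the Pearson correlation between plus-strand and shifted minus-strand
#' 5'-position occupancy, evaluated on a shift grid, plus the derived summary
#' quantities: the background (minimum) correlation, the correlation at the
#' estimated fragment width, the correlation at the read-length ("phantom")
#' peak, the estimated fragment width itself, and the predicted tag length.
#'
#' @slot shifts Integer vector of evaluated shifts (bp), strictly increasing.
#' @slot cc Correlation value at each shift, in [-1, 1].
#' @slot ccBackground Minimum correlation over the grid.
#' @slot ccFragment Correlation at the estimated fragment-width shift.
#' @slot ccReadlen Correlation at the predicted tag-length shift.
#' @slot fragmentWidth Estimated fragment width (bp).
#' @slot predictedTagLength Shift of the phantom peak (bp).
#' @slot meanReadLength Mean sequenced read length (bp).
#' @export
setClass("XcorProfile",
  representation(
    shifts = "integer",
    cc = "numeric",
    ccBackground = "numeric",
    ccFragment = "numeric",
    ccReadlen = "numeric",
    fragmentWidth = "numeric",
    predictedTagLength = "numeric",
    meanReadLength = "numeric"
  )
)

setValidity("XcorProfile", function(object) {
  msg <- NULL
  if (length(object@shifts) != length(object@cc))
    msg <- c(msg, "shifts and cc must have equal length")
  if (is.unsorted(object@shifts, strictly = TRUE))
    msg <- c(msg, "shifts must be strictly increasing")
  if (length(object@cc) && any(abs(object@cc) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(object@ccBackground) == 1L && length(object@ccFragment) == 1L &&
      !is.na(object@ccBackground) && !is.na(object@ccFragment) &&
      object@ccBackground > object@ccFragment + 1e-12)
    msg <- c(msg, "ccBackground cannot exceed ccFragment")
  if (is.null(msg)) TRUE else msg
})

#' StitchedRegionSet: gap-merged peak clusters with signal ranking
#'
#' Regions produced by stitching peaks whose gaps are at most
#' \code{stitchGap} bp, carrying per-region metadata columns
#' \code{memberPeaks} (number of constituent peaks), \code{signal}
#' (control-corrected tags-per-million), \code{rank} (1-based position in
#' ascending-signal order) and \code{isSuper} (above the inflection-point
#' cutoff), plus the cutoff itself.
#'
#' @slot regions \code{GRanges} of stitched regions with metadata columns.
#' @slot stitchGap Maximum gap merged (bp).
#' @slot cutoffSignal Signal value separating super from typical regions
#'   (NA before classification).
#' @export
setClass("StitchedRegionSet",
  representation(
    regions = "GRanges",
    stitchGap = "numeric",
    cutoffSignal = "numeric"
  )
)

setValidity("StitchedRegionSet", function(object) {
  msg <- NULL
  r <- object@regions
  if (length(r) > 1L) {
    red <- reduce(r, ignore.strand = TRUE)
    if (length(red) != length(r))
      msg <- c(msg, "stitched regions must not overlap one another")
  }
  if (!all(c("memberPeaks", "signal", "rank", "isSuper") %in%
           colnames(mcols(r))))
    msg <- c(msg, paste("regions need metadata columns memberPeaks,",
                        "signal, rank, isSuper"))
  if (object@stitchGap < 0)
    msg <- c(msg, "stitchGap must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' CoverageMatrix: per-gene binned tag density
#'
#' Rows are genes (orientation-flipped so column 1 is always the 5' end),
#' columns are bins; values are tag densities in tags-per-million per bp.
#' The bin layout (flank vs body, width in bp or gene fraction) is described
#' by the \code{bins} data.frame.
#'
#' @slot values Numeric matrix, genes x bins; NA marks bins truncated off
#'   the chromosome.
#' @slot bins data.frame with columns \code{label}, \code{type} (one of
#'   "flank5", "body", "flank3", "window") and \code{width} (bp, NA for
#'   fractional body bins).
#' @export
setClass("CoverageMatrix",
  representation(values = "matrix", bins = "data.frame")
)

setValidity("CoverageMatrix", function(object) {
  if (ncol(object@values) != nrow(object@bins))
    return("one bins row per value column required")
  v <- object@values
  if (length(v) && any(v < -1e-12, na.rm = TRUE))
    return("densities must be non-negative")
  TRUE
})

#' AnnotationDistribution: genic classification of peaks
#'
#' Each peak is assigned exactly one category by precedence
#' (promoter > gene body > gene-centric window > intergenic) plus its
#' nearest gene by TSS distance.
#'
#' @slot counts Named integer vector over the four categories.
#' @slot perPeak \code{DataFrame} with one row per peak: \code{peak},
#'   \code{category}, \code{nearestGene}, \code{distance} (bp, signed,
#'   0 when the peak covers the TSS).
#' @export
setClass("AnnotationDistribution",
  representation(counts = "integer", perPeak = "DataFrame")
)

setValidity("AnnotationDistribution", function(object) {
  if (sum(object@counts) != nrow(object@perPeak))
    return("category counts must sum to the number of peaks")
  TRUE
})

#' MetricPanel: the full quality-metric panel with rank flags
#'
#' Ordered metric entries, each carrying the metric's value (or NA when the
#' inputs needed to compute it were not provided), its five-level rank flag,
#' and the flag's numeric score, plus the overall quality score Q (the mean
#' score over ranked metrics) and its own rank.
#'
#' @slot entries \code{DataFrame} with columns \code{metric} (short key),
#'   \code{display} (human-readable name), \code{value}, \code{rank}
#'   (Excellent/Good/Average/Below-average/Poor or NA when unranked or
#'   missing) and \code{score}.
#' @slot overallQ Mean score over ranked, non-missing metrics.
#' @slot overallRank Rank label assigned to \code{overallQ}.
#' @export
setClass("MetricPanel",
  representation(
    entries = "DataFrame",
    overallQ = "numeric",
    overallRank = "character"
  )
)

setValidity("MetricPanel", function(object) {
  need <- c("metric", "display", "value", "rank", "score")
  if (!all(need %in% colnames(object@entries)))
    return(paste("entries needs columns", paste(need, collapse = ", ")))
  sc <- object@entries$score
  ok <- is.na(sc) | sc %in% c(-2, -1, 0, 1, 2)
  if (!all(ok))
    return("scores must lie on the {-2,-1,0,1,2} scale")
  TRUE
})
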
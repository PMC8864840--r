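#' @include AllClasses.R
NULL

#' Accessors for chromaQC classes
#'
#' Small accessor generics: \code{tags} returns the tag \code{GRanges} of a
#' \code{TagSet}; \code{chromSizes}, \code{totalRaw} and \code{totalMapped}
#' return its library-level fields; \code{regions} returns the stitched
#' \code{GRanges} of a \code{StitchedRegionSet} and \code{cutoffSignal} its
#' super/typical separation value; \code{panelEntries} returns the metric
#' table of a \code{MetricPanel} as a \code{DataFrame}.
#'
#' @param x A chromaQC object.
#' @return The slot value (see details above).
#' @name accessors
#' @aliases tags chromSizes totalRaw totalMapped regions cutoffSignal
#'   panelEntries
#' @examples
#' ts <- TagSet(GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(5, width = 1), strand = "+", readLength = 36L),
#'   chromSizes = c(chr1 = 100))
#' tags(ts)
#' totalMapped(ts)
NULL

#' @rdname accessors
#' @export
setGeneric("tags", function(x) standardGeneric("tags"))
#' @rdname accessors
#' @export
setMethod("tags", "TagSet", function(x) x@tags)

#' @rdname accessors
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))
#' @rdname accessors
#' @export
setMethod("chromSizes", "TagSet", function(x) x@chromSizes)

#' @rdname accessors
#' @export
setGeneric("totalRaw", function(x) standardGeneric("totalRaw"))
#' @rdname accessors
#' @export
setMethod("totalRaw", "TagSet", function(x) x@totalRaw)

#' @rdname accessors
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))
#' @rdname accessors
#' @export
setMethod("totalMapped", "TagSet", function(x) x@totalMapped)

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setMethod("regions", "StitchedRegionSet", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("cutoffSignal", function(x) standardGeneric("cutoffSignal"))
#' @rdname accessors
#' @export
setMethod("cutoffSignal", "StitchedRegionSet", function(x) x@cutoffSignal)

#' @rdname accessors
#' @export
setGeneric("panelEntries", function(x) standardGeneric("panelEntries"))
#' @rdname accessors
#' @export
setMethod("panelEntries", "MetricPanel", function(x) x@entries)

#' @export
setMethod("length", "TagSet", function(x) length(x@tags))

#' @export
setMethod("length", "StitchedRegionSet", function(x) length(x@regions))

setMethod("show", "TagSet", function(object) {
  cat("TagSet with", length(object@tags), "tags on",
      length(unique(as.character(seqnames(object@tags)))), "chromosome(s)\n")
  cat("  totalRaw:", format(object@totalRaw, big.mark = ","),
      " totalMapped:", format(object@totalMapped, big.mark = ","), "\n")
  if (length(object@chromSizes))
    cat("  genome:", paste0(names(object@chromSizes), "=",
        format(object@chromSizes, scientific = FALSE, trim = TRUE),
        collapse = ", "), "\n")
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", object@inputTags, "in,",
      object@duplicatesRemoved, "duplicates removed,",
      object@blacklistedRemoved, "blacklisted removed,",
      object@outputTags, "out\n")
})

setMethod("show", "XcorProfile", function(object) {
  cat("XcorProfile over shifts [", min(object@shifts), ",",
      max(object@shifts), "] bp (", length(object@shifts), "points )\n")
  cat("  fragment width:", object@fragmentWidth,
      "bp; predicted tag length:", object@predictedTagLength, "bp\n")
  cat(sprintf("  cc: background %.4f, fragment %.4f, read-length %.4f\n",
              object@ccBackground, object@ccFragment, object@ccReadlen))
})

setMethod("show", "StitchedRegionSet", function(object) {
  n <- length(object@regions)
  ns <- if (n) sum(object@regions$isSuper, na.rm = TRUE) else 0L
  cat("StitchedRegionSet:", n, "regions (gap <=", object@stitchGap, "bp),",
      ns, "super\n")
  if (!is.na(object@cutoffSignal))
    cat(sprintf("  cutoff signal: %.4f\n", object@cutoffSignal))
})

setMethod("show", "CoverageMatrix", function(object) {
  cat("CoverageMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "bins (",
      paste(unique(object@bins$type), collapse = "/"), ")\n")
})

setMethod("show", "AnnotationDistribution", function(object) {
  cat("AnnotationDistribution over", nrow(object@perPeak), "peaks:\n")
  for (nm in names(object@counts))
    cat(sprintf("  %-20s %d\n", nm, object@counts[[nm]]))
})

setMethod("show", "MetricPanel", function(object) {
  cat("MetricPanel with", nrow(object@entries), "metrics\n")
  e <- object@entries
  for (i in seq_len(nrow(e))) {
    val <- if (is.na(e$value[i])) "NA" else format(e$value[i], digits = 5)
    rk <- if (is.na(e$rank[i])) "-" else e$rank[i]
    cat(sprintf("  %-28s %12s  %s\n", e$display[i], val, rk))
  }
  cat(sprintf("  Overall quality Q = %.3f (%s)\n",
              object@overallQ, object@overallRank))
})
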
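#' @include AllClasses.R utils.R
NULL

#' Remove redundant (duplicate) tags
#'
#' Keeps at most one tag per (chromosome, 5' position, strand) key — the
#' first encountered in input order. Read length is deliberately not part
#' of the key: a tag is the 5' end of a single-end read, so reads of
#' different lengths starting at the same base are still redundant.
#'
#' @param ts A \code{\link{TagSet}}.
#' @return A list with elements \code{tags} (deduplicated \code{TagSet})
#'   and \code{report} (a \code{FilterReport}).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(10, 10, 20), width = 1), strand = "+",
#'   readLength = 36L)
#' ts <- TagSet(gr, chromSizes = c(chr1 = 100))
#' removeDuplicates(ts)$report
#' @export
removeDuplicates <- function(ts) {
  gr <- tags(ts)
  dup <- duplicated(tagKeys(gr))
  out <- initialize(ts, tags = gr[!dup])
  list(tags = out,
       report = FilterReport(inputTags = length(gr),
                             duplicatesRemoved = sum(dup)))
}

#' Remove tags falling in blacklisted regions
#'
#' A tag is removed iff its 5' position lies inside any blacklist interval
#' (the half-open test of the BED convention: a tag at 0-based position p
#' is inside [s, e) iff s <= p < e). Strand is ignored. Blacklist entries
#' on chromosomes without tags are silently inert.
#'
#' @param ts A \code{\link{TagSet}}.
#' @param blacklist \code{GRanges} of blacklisted regions.
#' @return A list with elements \code{tags} and \code{report}, as for
#'   \code{\link{removeDuplicates}}.
#' @export
filterBlacklist <- function(ts, blacklist) {
  gr <- tags(ts)
  if (!length(blacklist) || !length(gr)) {
    return(list(tags = ts, report = FilterReport(inputTags = length(gr))))
  }
  ## blacklist entries on chromosomes absent from the tags are a
  ## silent no-op; keep the Seqinfo merge quiet about them
  hit <- suppressWarnings(overlapsAny(gr, blacklist,
                                      ignore.strand = TRUE))
  out <- initialize(ts, tags = gr[!hit])
  list(tags = out,
       report = FilterReport(inputTags = length(gr),
                             blacklistedRemoved = sum(hit)))
}

#' Remove peaks overlapping blacklisted regions
#'
#' A peak is removed iff it overlaps any blacklist interval by at least
#' 1 bp (half-open abutment does not count as overlap).
#'
#' @param peaks,blacklist \code{GRanges}.
#' @return The retained peaks, order preserved.
#' @export
filterPeaksBlacklist <- function(peaks, blacklist) {
  if (!length(blacklist) || !length(peaks)) return(peaks)
  peaks[!suppressWarnings(overlapsAny(peaks, blacklist,
                                      ignore.strand = TRUE))]
}

#' Apply the standard tag filters in fixed order
#'
#' Duplicates are removed first, then blacklisted tags, so that the
#' non-redundant fraction (computed before any filtering) is unaffected by
#' the blacklist choice. Returns the filtered tags plus a combined
#' \code{FilterReport}.
#'
#' @param ts A \code{\link{TagSet}}.
#' @param blacklist Optional \code{GRanges} of blacklisted regions.
#' @return A list with elements \code{tags} and \code{report}.
#' @export
filterTags <- function(ts, blacklist = NULL) {
  d <- removeDuplicates(ts)
  b <- if (is.null(blacklist)) {
    list(tags = d$tags, report = FilterReport(length(tags(d$tags))))
  } else filterBlacklist(d$tags, blacklist)
  list(tags = b$tags,
       report = FilterReport(
         inputTags = length(tags(ts)),
         duplicatesRemoved = d$report@duplicatesRemoved,
         blacklistedRemoved = b$report@blacklistedRemoved))
}
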
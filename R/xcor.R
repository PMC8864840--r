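#' @include AllClasses.R utils.R
NULL

## Exact Pearson correlation between two binary occupancy vectors given
## only their set sizes, overlap count and window length. For indicators
## x, y over a window of length L with nx, ny ones and m co-occurrences:
##   cov = m/L - (nx/L)(ny/L),  var_x = (nx/L)(1 - nx/L), ditto var_y.
binaryPearson <- function(m, nx, ny, L) {
  mx <- nx / L
  my <- ny / L
  vx <- mx * (1 - mx)
  vy <- my * (1 - my)
  ifelse(vx <= 0 | vy <= 0, 0, (m / L - mx * my) / sqrt(vx * vy))
}

## Per-chromosome cross-correlation curve over a shift grid.
## plusPos/minusPos: sorted unique 1-based 5' positions; N: chrom length.
## cc(s) = Pearson cor of plus indicator over [1, N-s] with minus
## indicator over [s+1, N] (minus shifted left by s).
chromXcor <- function(plusPos, minusPos, N, shifts) {
  occM <- logical(N)
  occM[minusPos] <- TRUE
  nxs <- findInterval(N - shifts, plusPos)
  nys <- length(minusPos) - findInterval(shifts, minusPos)
  ms <- vapply(seq_along(shifts), function(i) {
    k <- nxs[i]
    if (k == 0L) return(0L)
    sum(occM[plusPos[seq_len(k)] + shifts[i]])
  }, 0L)
  binaryPearson(ms, nxs, nys, N - shifts)
}

#' Strand cross-correlation profile
#'
#' Computes, for every shift on a grid, the Pearson correlation between the
#' plus-strand 5'-position occupancy vector and the minus-strand occupancy
#' vector shifted towards it, per chromosome, combined as a
#' tag-count-weighted mean. The curve of a successful experiment peaks at
#' the fragment length (true signal) with a secondary "phantom" peak at the
#' read length. Occupancy is binary over distinct 5' positions, so tags
#' should be deduplicated first. Chromosomes with fewer than
#' \code{minTagsPerChrom} tags, or shorter than the largest shift, are
#' skipped.
#'
#' The returned \code{\link{XcorProfile}} carries the derived summaries:
#' estimated fragment width (curve maximum outside the phantom window
#' around the mean read length), predicted tag length (maximum inside that
#' window), and the background (minimum) correlation, from which
#' \code{\link{computeNSC}} and \code{\link{computeRSC}} are ratios.
#'
#' @param ts A deduplicated \code{\link{TagSet}}.
#' @param shiftRange Two-element [lo, hi] shift bounds in bp (default
#'   c(0, 500), covering typical fragmentation sizes).
#' @param step Grid step in bp (default 5).
#' @param minTagsPerChrom Minimum tags for a chromosome to contribute
#'   (default 200).
#' @param phantomHalfWidth Half-width (bp) of the exclusion window around
#'   the mean read length (default 10, mirroring the tag-length metric's
#'   +/-10 tolerance).
#' @return An \code{\link{XcorProfile}}.
#' @export
strandCrossCorrelation <- function(ts, shiftRange = c(0L, 500L), step = 5L,
                                   minTagsPerChrom = 200L,
                                   phantomHalfWidth = 10L) {
  gr <- tags(ts)
  stopifnot(length(shiftRange) == 2L, shiftRange[2L] > shiftRange[1L],
            step >= 1L)
  shifts <- as.integer(seq(shiftRange[1L], shiftRange[2L], by = step))
  std <- as.character(strand(gr))
  if (!any(std == "+") || !any(std == "-"))
    stop("cross-correlation undefined: both strands must be represented")
  cs <- chromSizes(ts)
  chroms <- names(cs)
  ccAcc <- numeric(length(shifts))
  wAcc <- 0
  skippedShort <- character()
  for (ch in chroms) {
    N <- as.integer(cs[[ch]])
    onCh <- as.character(seqnames(gr)) == ch
    plusPos <- sort(unique(start(gr)[onCh & std == "+"]))
    minusPos <- sort(unique(start(gr)[onCh & std == "-"]))
    ntag <- length(plusPos) + length(minusPos)
    if (ntag < minTagsPerChrom) next
    if (N <= shiftRange[2L]) {
      skippedShort <- c(skippedShort, ch)
      next
    }
    if (!length(plusPos) || !length(minusPos)) next
    ccAcc <- ccAcc + ntag * chromXcor(plusPos, minusPos, N, shifts)
    wAcc <- wAcc + ntag
  }
  if (length(skippedShort))
    warning("chromosome(s) shorter than the maximum shift skipped: ",
            paste(skippedShort, collapse = ", "))
  if (wAcc == 0)
    stop("no chromosome had enough tags for cross-correlation")
  cc <- ccAcc / wAcc
  rl <- gr$readLength
  mrl <- if (length(rl)) mean(rl, na.rm = TRUE) else NA_real_
  xcorProfileFromCC(shifts, cc, meanReadLength = mrl,
                    phantomHalfWidth = phantomHalfWidth)
}

#' Build an XcorProfile from a precomputed correlation curve
#'
#' Derives the summary quantities (background, fragment width, predicted
#' tag length and their correlations) from an explicit (shift, cc) curve.
#' Used internally by \code{\link{strandCrossCorrelation}} and directly
#' when analysing constructed profiles.
#'
#' @param shifts Strictly increasing integer shifts (bp).
#' @param cc Correlation at each shift.
#' @param meanReadLength Mean read length (bp); centre of the phantom
#'   window.
#' @param phantomHalfWidth Half-width of the phantom exclusion window (bp).
#' @return An \code{\link{XcorProfile}}.
#' @export
xcorProfileFromCC <- function(shifts, cc, meanReadLength,
                              phantomHalfWidth = 10L) {
  shifts <- as.integer(shifts)
  stopifnot(length(shifts) == length(cc), !is.unsorted(shifts,
                                                       strictly = TRUE))
  inPhantom <- if (is.na(meanReadLength)) rep(FALSE, length(shifts))
    else shifts >= meanReadLength - phantomHalfWidth &
         shifts <= meanReadLength + phantomHalfWidth
  if (all(inPhantom))
    stop("all shifts fall inside the phantom exclusion window; ",
         "widen the shift range")
  outIdx <- which(!inPhantom)
  fragIdx <- outIdx[which.max(cc[outIdx])]
  fragmentWidth <- shifts[fragIdx]
  if (any(inPhantom)) {
    inIdx <- which(inPhantom)
    tagIdx <- inIdx[which.max(cc[inIdx])]
    predicted <- shifts[tagIdx]
    ccReadlen <- cc[tagIdx]
  } else {
    warning("no shift falls in the phantom window; ",
            "predicted tag length set to the mean read length")
    predicted <- as.numeric(meanReadLength)
    nearest <- which.min(abs(shifts - meanReadLength))
    ccReadlen <- cc[nearest]
  }
  new("XcorProfile", shifts = shifts, cc = as.numeric(cc),
      ccBackground = min(cc), ccFragment = cc[fragIdx],
      ccReadlen = ccReadlen, fragmentWidth = as.numeric(fragmentWidth),
      predictedTagLength = as.numeric(predicted),
      meanReadLength = as.numeric(meanReadLength))
}

#' Estimated fragment width
#'
#' The shift maximising the cross-correlation outside the phantom-peak
#' exclusion window around the mean read length.
#'
#' @param profile An \code{\link{XcorProfile}}.
#' @return Fragment width in bp.
#' @export
estimateFragmentWidth <- function(profile) profile@fragmentWidth

#' Predicted tag length and its deviation from the read length
#'
#' \code{predictedTagLength} returns the shift of the maximal correlation
#' inside the phantom window; \code{tagLengthDelta} returns the
#' tag-length metric E = |predicted - mean read length|.
#'
#' @param profile An \code{\link{XcorProfile}}.
#' @return Length in bp (\code{predictedTagLength}) or absolute deviation
#'   in bp (\code{tagLengthDelta}).
#' @export
predictedTagLength <- function(profile) profile@predictedTagLength

#' @rdname predictedTagLength
#' @export
tagLengthDelta <- function(profile) {
  if (is.na(profile@meanReadLength)) return(NA_real_)
  abs(profile@predictedTagLength - profile@meanReadLength)
}

#' Normalized strand-correlation coefficient (NSC)
#'
#' The maximum cross-correlation divided by the background (minimum)
#' cross-correlation. At least 1 by construction when the background is
#' positive; a flat profile gives 1 (no enrichment). Undefined (NA) when
#' the background is not positive.
#'
#' @param profile An \code{\link{XcorProfile}}.
#' @return The NSC ratio, or NA.
#' @export
computeNSC <- function(profile) {
  bg <- profile@ccBackground
  if (is.na(bg) || bg <= 0) return(NA_real_)
  max(profile@cc) / bg
}

#' Relative strand-correlation coefficient (RSC)
#'
#' The background-subtracted fragment-length correlation over the
#' background-subtracted read-length (phantom) correlation:
#' \code{(ccFragment - bg) / (ccReadlen - bg)}. Undefined (NA) when the
#' phantom correlation equals the background.
#'
#' @param profile An \code{\link{XcorProfile}}.
#' @return The RSC ratio, or NA.
#' @export
computeRSC <- function(profile) {
  bg <- profile@ccBackground
  denom <- profile@ccReadlen - bg
  if (is.na(denom) || denom == 0) return(NA_real_)
  (profile@ccFragment - bg) / denom
}

#' Cross-correlation curve as a data.frame
#'
#' @param profile An \code{\link{XcorProfile}}.
#' @return data.frame with columns \code{shift} and \code{cc}, suitable
#'   for a TSV dump.
#' @export
xcorTable <- function(profile) {
  data.frame(shift = profile@shifts, cc = profile@cc)
}
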
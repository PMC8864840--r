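#' @include AllClasses.R utils.R
NULL

#' Fraction of reads in peaks (FRiP)
#'
#' The fraction of tags whose 5' position falls inside the union of the
#' peak intervals (overlapping peaks are reduced first so no tag is
#' double-counted). Tags should be deduplicated and blacklist-filtered,
#' and peaks blacklist-filtered, before calling.
#'
#' @param ts A filtered \code{\link{TagSet}}.
#' @param peaks \code{GRanges} of peaks.
#' @return Fraction in [0, 1]; 0 when there are no peaks; NA when there
#'   are no tags.
#' @export
computeFRiP <- function(ts, peaks) {
  gr <- tags(ts)
  if (!length(gr)) return(NA_real_)
  if (!length(peaks)) return(0)
  un <- reduce(peaks, ignore.strand = TRUE)
  mean(overlapsAny(gr, un, ignore.strand = TRUE))
}

#' Count peaks (after blacklist filtering)
#'
#' @param peaks \code{GRanges} of peaks, or NULL for an absent
#'   input-corrected peak set.
#' @return The record count, or NA when \code{peaks} is NULL (the metric
#'   is then reported missing).
#' @export
countPeaks <- function(peaks) {
  if (is.null(peaks)) return(NA_real_)
  length(peaks)
}

#' Stitch peaks into clustered regions
#'
#' Merges peaks transitively whenever the gap between two peaks (start of
#' the later minus end of the earlier, in 0-based half-open coordinates)
#' is at most \code{stitchGap} bp. The resulting region spans its member
#' peaks. Geometry only: signals and the super/typical split are added by
#' \code{\link{scoreRegions}} and \code{\link{classifyRegions}}.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param stitchGap Maximum gap merged, in bp (default 12500, the ROSE
#'   convention).
#' @return A \code{\link{StitchedRegionSet}}.
#' @examples
#' p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 251),
#'   c(200, 350)))
#' length(stitchPeaks(p, 12500))  # 1 region
#' length(stitchPeaks(p, 10))    # 2 regions
#' @export
stitchPeaks <- function(peaks, stitchGap = 12500) {
  if (stitchGap < 0) stop("stitchGap must be non-negative")
  ## reduce() keeps ranges separated by a gap of at least min.gapwidth
  ## apart, i.e. merges gaps <= min.gapwidth - 1; gap <= stitchGap needs
  ## min.gapwidth = stitchGap + 1
  red <- reduce(peaks, min.gapwidth = stitchGap + 1,
                ignore.strand = TRUE, with.revmap = TRUE)
  regions <- GRanges(seqnames(red), IRanges(start(red), end(red)))
  regions$memberPeaks <- lengths(red$revmap)
  regions$signal <- NA_real_
  regions$rank <- NA_integer_
  regions$isSuper <- NA
  new("StitchedRegionSet", regions = regions,
      stitchGap = as.numeric(stitchGap), cutoffSignal = NA_real_)
}

#' Score stitched regions by control-corrected tag density
#'
#' Signal of a region is the sample tags-per-million falling in it, minus
#' the control tags-per-million when a control is given, floored at 0
#' (negative densities are artifacts of sparse controls). Regions are then
#' ranked 1..n in ascending signal, ties broken by genomic order
#' (chromosome, start).
#'
#' @param srs A \code{\link{StitchedRegionSet}} from
#'   \code{\link{stitchPeaks}}.
#' @param ts Filtered sample \code{\link{TagSet}}.
#' @param controlTs Optional filtered control \code{\link{TagSet}}.
#' @return The \code{StitchedRegionSet} with \code{signal} and \code{rank}
#'   filled in.
#' @export
scoreRegions <- function(srs, ts, controlTs = NULL) {
  r <- regions(srs)
  nTot <- length(tags(ts))
  cnt <- countOverlaps(r, tags(ts), ignore.strand = TRUE)
  sig <- if (nTot > 0) cnt / nTot * 1e6 else rep(0, length(r))
  if (!is.null(controlTs)) {
    nCtl <- length(tags(controlTs))
    ctl <- countOverlaps(r, tags(controlTs), ignore.strand = TRUE)
    csig <- if (nCtl > 0) ctl / nCtl * 1e6 else rep(0, length(r))
    sig <- pmax(sig - csig, 0)
  }
  r$signal <- sig
  ord <- order(sig, as.integer(factor(as.character(seqnames(r)))),
               start(r))
  r$rank[ord] <- seq_along(ord)
  initialize(srs, regions = r)
}

#' Inflection-point cutoff on a ranked signal curve
#'
#' The ROSE-style slope-1 tangent rule: regions are sorted by ascending
#' signal, rank index and signal are each rescaled to [0, 1], and the
#' cutoff is the signal at the point where the discrete forward slope of
#' the scaled curve exceeds 1 and stays above it for the remainder of the
#' curve (on a convex curve this is simply the first slope-1 crossing;
#' requiring the exceedance to persist keeps isolated noise slopes on a
#' flat curve from firing the rule). Regions with signal strictly above
#' the cutoff are "super". A curve whose final slope never exceeds 1
#' (e.g. a linear ramp) yields the maximum signal as cutoff and zero
#' super regions; identical signals likewise (with a warning).
#'
#' @param signals Numeric vector of region signals (any order).
#' @return List with \code{cutoff} (signal value) and \code{nSuper}
#'   (number of signals strictly above it).
#' @export
findCutoff <- function(signals) {
  n <- length(signals)
  if (n < 3L) stop("need at least 3 regions to place a cutoff")
  s <- sort(signals)
  rng <- s[n] - s[1L]
  if (rng == 0) {
    warning("all region signals identical; no super regions")
    return(list(cutoff = s[n], nSuper = 0L))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1L]) / rng
  slope <- diff(y) / diff(x)
  ## strict "exceeds 1", with an epsilon so an exactly-linear curve
  ## (slope identically 1 up to rounding) never fires
  exceeds <- slope > 1 + 1e-9
  if (!exceeds[n - 1L]) return(list(cutoff = s[n], nSuper = 0L))
  below <- which(!exceeds)
  i <- if (length(below)) below[length(below)] + 1L else 1L
  cutoff <- s[i]
  list(cutoff = cutoff, nSuper = sum(signals > cutoff))
}

#' Classify stitched regions as super or typical
#'
#' Applies \code{\link{findCutoff}} to the region signals and marks
#' regions strictly above the cutoff as super.
#'
#' @param srs A scored \code{\link{StitchedRegionSet}}.
#' @return The \code{StitchedRegionSet} with \code{isSuper} and
#'   \code{cutoffSignal} filled in.
#' @export
classifyRegions <- function(srs) {
  r <- regions(srs)
  if (length(r) < 3L) {
    r$isSuper <- rep(FALSE, length(r))
    return(initialize(srs, regions = r,
                      cutoffSignal = if (length(r))
                        max(r$signal) else NA_real_))
  }
  cut <- findCutoff(r$signal)
  r$isSuper <- r$signal > cut$cutoff
  initialize(srs, regions = r, cutoffSignal = cut$cutoff)
}

#' Super-to-stitched ratio (S)
#'
#' The number of super regions divided by the number of stitched regions.
#'
#' @param srs A classified \code{\link{StitchedRegionSet}}.
#' @return Fraction in [0, 1], or NA for an empty region set.
#' @export
sRatio <- function(srs) {
  n <- length(srs)
  if (!n) return(NA_real_)
  sum(regions(srs)$isSuper, na.rm = TRUE) / n
}

#' Write stitched regions as BED6+
#'
#' Columns: chrom, start, end, name (region id), score (rank), strand,
#' then memberPeaks, signal, isSuper.
#'
#' @param srs A \code{\link{StitchedRegionSet}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeStitchedBED <- function(srs, path) {
  r <- regions(srs)
  r$name <- sprintf("region_%d", seq_along(r))
  r$score <- r$rank
  r$isSuper <- ifelse(is.na(r$isSuper), "NA",
                      ifelse(r$isSuper, "1", "0"))
  r$signal <- round(r$signal, 4)
  writeBED(r, path, extraCols = c("memberPeaks", "signal", "isSuper"))
}
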
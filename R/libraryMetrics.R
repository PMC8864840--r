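#' @include AllClasses.R utils.R
NULL

#' Percentage of reads aligned
#'
#' @param totalRaw Total sequencing reads.
#' @param totalMapped Mapped reads.
#' @return \code{100 * totalMapped / totalRaw}, or \code{NA} when no raw
#'   reads were recorded (the metric is then reported missing and excluded
#'   from the overall quality score).
#' @examples
#' alignedPercent(10e6, 8e6)  # 80
#' @export
alignedPercent <- function(totalRaw, totalMapped) {
  if (is.na(totalRaw) || totalRaw <= 0) return(NA_real_)
  stopifnot(totalMapped <= totalRaw)
  100 * totalMapped / totalRaw
}

#' Non-redundant fraction (NRF)
#'
#' The fraction of mapped reads that are unique: the number of distinct
#' (chromosome, 5' position, strand) keys divided by the number of mapped
#' reads. Computed on mapped tags \emph{before} duplicate or blacklist
#' filtering, with the mapped-read denominator of the ENCODE convention.
#'
#' @param ts A \code{\link{TagSet}} (pre-filtering).
#' @return Fraction in [0, 1], or NA when no reads mapped.
#' @export
computeNRF <- function(ts) {
  gr <- tags(ts)
  denom <- totalMapped(ts)
  if (!length(gr) || denom <= 0) return(NA_real_)
  length(unique(tagKeys(gr))) / denom
}

#' PCR bottleneck coefficient (PBC)
#'
#' Library-complexity measure: the fraction of genomic locations covered by
#' exactly one read among locations covered by at least one read, where a
#' location is a (chromosome, 5' position, strand) key.
#'
#' @param ts A \code{\link{TagSet}} (pre-filtering).
#' @return Fraction in [0, 1], or NA when no reads mapped.
#' @export
computePBC <- function(ts) {
  gr <- tags(ts)
  if (!length(gr)) return(NA_real_)
  counts <- table(tagKeys(gr))
  sum(counts == 1L) / length(counts)
}

#' Per-base quality flag
#'
#' FastQC-style rule on the per-cycle quality summary: \code{fail} if any
#' cycle has lower-quartile < 5 or median < 20; otherwise \code{warn} if
#' any cycle has lower-quartile < 10 or median < 25; otherwise \code{pass}.
#' Thresholds are exposed for tuning.
#'
#' @param stats A \code{fastqStats} object from
#'   \code{\link{readFastqStats}}, or NULL (returns NA: metric missing).
#' @param failQ25,failMedian,warnQ25,warnMedian Rule thresholds.
#' @return "pass", "warn", "fail", or NA.
#' @export
baseQualityFlag <- function(stats, failQ25 = 5, failMedian = 20,
                            warnQ25 = 10, warnMedian = 25) {
  if (is.null(stats)) return(NA_character_)
  pc <- stats$perCycle
  if (any(pc$q25 < failQ25 | pc$median < failMedian)) return("fail")
  if (any(pc$q25 < warnQ25 | pc$median < warnMedian)) return("warn")
  "pass"
}

#' Sequence-diversity (overrepresentation) flag
#'
#' \code{fail} if any exact sequence exceeds 1\% of the sampled reads,
#' \code{warn} if any exceeds 0.1\%, else \code{pass}.
#'
#' @param stats A \code{fastqStats} object, or NULL (returns NA).
#' @param warnFrac,failFrac Overrepresentation thresholds (fractions).
#' @return "pass", "warn", "fail", or NA.
#' @export
diversityFlag <- function(stats, warnFrac = 0.001, failFrac = 0.01) {
  if (is.null(stats)) return(NA_character_)
  top <- if (length(stats$seqFreq)) max(stats$seqFreq) else 0
  if (top > failFrac) return("fail")
  if (top > warnFrac) return("warn")
  "pass"
}

#' Library metrics bundle
#'
#' Convenience wrapper computing the sequencing-library metrics from a
#' pre-filter \code{TagSet} and optional FASTQ statistics.
#'
#' @param ts A \code{\link{TagSet}} (pre-filtering).
#' @param fastqStats Optional \code{fastqStats} object.
#' @return Named list: \code{rawReads}, \code{alignedPercent}, \code{nrf},
#'   \code{pbc}, \code{baseQuality}, \code{diversity},
#'   \code{meanReadLength}.
#' @export
libraryMetrics <- function(ts, fastqStats = NULL) {
  rl <- tags(ts)$readLength
  mrl <- if (!is.null(fastqStats)) fastqStats$meanReadLength
         else if (length(rl)) mean(rl, na.rm = TRUE) else NA_real_
  list(rawReads = totalRaw(ts),
       alignedPercent = alignedPercent(totalRaw(ts), totalMapped(ts)),
       nrf = computeNRF(ts),
       pbc = computePBC(ts),
       baseQuality = baseQualityFlag(fastqStats),
       diversity = diversityFlag(fastqStats),
       meanReadLength = mrl)
}
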
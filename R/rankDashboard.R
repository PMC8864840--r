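#' @include AllClasses.R
NULL

## The five rank levels, their numeric scores and flag colors. The score
## scale is forced by the overall-quality thresholds: a mean of metric
## scores can only reach the "Q >= 2" band if the scale tops out at 2.
rankLabels <- c("Excellent", "Good", "Average", "Below-average", "Poor")
rankScores <- stats::setNames(c(2, 1, 0, -1, -2), rankLabels)
rankColors <- stats::setNames(
  c("#1a9850", "#91cf60", "#fee08b", "#fc8d59", "#d73027"), rankLabels)

## Graded thresholds, applied top-down with inclusive >= at each boundary:
## value >= t[1] -> Excellent, >= t[2] -> Good, >= t[3] -> Average,
## >= t[4] -> Below-average, else Poor.
gradedThresholds <- list(
  A = c(80, 70, 60, 50),
  F = c(0.05, 0.02, 0.01, 0.0075),
  L = c(10000, 5000, 2000, 1000),
  NRF = c(0.8, 0.7, 0.6, 0.5),
  N = c(10000, 5000, 2000, 1000),
  C = c(0.9, 0.75, 0.66, 0.5),
  P = c(10000, 5000, 2000, 1000),
  R = c(30e6, 25e6, 20e6, 15e6),
  S = c(0.2, 0.1, 0.05, 0.02),
  Q = c(2, 1, 0, -1)
)

## pass/warn/fail metrics map onto the ends and middle of the scale
flagMap <- c(pass = "Excellent", warn = "Average", fail = "Poor")

## metric registry: display names in panel order, and how each is ranked
metricRegistry <- data.frame(
  metric = c("A", "B", "FragWidth", "E", "F", "L", "NRF", "N", "NSC",
             "D", "C", "P", "R", "ReadLength", "RSC", "SE", "S"),
  display = c("Aligned percent", "Base quality",
              "Estimated fragment width", "Estimated tag length",
              "FRiP", "Linear stitched peaks (enhancers)",
              "Non-redundant fraction (NRF)", "Normalized peaks",
              "Normalized strand-correlation coefficient (NSC)",
              "Sequence diversity", "PCR bottleneck coefficient (PBC)",
              "Peaks", "Raw reads", "Read length",
              "Relative strand-correlation coefficient (RSC)",
              "SE-like enriched regions (super enhancers)",
              "Super stitched peaks ratio"),
  kind = c("graded", "flag", "unranked", "delta", "graded", "graded",
           "graded", "graded", "nsc", "flag", "graded", "graded",
           "graded", "unranked", "rsc", "unranked", "graded"),
  format = c("percent", "flag", "bp", "bp", "ratio", "count", "ratio",
             "count", "ratio", "flag", "ratio", "count", "count", "bp",
             "ratio", "count", "ratio"),
  stringsAsFactors = FALSE
)

#' Rank a quality metric on the five-level scale
#'
#' Classifies a metric value into Excellent / Good / Average /
#' Below-average / Poor using the published threshold scheme: graded
#' metrics are tested top-down with inclusive \code{>=} at every boundary;
#' pass/warn/fail metrics map pass to Excellent, warn to Average and fail
#' to Poor; the tag-length deviation E is Excellent when |E| < 10 bp and
#' Poor otherwise; NSC is Excellent at >= 1.045 and Poor below; RSC is
#' Excellent at >= 1, Good at >= 0.75 and Poor below. Metrics with no
#' thresholds (estimated fragment width, read length, SE-like region
#' count) are unranked and return NA.
#'
#' @param name Short metric key: one of A, B, FragWidth, E, F, L, NRF, N,
#'   NSC, D, C, P, R, ReadLength, RSC, SE, S, Q.
#' @param value The metric value (a number, or "pass"/"warn"/"fail" for
#'   the flag metrics B and D). NA yields NA (metric missing).
#' @return A rank label, or NA for unranked/missing metrics.
#' @examples
#' rankMetric("NRF", 0.8)   # boundary -> Excellent
#' rankMetric("NRF", 0.55)  # Below-average
#' rankMetric("NSC", 1.044) # Poor
#' @export
rankMetric <- function(name, value) {
  if (name == "Q") return(rankGraded(value, gradedThresholds$Q))
  row <- metricRegistry[metricRegistry$metric == name, ]
  if (!nrow(row)) stop("unknown metric: ", name)
  if (length(value) != 1L || is.na(value)) return(NA_character_)
  switch(row$kind,
    graded = rankGraded(as.numeric(value), gradedThresholds[[name]]),
    flag = {
      if (!value %in% names(flagMap))
        stop("flag metric ", name, " needs pass/warn/fail, got ", value)
      unname(flagMap[value])
    },
    delta = if (abs(as.numeric(value)) < 10) "Excellent" else "Poor",
    nsc = if (as.numeric(value) >= 1.045) "Excellent" else "Poor",
    rsc = {
      v <- as.numeric(value)
      if (v >= 1) "Excellent" else if (v >= 0.75) "Good" else "Poor"
    },
    unranked = NA_character_
  )
}

rankGraded <- function(value, th) {
  if (is.na(value)) return(NA_character_)
  if (value >= th[1L]) "Excellent"
  else if (value >= th[2L]) "Good"
  else if (value >= th[3L]) "Average"
  else if (value >= th[4L]) "Below-average"
  else "Poor"
}

#' Numeric score and flag color of a rank label
#'
#' @param label A rank label (Excellent, Good, Average, Below-average,
#'   Poor) or NA.
#' @return \code{rankScore}: the score on the 2/1/0/-1/-2 scale (NA for
#'   NA); \code{rankColor}: the hex flag color.
#' @export
rankScore <- function(label) {
  ifelse(is.na(label), NA_real_, rankScores[label])
}

#' @rdname rankScore
#' @export
rankColor <- function(label) {
  ifelse(is.na(label), "#ffffff", rankColors[label])
}

#' Assemble the quality-metric panel
#'
#' Ranks every supplied metric, attaches scores, and computes the overall
#' quality Q as the arithmetic mean of the scores of ranked, non-missing
#' metrics (unranked metrics and metrics whose inputs were not provided
#' are excluded rather than penalised). Q is itself ranked on its own
#' thresholds.
#'
#' @param values Named list of metric values keyed by the short metric
#'   keys of \code{\link{rankMetric}} (missing keys are reported as NA).
#' @return A \code{\link{MetricPanel}}.
#' @examples
#' p <- buildMetricPanel(list(A = 85, NRF = 0.9, C = 0.95, F = 0.06))
#' p
#' @export
buildMetricPanel <- function(values) {
  reg <- metricRegistry
  n <- nrow(reg)
  val <- rep(NA_real_, n)
  valChr <- rep(NA_character_, n)
  rank <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    key <- reg$metric[i]
    v <- values[[key]]
    if (is.null(v) || length(v) != 1L || is.na(v)) next
    if (reg$kind[i] == "flag") valChr[i] <- as.character(v)
    else val[i] <- as.numeric(v)
    rank[i] <- rankMetric(key, v)
  }
  score <- rankScore(rank)
  ranked <- !is.na(score)
  if (!any(ranked))
    stop("no rankable metrics supplied")
  q <- mean(score[ranked])
  entries <- DataFrame(metric = reg$metric, display = reg$display,
                       value = val, valueChr = valChr, rank = rank,
                       score = score, format = reg$format)
  new("MetricPanel", entries = entries, overallQ = q,
      overallRank = rankMetric("Q", q))
}

#' Overall quality of a panel
#'
#' @param panel A \code{\link{MetricPanel}}.
#' @return List with \code{Q} (mean score over ranked metrics) and
#'   \code{rank} (its label).
#' @export
overallQuality <- function(panel) {
  list(Q = panel@overallQ, rank = panel@overallRank)
}

formatMetricValue <- function(value, valueChr, fmt) {
  if (!is.na(valueChr)) return(valueChr)
  if (is.na(value)) return("NA")
  switch(fmt,
    percent = sprintf("%.1f", value),
    ratio = sprintf("%.4f", value),
    count = formatC(value, format = "d", big.mark = ","),
    bp = sprintf("%.0f", value),
    flag = "NA",
    format(value))
}

#' Render the quality report (TSV + color-flagged HTML)
#'
#' Writes the panel as \code{<prefix>-stats.tsv} (columns metric, value,
#' rank, score; one row per metric plus the overall quality) and as a
#' self-contained \code{<prefix>-stats.html} whose rank cells are
#' background-colored by flag. Values are fixed-precision (ratios 4
#' decimals, percentages 1 decimal, counts with thousands separators) so
#' re-rendering the same panel is byte-identical. Missing metrics show
#' "NA" with an unflagged "-" rank and do not enter Q.
#'
#' @param panel A \code{\link{MetricPanel}}.
#' @param outDir Output directory (created if needed).
#' @param prefix File-name prefix (default "chromaqc").
#' @return Invisibly, a character vector with the tsv and html paths.
#' @export
renderReport <- function(panel, outDir, prefix = "chromaqc") {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outDir)
  e <- panel@entries
  valTxt <- vapply(seq_len(nrow(e)), function(i)
    formatMetricValue(e$value[i], e$valueChr[i], e$format[i]), "")
  rankTxt <- ifelse(is.na(e$rank), "-", e$rank)
  scoreTxt <- ifelse(is.na(e$score), "-",
                     formatC(e$score, format = "d"))
  qTxt <- sprintf("%.4f", panel@overallQ)
  tsv <- file.path(outDir, paste0(prefix, "-stats.tsv"))
  lines <- c("metric\tvalue\trank\tscore",
             paste(e$display, valTxt, rankTxt, scoreTxt, sep = "\t"),
             paste("Overall quality", qTxt, panel@overallRank,
                   sprintf("%.4f", panel@overallQ), sep = "\t"))
  writeLines(lines, tsv)
  html <- file.path(outDir, paste0(prefix, "-stats.html"))
  writeLines(reportHTML(e, valTxt, rankTxt, scoreTxt, panel), html)
  invisible(c(tsv = tsv, html = html))
}

reportHTML <- function(e, valTxt, rankTxt, scoreTxt, panel) {
  cellColor <- function(rank) {
    if (is.na(rank) || !(rank %in% names(rankColors))) "#ffffff"
    else rankColors[[rank]]
  }
  rows <- vapply(seq_len(nrow(e)), function(i) {
    col <- cellColor(e$rank[i])
    sprintf(paste0("<tr><td>%s</td><td class=\"num\">%s</td>",
                   "<td style=\"background:%s\">%s</td>",
                   "<td class=\"num\">%s</td></tr>"),
            e$display[i], valTxt[i], col, rankTxt[i], scoreTxt[i])
  }, "")
  qcol <- cellColor(panel@overallRank)
  qrow <- sprintf(paste0("<tr class=\"overall\"><td>Overall quality</td>",
                         "<td class=\"num\">%.4f</td>",
                         "<td style=\"background:%s\">%s</td>",
                         "<td class=\"num\">%.4f</td></tr>"),
                  panel@overallQ, qcol, panel@overallRank,
                  panel@overallQ)
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>Quality metrics</title>",
    "<style>",
    "body{font-family:sans-serif;margin:2em}",
    "table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:4px 10px}",
    "td.num{text-align:right}",
    "tr.overall td{font-weight:bold}",
    "</style></head><body>",
    "<h1>Quality metrics</h1>",
    "<table>",
    "<tr><th>Metric</th><th>Value</th><th>Rank</th><th>Score</th></tr>",
    rows, qrow,
    "</table></body></html>")
}
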
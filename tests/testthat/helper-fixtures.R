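suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## ---- fixture builders -------------------------------------------------

## TagSet from 0-based 5' positions
makeTagSet <- function(chrom, pos0, strand, readLength = 50L,
                       chromSizes = c(chr1 = 1e5, chr2 = 1e5),
                       totalRaw = NULL, totalMapped = NULL) {
  n <- max(length(chrom), length(pos0), length(strand))
  gr <- GRanges(rep_len(chrom, n), IRanges(rep_len(pos0, n) + 1L,
                                           width = 1L),
                strand = rep_len(strand, n))
  gr$readLength <- as.integer(rep_len(readLength, n))
  TagSet(gr,
         totalRaw = if (is.null(totalRaw)) n else totalRaw,
         totalMapped = if (is.null(totalMapped)) n else totalMapped,
         chromSizes = chromSizes)
}

## random non-degenerate interval set (1-based GRanges) on small genome
randomIntervals <- function(n, chromSizes = c(chr1 = 1e5, chr2 = 1e5),
                            maxWidth = 2000L) {
  ci <- sample.int(length(chromSizes), n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  s0 <- floor(runif(n) * (chromSizes[ci] - w))
  gr <- GRanges(names(chromSizes)[ci], IRanges(s0 + 1L, width = w))
  gr$name <- paste0("iv", seq_len(n))
  gr$score <- round(runif(n) * 100)
  gr
}

randomTagSet <- function(nTags, chromSizes = c(chr1 = 1e5, chr2 = 1e5),
                         dupFrac = 0.2) {
  ci <- sample.int(length(chromSizes), nTags, replace = TRUE)
  pos0 <- floor(runif(nTags) * (chromSizes[ci] - 100))
  std <- sample(c("+", "-"), nTags, replace = TRUE)
  ndup <- round(nTags * dupFrac)
  if (ndup > 0) {
    pick <- sample.int(nTags, ndup, replace = TRUE)
    ci <- c(ci, ci[pick]); pos0 <- c(pos0, pos0[pick])
    std <- c(std, std[pick])
  }
  makeTagSet(names(chromSizes)[ci], pos0, std, chromSizes = chromSizes)
}

## the 50-peak toy set used by enrichment fixtures
toyPeaks <- function(chromSizes = c(chr1 = 1e6, chr2 = 1e6),
                     width = 1000L, nPerChrom = 25L) {
  st <- rep(seq(10000, 900000, length.out = nPerChrom), 2)
  GRanges(rep(names(chromSizes), each = nPerChrom),
          IRanges(start = st, width = width))
}

## ---- independent brute-force oracles ----------------------------------

## NRF / PBC by an explicit key -> count dictionary built with a loop
oracleKeyCounts <- function(ts) {
  gr <- tags(ts)
  env <- new.env(parent = emptyenv())
  for (i in seq_along(gr)) {
    k <- paste(as.character(seqnames(gr))[i], start(gr)[i] - 1L,
               as.character(strand(gr))[i])
    env[[k]] <- (if (is.null(env[[k]])) 0L else env[[k]]) + 1L
  }
  counts <- unlist(as.list(env))
  list(distinct = length(counts), singleton = sum(counts == 1L),
       total = length(gr))
}

oracleNRF <- function(ts) {
  kc <- oracleKeyCounts(ts)
  kc$distinct / totalMapped(ts)
}

oraclePBC <- function(ts) {
  kc <- oracleKeyCounts(ts)
  kc$singleton / kc$distinct
}

## point-in-interval scan: is 0-based pos inside any [s0, e0) interval?
oracleInAny <- function(chrom, pos0, ivChrom, ivS0, ivE0) {
  for (j in seq_along(ivChrom)) {
    if (chrom == ivChrom[j] && pos0 >= ivS0[j] && pos0 < ivE0[j])
      return(TRUE)
  }
  FALSE
}

oracleBlacklistKeep <- function(ts, blacklist) {
  gr <- tags(ts)
  bc <- as.character(seqnames(blacklist))
  bs0 <- start(blacklist) - 1L
  be0 <- end(blacklist)
  keep <- logical(length(gr))
  for (i in seq_along(gr)) {
    keep[i] <- !oracleInAny(as.character(seqnames(gr))[i],
                            start(gr)[i] - 1L, bc, bs0, be0)
  }
  keep
}

oracleFRiP <- function(ts, peaks) {
  gr <- tags(ts)
  if (!length(gr)) return(NA_real_)
  if (!length(peaks)) return(0)
  pc <- as.character(seqnames(peaks))
  ps0 <- start(peaks) - 1L
  pe0 <- end(peaks)
  hits <- 0L
  for (i in seq_along(gr)) {
    if (oracleInAny(as.character(seqnames(gr))[i], start(gr)[i] - 1L,
                    pc, ps0, pe0))
      hits <- hits + 1L
  }
  hits / length(gr)
}

## all-pairs >=1 bp overlap test on 0-based half-open intervals
oracleOverlapAny <- function(aC, aS0, aE0, bC, bS0, bE0) {
  out <- logical(length(aC))
  for (i in seq_along(aC)) {
    for (j in seq_along(bC)) {
      if (aC[i] == bC[j] && aS0[i] < bE0[j] && bS0[j] < aE0[i]) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

## union-find stitcher: merge peaks whose gap <= gap bp, return for each
## peak a component id, plus component spans
oracleStitch <- function(peaks, gap) {
  n <- length(peaks)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  pc <- as.character(seqnames(peaks))
  s0 <- start(peaks) - 1L
  e0 <- end(peaks)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || pc[i] != pc[j]) next
      g <- max(s0[j] - e0[i], s0[i] - e0[j])
      overlap <- s0[i] < e0[j] && s0[j] < e0[i]
      if (overlap || g <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  ids <- unique(comp)
  spans <- do.call(rbind, lapply(ids, function(k) {
    m <- comp == k
    data.frame(chrom = pc[which(m)[1]], s0 = min(s0[m]), e0 = max(e0[m]),
               members = sum(m))
  }))
  spans[order(spans$chrom, spans$s0), ]
}

## per-peak category by precedence, via explicit interval arithmetic
oracleAnnotate <- function(peaks, genes, promoterHalf, windowHalf) {
  pc <- as.character(seqnames(peaks)); ps0 <- start(peaks) - 1L
  pe0 <- end(peaks)
  gc <- as.character(seqnames(genes)); gs0 <- start(genes) - 1L
  ge0 <- end(genes)
  minus <- as.character(strand(genes)) == "-"
  tss0 <- ifelse(minus, ge0 - 1L, gs0)
  out <- character(length(peaks))
  for (i in seq_along(peaks)) {
    cat_i <- "intergenic"
    for (j in seq_along(genes)) {
      if (pc[i] != gc[j]) next
      ovl <- function(s0, e0) ps0[i] < e0 && s0 < pe0[i]
      if (ovl(tss0[j] - promoterHalf, tss0[j] + promoterHalf)) {
        cat_i <- "promoter"
        break
      }
    }
    if (cat_i == "intergenic") for (j in seq_along(genes)) {
      if (pc[i] == gc[j] && ps0[i] < ge0[j] && gs0[j] < pe0[i]) {
        cat_i <- "gene_body"
        break
      }
    }
    if (cat_i == "intergenic") for (j in seq_along(genes)) {
      if (pc[i] == gc[j] && ps0[i] < ge0[j] + windowHalf &&
          gs0[j] - windowHalf < pe0[i]) {
        cat_i <- "gene_centric_window"
        break
      }
    }
    out[i] <- cat_i
  }
  out
}
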
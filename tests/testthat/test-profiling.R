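mkGene <- function(chrom, start1, end1, strand, id = "g1") {
  g <- GRanges(chrom, IRanges(start1, end1), strand = strand)
  g$gene_id <- id
  g
}

test_that("uniform tags give an exactly flat promoter profile", {
  ## one tag at every 10th base: every 50 bp bin holds exactly 5 tags
  ts <- makeTagSet("chr1", seq(0, 99990, by = 10), "+",
                   chromSizes = c(chr1 = 1e5))
  g <- mkGene("chr1", 50001, 60000, "+")
  cm <- promoterMatrix(ts, g, halfWindow = 2000, bin = 50)
  v <- cm@values[1, ]
  expect_equal(length(v), 80)
  expect_true(all(v == v[1]))
  expect_gt(v[1], 0)
})

test_that("a TSS point mass lands in the centre bin, strand-aware", {
  cs <- c(chr1 = 1e5)
  gPlus <- mkGene("chr1", 50001, 60000, "+")
  ## all tags exactly at the TSS (0-based 50000)
  ts <- makeTagSet("chr1", rep(50000, 20), "+", chromSizes = cs)
  cm <- promoterMatrix(ts, gPlus, halfWindow = 2000, bin = 50)
  nz <- which(cm@values[1, ] > 0)
  expect_equal(nz, 41L)  # first bin of the downstream half
  ## minus-strand gene with tags 100 bp downstream of its TSS
  gMinus <- mkGene("chr1", 40001, 50000, "-")   # TSS 0-based 49999
  tsM <- makeTagSet("chr1", rep(49899, 20), "+", chromSizes = cs)
  cmM <- promoterMatrix(tsM, gMinus, halfWindow = 2000, bin = 50)
  ## mirrored plus gene: tags 100 bp downstream of TSS 50000
  tsP <- makeTagSet("chr1", rep(50100, 20), "+", chromSizes = cs)
  cmP <- promoterMatrix(tsP, gPlus, halfWindow = 2000, bin = 50)
  expect_equal(which(cmM@values[1, ] > 0), which(cmP@values[1, ] > 0))
})

test_that("window bins off the chromosome are NA, truncated bins scaled", {
  ts <- makeTagSet("chr1", seq(0, 9990, by = 10), "+",
                   chromSizes = c(chr1 = 1e4))
  g <- mkGene("chr1", 501, 2000, "+")   # window [“-1500”, 2500)
  cm <- promoterMatrix(ts, g, halfWindow = 2000, bin = 50)
  v <- cm@values[1, ]
  expect_true(all(is.na(v[1:30])))      # fully off-chromosome
  expect_false(any(is.na(v[31:80])))
  expect_equal(v[31], v[40])            # truncated side still per-bp fair
})

test_that("fragment extension spreads a point mass over adjacent bins", {
  cs <- c(chr1 = 1e5)
  g <- mkGene("chr1", 50001, 60000, "+")
  ts <- makeTagSet("chr1", rep(50000, 10), "+", chromSizes = cs)
  cm <- promoterMatrix(ts, g, halfWindow = 2000, bin = 50, fragLen = 150)
  nz <- which(cm@values[1, ] > 0)
  expect_equal(nz, 41:43)  # 150 bp fragment covers three 50 bp bins
  ## minus-strand tags extend leftwards
  tsM <- makeTagSet("chr1", rep(50000, 10), "-", chromSizes = cs)
  cmM <- promoterMatrix(tsM, g, halfWindow = 2000, bin = 50,
                        fragLen = 150)
  expect_equal(which(cmM@values[1, ] > 0), 38:41)
})

test_that("metagene profiles are flat under uniform coverage and
          length-fair", {
  cs <- c(chr1 = 2e5)
  ts <- makeTagSet("chr1", seq(0, 199995, by = 5), "+", chromSizes = cs)
  gShort <- mkGene("chr1", 50001, 60000, "+", "short")
  gLong <- mkGene("chr1", 100001, 120000, "+", "long")
  cm <- metageneMatrix(ts, c(gShort, gLong), bodyBins = 100,
                       flank = 2000, flankBin = 50)
  v <- cm@values
  ## uniform 1-per-5-bp tags: every per-bp density identical
  expect_equal(max(v, na.rm = TRUE) / min(v, na.rm = TRUE), 1,
               tolerance = 1e-9)
  ## doubling gene length leaves per-bp body densities unchanged
  expect_equal(v["short", 41:140], v["long", 41:140])
})

test_that("tags confined to gene bodies leave flanks empty", {
  cs <- c(chr1 = 1e5)
  g <- mkGene("chr1", 40001, 60000, "+")
  ts <- makeTagSet("chr1", seq(40500, 59500, by = 20), "+",
                   chromSizes = cs)
  cm <- metageneMatrix(ts, g, bodyBins = 50, flank = 1000,
                       flankBin = 50)
  v <- cm@values[1, ]
  expect_true(all(v[1:20] == 0))
  expect_true(all(v[71:90] == 0))
  expect_true(any(v[21:70] > 0))
})

test_that("short genes are skipped with a warning", {
  cs <- c(chr1 = 1e5)
  gs <- c(mkGene("chr1", 1001, 1050, "+", "tiny"),
          mkGene("chr1", 50001, 60000, "+", "ok"))
  ts <- makeTagSet("chr1", seq(0, 99990, by = 10), "+", chromSizes = cs)
  expect_warning(cm <- metageneMatrix(ts, gs, bodyBins = 100),
                 "skipped")
  expect_equal(rownames(cm@values), "ok")
})

test_that("average profile is the column mean with NA exclusion", {
  m <- new("CoverageMatrix",
           values = matrix(c(0, 2, 2, 0), 2, 2),
           bins = data.frame(label = c("b1", "b2"), type = "window",
                             width = 50))
  expect_equal(averageProfile(m), c(1, 1))
  single <- new("CoverageMatrix",
                values = matrix(c(3, 7), 1, 2),
                bins = data.frame(label = c("b1", "b2"),
                                  type = "window", width = 50))
  expect_equal(averageProfile(single), c(3, 7))
  naM <- new("CoverageMatrix",
             values = matrix(c(NA, 2, 4, 6), 2, 2),
             bins = data.frame(label = c("b1", "b2"), type = "window",
                               width = 50))
  expect_equal(averageProfile(naM), c(2, 5))
  empty <- new("CoverageMatrix",
               values = matrix(numeric(), 0, 2),
               bins = data.frame(label = c("b1", "b2"),
                                 type = "window", width = 50))
  expect_error(averageProfile(empty), "empty")
})

test_that("TSS-enriched simulations peak at the centre of the mean
          profile", {
  set.seed(111)
  genes <- simulateAnnotation(10, chromSizes = c(chr1 = 1e6,
                                                 chr2 = 1e6),
                              seed = 112)
  tssPk <- GRanges(seqnames(genes),
                   IRanges(geneTSS(genes) - 100, geneTSS(genes) + 100))
  sim <- simulateTags(peaks = tssPk, fripTarget = 0.8,
                      fragmentLength = 150, nFragments = 20000,
                      seed = 113)
  d <- removeDuplicates(sim$tags)$tags
  cm <- promoterMatrix(d, genes, halfWindow = 2000, bin = 50)
  prof <- averageProfile(cm)
  centre <- which.max(prof)
  expect_true(abs(centre - 40.5) < 6)
})

test_that("mirroring every coordinate and strand leaves rows unchanged", {
  set.seed(121)
  N <- 1e5
  cs <- c(chr1 = N)
  pos0 <- sample(0:(N - 1), 3000)
  std <- sample(c("+", "-"), 3000, replace = TRUE)
  ts <- makeTagSet("chr1", pos0, std, chromSizes = cs)
  g <- mkGene("chr1", 40001, 60000, "+")
  ## mirror: 0-based position p -> N - 1 - p, strands flipped
  mPos0 <- N - 1 - pos0
  mStd <- ifelse(std == "+", "-", "+")
  tsM <- makeTagSet("chr1", mPos0, mStd, chromSizes = cs)
  gM <- mkGene("chr1", N - 60000 + 1, N - 40001 + 1, "-")
  cm <- promoterMatrix(ts, g, halfWindow = 2000, bin = 50)
  cmM <- promoterMatrix(tsM, gM, halfWindow = 2000, bin = 50)
  expect_equal(cmM@values[1, ], cm@values[1, ])
  mm <- metageneMatrix(ts, g, bodyBins = 50, flank = 2000,
                       flankBin = 50)
  mmM <- metageneMatrix(tsM, gM, bodyBins = 50, flank = 2000,
                        flankBin = 50)
  expect_equal(mmM@values[1, ], mm@values[1, ])
})

test_that("promoter-bin tag totals conserve the tag count on a tiling", {
  set.seed(122)
  cs <- c(chr1 = 1e4)
  pos0 <- sample(0:9999, 2000, replace = TRUE)
  ts <- makeTagSet("chr1", pos0, "+", chromSizes = cs)
  ## windows [0,4000) and [4000,8000) and [8000,10000+2000): genes with
  ## TSS at 2000, 6000, 10000 tile the chromosome with halfWindow 2000
  gs <- c(mkGene("chr1", 2001, 3000, "+", "a"),
          mkGene("chr1", 6001, 7000, "+", "b"),
          mkGene("chr1", 10001, 11000, "+", "c"))
  cm <- promoterMatrix(ts, gs, halfWindow = 2000, bin = 50)
  ## densities back to counts: density * width * total / 1e6
  widths <- ifelse(is.na(cm@values), 0, 50)
  counts <- cm@values * widths * length(tags(ts)) / 1e6
  ## window "c" sticks out past the chromosome end: NA bins drop, so the
  ## recovered total never exceeds and here equals the tag count
  expect_equal(sum(counts, na.rm = TRUE), 2000)
})

test_that("peak annotation follows the precedence rules", {
  gs <- c(mkGene("chr1", 10001, 30000, "+", "gA"),
          mkGene("chr1", 60001, 80000, "-", "gB"))
  ## overlapping the promoter window of gA ([9000,11000) 0-based)
  pkProm <- GRanges("chr1", IRanges(9501, 9800))
  ## inside gA's body, outside its promoter
  pkBody <- GRanges("chr1", IRanges(15001, 15500))
  ## within 10 kb of gA's body, in no body or promoter
  pkWin <- GRanges("chr1", IRanges(35001, 35500))
  ## far from everything
  pkInter <- GRanges("chr1", IRanges(48001, 48500))
  ad <- annotatePeaks(c(pkProm, pkBody, pkWin, pkInter), gs)
  expect_equal(as.vector(ad@perPeak$category),
               c("promoter", "gene_body", "gene_centric_window",
                 "intergenic"))
  expect_equal(sum(ad@counts), 4L)
  ## nearest gene and signed distance; 0 when the peak covers the TSS
  pkOnTSS <- GRanges("chr1", IRanges(9951, 10150))
  adT <- annotatePeaks(pkOnTSS, gs)
  expect_equal(adT@perPeak$distance, 0)
  expect_equal(as.vector(adT@perPeak$nearestGene), "gA")
  adB <- annotatePeaks(pkBody, gs)
  ## midpoint 0-based (15000+15500)/2 = 15250; TSS gA at 10000
  expect_equal(adB@perPeak$distance, 15250 - 10000)
})

test_that("annotation matches the all-pairs oracle and counts sum", {
  set.seed(131)
  for (i in 1:5) {
    genes <- simulateAnnotation(10, chromSizes = c(chr1 = 1e6,
                                                   chr2 = 1e6),
                                seed = 131 + i)
    peaks <- randomIntervals(50, chromSizes = c(chr1 = 1e6,
                                                chr2 = 1e6),
                             maxWidth = 5000)
    ad <- annotatePeaks(peaks, genes, promoterHalf = 1000,
                        windowHalf = 10000)
    oc <- oracleAnnotate(peaks, genes, 1000, 10000)
    expect_equal(as.vector(ad@perPeak$category), oc)
    expect_equal(sum(ad@counts), length(peaks))
    tab <- annotationTable(ad)
    expect_equal(sum(tab$count), 50L)
    expect_equal(sum(tab$fraction), 1)
  }
})
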
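## a strictly positive unimodal cc curve over the default grid, with a
## fragment peak and a phantom bump, for constructed-profile tests
makeCC <- function(shifts, bg, peaks) {
  cc <- rep(bg, length(shifts))
  for (p in peaks)
    cc <- pmax(cc, p$h * exp(-((shifts - p$at) / p$w)^2))
  cc
}

test_that("identical plus/minus occupancy gives cc(0) = 1", {
  set.seed(71)
  pos <- sample(600:9000, 400)
  ts <- makeTagSet("chr1", c(pos, pos), rep(c("+", "-"), each = 400),
                   chromSizes = c(chr1 = 1e4))
  prof <- suppressWarnings(
    strandCrossCorrelation(ts, shiftRange = c(0, 600), step = 5,
                           minTagsPerChrom = 100))
  expect_equal(prof@cc[prof@shifts == 0], 1, tolerance = 1e-12)
})

test_that("independent uniform strands give near-zero correlation", {
  ts <- simulateNullTags(chromSizes = c(chr1 = 5e5),
                         nTagsPerStrand = 20000, seed = 72)
  prof <- strandCrossCorrelation(ts)
  expect_true(all(abs(prof@cc) < 0.05))
})

test_that("fragment-length simulations put the peak at the fragment size", {
  pks <- toyPeaks()
  sim <- simulateTags(peaks = pks, fripTarget = 0.3,
                      fragmentLength = 150, nFragments = 30000,
                      seed = 73)
  d <- removeDuplicates(sim$tags)$tags
  prof <- strandCrossCorrelation(d)
  expect_lte(abs(estimateFragmentWidth(prof) - 150), 5)
  expect_gt(computeNSC(prof), 1)
})

test_that("fragment estimation skips the phantom window", {
  shifts <- seq(0, 500, 5)
  ## global max at 76 (phantom), secondary at 180
  cc <- makeCC(shifts, 0.02,
               list(list(at = 76, h = 0.3, w = 8),
                    list(at = 180, h = 0.2, w = 30)))
  prof <- xcorProfileFromCC(shifts, cc, meanReadLength = 76)
  expect_equal(estimateFragmentWidth(prof), 180)
  expect_equal(predictedTagLength(prof), 75)  # grid point nearest 76
  ## monotone decreasing curve: smallest non-excluded shift wins
  cc2 <- seq(0.5, 0.1, length.out = length(shifts))
  prof2 <- xcorProfileFromCC(shifts, cc2, meanReadLength = 76)
  expect_equal(estimateFragmentWidth(prof2), 0)
})

test_that("tag-length deviation E measures phantom vs read length", {
  shifts <- seq(0, 500, 5)
  cc <- makeCC(shifts, 0.02,
               list(list(at = 75, h = 0.25, w = 6),
                    list(at = 200, h = 0.35, w = 30)))
  prof <- xcorProfileFromCC(shifts, cc, meanReadLength = 75)
  expect_equal(predictedTagLength(prof), 75)
  expect_equal(tagLengthDelta(prof), 0)
  ## phantom at 80, mean read length 76 -> E = 4 (within +/-10)
  cc2 <- makeCC(shifts, 0.02,
                list(list(at = 80, h = 0.25, w = 4),
                     list(at = 200, h = 0.35, w = 30)))
  prof2 <- xcorProfileFromCC(shifts, cc2, meanReadLength = 76)
  expect_equal(tagLengthDelta(prof2), abs(80 - 76))
  ## E arithmetic on an explicitly constructed profile: 100 vs 76 -> 24
  prof3 <- new("XcorProfile", shifts = as.integer(shifts),
               cc = makeCC(shifts, 0.02, list()), ccBackground = 0.02,
               ccFragment = 0.02, ccReadlen = 0.02,
               fragmentWidth = 200, predictedTagLength = 100,
               meanReadLength = 76)
  expect_equal(tagLengthDelta(prof3), 24)
})

test_that("NSC and RSC are the documented ratios", {
  shifts <- seq(0, 500, 5)
  mkProf <- function(bg, frag, readlen) {
    new("XcorProfile", shifts = as.integer(shifts),
        cc = pmin(pmax(makeCC(shifts, bg, list(
          list(at = 150, h = frag, w = 20),
          list(at = 75, h = readlen, w = 6))), bg), 1),
        ccBackground = bg, ccFragment = frag, ccReadlen = readlen,
        fragmentWidth = 150, predictedTagLength = 75,
        meanReadLength = 75)
  }
  p1 <- mkProf(0.200, 0.209, 0.205)
  expect_equal(computeNSC(p1), 0.209 / 0.200)
  ## flat profile: no enrichment, NSC = 1
  flat <- xcorProfileFromCC(shifts, rep(0.1, length(shifts)),
                            meanReadLength = 75)
  expect_equal(computeNSC(flat), 1)
  p2 <- mkProf(0.1, 0.4, 0.2)
  expect_equal(computeNSC(p2), 4)
  expect_equal(computeRSC(p2), (0.4 - 0.1) / (0.2 - 0.1))
  ## fragment cc equal to phantom cc -> RSC = 1
  p3 <- mkProf(0.1, 0.3, 0.3)
  expect_equal(computeRSC(p3), 1)
  ## fragment cc at background -> RSC = 0
  p4 <- mkProf(0.1, 0.1, 0.3)
  expect_equal(computeRSC(p4), 0)
  ## undefined cases: a non-positive background leaves NSC undefined
  ccNeg <- makeCC(shifts, 0.05, list(list(at = 150, h = 0.3, w = 20)))
  ccNeg[length(ccNeg)] <- -0.02
  expect_true(is.na(computeNSC(xcorProfileFromCC(
    shifts, ccNeg, meanReadLength = 75))))
  expect_true(is.na(computeRSC(mkProf(0.1, 0.2, 0.1))))
})

test_that("NSC is at least 1 whenever the background is positive", {
  set.seed(81)
  shifts <- seq(0, 500, 5)
  for (i in 1:20) {
    cc <- runif(length(shifts), 0.01, 0.5)
    prof <- xcorProfileFromCC(shifts, cc, meanReadLength = 75)
    expect_gte(computeNSC(prof), 1)
  }
})

test_that("cc is invariant to chromosome labels and empty chromosomes", {
  set.seed(82)
  pos <- sample(1000:90000, 2000)
  std <- sample(c("+", "-"), 2000, replace = TRUE)
  ts1 <- makeTagSet("chr1", pos, std, chromSizes = c(chr1 = 1e5))
  ts2 <- makeTagSet("chrZ", pos, std, chromSizes = c(chrZ = 1e5))
  p1 <- strandCrossCorrelation(ts1)
  p2 <- strandCrossCorrelation(ts2)
  expect_identical(p1@cc, p2@cc)
  ## adding a tag-free chromosome changes nothing
  ts3 <- makeTagSet("chr1", pos, std,
                    chromSizes = c(chr1 = 1e5, chrEmpty = 5e5))
  expect_identical(strandCrossCorrelation(ts3)@cc, p1@cc)
})

test_that("degenerate inputs error or warn as documented", {
  tsPlus <- makeTagSet("chr1", 1:300, "+")
  expect_error(strandCrossCorrelation(tsPlus), "both strands")
  ## chromosome shorter than the maximum shift is skipped with a warning
  tsShort <- makeTagSet("chr1", rep(1:150, 2),
                        rep(c("+", "-"), each = 150),
                        chromSizes = c(chr1 = 400))
  expect_warning(expect_error(strandCrossCorrelation(tsShort),
                              "enough tags"),
                 "skipped")
})
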
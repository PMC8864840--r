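Package: chromaQC
Title: Quality-Metric Panel and Rank-Flag Dashboard for Chromatin
    Occupancy Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the quality-control metric panel for ChIP-seq and
    CUT&RUN experiments from standard alignment, peak, and annotation
    files: library metrics (raw reads, aligned percent, non-redundant
    fraction, PCR bottleneck coefficient, per-base quality and sequence
    diversity flags), strand cross-correlation analysis (fragment-width
    and tag-length estimation, NSC, RSC), fraction of reads in peaks,
    ROSE-style stitched-region and super-enhancer-like region calling
    with an inflection-point cutoff, promoter and metagene coverage
    profiling, and peak annotation distribution. Every metric is
    classified on a five-level color-rank scale, averaged into an
    overall quality score, and exported as a tab-delimited table and a
    self-contained color-flagged HTML report. A seeded synthetic-data
    generator emits alignment, peak, gene, blacklist, and FASTQ
    fixtures with exact ground-truth tallies for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: QualityControl, ChIPSeq, Sequencing, Coverage
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chromaQC-package.R'
    'utils.R'
    'enrichment.R'
    'io.R'
    'libraryMetrics.R'
    'xcor.R'
    'readProcessing.R'
    'pipeline.R'
    'profiling.R'
    'rankDashboard.R'
    'simulate.R'
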
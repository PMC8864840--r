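## Internal helpers shared across modules.

## Run an expression under a private RNG stream so callers never touch the
## global random state. Everything stochastic in the package funnels
## through here with an explicit seed.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## 0-based 5' position of each tag (plus strand: leftmost base; minus
## strand: rightmost base). Tags are stored as width-1 GRanges at the 5'
## base, so this is just start - 1.
tagPos5 <- function(gr) start(gr) - 1L

## Open a text connection, transparently handling gzip by extension.
openText <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

isTRUEish <- function(x) isTRUE(as.logical(x))

## Duplicate key of a tag: chromosome, 0-based 5' position, strand.
tagKeys <- function(gr) {
  paste(as.character(seqnames(gr)), tagPos5(gr), as.character(strand(gr)),
        sep = ":")
}

## Strand-aware TSS (1-based): start for +, end for -.
tssPositions <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}
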
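## Internal helpers shared across modules.

## Evaluate expr under a local RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so simulator stages are independently
## reproducible.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## 0-based half-open substring of one chromosome of a DNAStringSet genome.
## Errors when the chromosome is absent or the window leaves the sequence.
getSeq0 <- function(genome, chrom, start0, end0) {
  if (!chrom %in% names(genome))
    stop("no genome sequence for chromosome '", chrom, "'")
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (start0 < 0 || end0 > len || end0 < start0)
    stop(sprintf("window [%d, %d) outside %s (length %d)",
                 start0, end0, chrom, len))
  as.character(Biostrings::subseq(genome[[chrom]], start0 + 1L, end0))
}

genomeSeqlengths <- function(genome) {
  if (is.numeric(genome)) return(genome)
  stats::setNames(Biostrings::width(genome), names(genome))
}

## locus identity key used for exact-coordinate set operations
lociKeys <- function(x) {
  paste(as.character(seqnames(x)), start(x), end(x), sep = ":")
}
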
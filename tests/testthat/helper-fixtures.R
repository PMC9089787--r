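## Fixture builders shared across test files. Everything is generated in
## code; nothing is read from disk except files the tests write themselves.

## a deterministic single-chromosome genome
tinyGenome <- function(len = 20000L, seed = 101L, name = "chrT") {
  g <- withr_seed(seed, {
    Biostrings::DNAStringSet(
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""))
  })
  names(g) <- name
  g
}

## seed-scoped evaluation without depending on withr
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

seq0 <- function(genome, chrom, s0, e0)
  as.character(Biostrings::subseq(genome[[chrom]], s0 + 1L, e0))

## write a SAM file from a data.frame of records (0-based pos/pnext)
writeSam <- function(records, seqlens, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  body <- if (nrow(records)) {
    ord <- order(match(records$rname, names(seqlens)), records$pos)
    r <- records[ord, ]
    paste(r$qname, r$flag, r$rname, r$pos + 1L, r$mapq, r$cigar,
          r$rnext, r$pnext + 1L, r$tlen, r$seq,
          vapply(nchar(r$seq), function(n) strrep("I", n), ""),
          sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  path
}

samRecord <- function(qname, flag, rname, pos, cigar, seq, mapq = 60L,
                      rnext = "=", pnext = 0L, tlen = 0L) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
             tlen = tlen, seq = seq)
}

## a junction-spanning read for circle [s0, e0) on `genome`: o bases before
## the junction, readLen - o after; returns an aligner-style SAM record
junctionRead <- function(genome, chrom, s0, e0, o, readLen = 75L,
                         qname = "jr1") {
  stopifnot(o < readLen)
  seq <- paste0(seq0(genome, chrom, e0 - o, e0),
                seq0(genome, chrom, s0, s0 + readLen - o))
  if (o >= readLen - o)
    samRecord(qname, 0L, chrom, e0 - o, sprintf("%dM%dS", o, readLen - o), seq)
  else
    samRecord(qname, 0L, chrom, s0, sprintf("%dS%dM", o, readLen - o), seq)
}

lociKeySet <- function(x)
  paste(as.character(seqnames(x)), start(x) - 1L, end(x), sep = ":")

## score a called set against a truth GRanges at exact coordinates
scoreCalls <- function(called, truth) {
  ck <- unique(lociKeySet(called))
  tk <- unique(lociKeySet(truth))
  list(recall = mean(tk %in% ck), precision = mean(ck %in% tk))
}

## per-molecule fragment table: one full-length read per record interval,
## sequence taken from the given haplotype genome (used by partition tests)
moleculeFragments <- function(records, genomeByHap, haplotype) {
  n <- length(records)
  ids <- sprintf("mol%06d", seq_len(n))
  chrom <- as.character(seqnames(records))
  s0 <- start(records) - 1L
  e0 <- end(records)
  seqs <- character(n)
  for (h in unique(haplotype)) {
    ix <- which(haplotype == h)
    g <- genomeByHap[[h]]
    for (ch in unique(chrom[ix])) {
      jx <- ix[chrom[ix] == ch]
      seqs[jx] <- as.character(Biostrings::extractAt(
        g[[ch]], IRanges::IRanges(start = s0[jx] + 1L, end = e0[jx])))
    }
  }
  DataFrame(read_id = ids, flag = 0L, chrom = chrom, pos = s0,
            mapq = 60L, cigar = sprintf("%dM", e0 - s0), seq = seqs,
            strand = "+", mate_chrom = chrom, mate_pos = s0,
            tlen = 0L, is_first = TRUE, is_paired = FALSE,
            is_proper = FALSE)
}
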
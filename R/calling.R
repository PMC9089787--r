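#' Extract junction signals from aligned fragments
#'
#' Scans primary alignments for the two evidence types of a circle
#' junction:
#' \itemize{
#'   \item \emph{split_read} — a read with a soft-clipped prefix or suffix of
#'     at least \code{minSoftclip} bases whose clipped sequence realigns by
#'     exact match, on the same chromosome and strand, at the opposite
#'     boundary so that the read layout is consistent with traversing the
#'     junction (sequence runs off the circle end and continues from the
#'     circle start). This pins both breakpoints at base resolution.
#'   \item \emph{outward_pair} — both mates map to the same chromosome in
#'     outward-facing orientation (leftmost mate reverse strand, rightmost
#'     forward) with an implied circle size inside
#'     \code{[minSize, maxSize]}. Outward pairs only bracket the
#'     breakpoints.
#' }
#' Clipped sequences with two or more exact placements in the search window
#' (candidate breakpoint +/- 1 kb, extended by \code{maxSize} on the side
#' where the partner breakpoint may lie) are ambiguous: the signal is
#' dropped and counted in the diagnostics tally, as are placements
#' inconsistent with a circle layout.
#'
#' @param fragments \code{DataFrame} from \code{\link{readAlignments}};
#'   fragments of one sample, coordinate-sorted.
#' @param genome named \code{DNAStringSet} (reference sequences).
#' @param cfg a \linkS4class{CallerConfig}.
#' @return data.frame with columns \code{chrom}, \code{left_bp} (0-based
#'   circle start), \code{right_bp} (0-based exclusive circle end),
#'   \code{evidence}, \code{read_id}; attribute \code{"diagnostics"} holds
#'   the \code{ambiguous} and \code{inconsistent} drop tallies.
#' @export
extractJunctionSignals <- function(fragments, genome, cfg = callerConfig()) {
  stopifnot(is(cfg, "CallerConfig"))
  empty <- data.frame(chrom = character(), left_bp = integer(),
                      right_bp = integer(), evidence = character(),
                      read_id = character())
  diag <- c(ambiguous = 0L, inconsistent = 0L)
  if (nrow(fragments) == 0L) {
    attr(empty, "diagnostics") <- diag
    return(empty)
  }
  fragments <- fragments[fragments$mapq >= cfg@mapqMin, , drop = FALSE]
  seqlens <- genomeSeqlengths(genome)
  miss <- setdiff(unique(fragments$chrom), names(seqlens))
  if (length(miss))
    stop("missing genome sequence for chromosome(s): ",
         paste(miss, collapse = ", "))

  cig <- fragments$cigar
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  firstOp <- vapply(ops, function(o) if (length(o)) o[1] else "", "")
  lastOp  <- vapply(ops, function(o) if (length(o)) o[length(o)] else "", "")
  firstLen <- vapply(lens, function(l) if (length(l)) l[1] else 0L, 0L)
  lastLen  <- vapply(lens, function(l) if (length(l)) l[length(l)] else 0L, 0L)
  clipL <- ifelse(firstOp == "S", firstLen, 0L)
  clipR <- ifelse(lastOp == "S", lastLen, 0L)
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)

  sig <- vector("list", 256L); nsig <- 0L
  addSig <- function(chrom, left, right, evidence, read_id) {
    nsig <<- nsig + 1L
    if (nsig > length(sig)) length(sig) <<- 2L * nsig
    sig[[nsig]] <<- list(chrom, as.integer(left), as.integer(right),
                         evidence, read_id)
  }

  ## split-read evidence: realign qualifying soft clips
  cand <- which(clipL >= cfg@minSoftclip | clipR >= cfg@minSoftclip)
  for (i in cand) {
    chrom <- fragments$chrom[i]
    len <- seqlens[[chrom]]
    subject <- genome[[chrom]]
    pos0 <- fragments$pos[i]
    refEnd0 <- pos0 + refw[i]
    rseq <- fragments$seq[i]
    nch <- nchar(rseq)
    if (clipR[i] >= cfg@minSoftclip) {
      ## suffix clip: matched block ends at the candidate circle end;
      ## clipped sequence should match at the circle start, left of it
      clip <- substr(rseq, nch - clipR[i] + 1L, nch)
      w0 <- max(0L, refEnd0 - cfg@maxSize - 1000L)
      w1 <- min(len, refEnd0 + 1000L)
      hits <- w0 + Biostrings::start(
        Biostrings::matchPattern(clip, Biostrings::subseq(subject, w0 + 1L, w1),
                                 fixed = TRUE)) - 1L
      if (length(hits) > 1L) diag["ambiguous"] <- diag["ambiguous"] + 1L
      else if (length(hits) == 1L) {
        if (hits < refEnd0) addSig(chrom, hits, refEnd0, "split_read",
                                   fragments$read_id[i])
        else diag["inconsistent"] <- diag["inconsistent"] + 1L
      }
    }
    if (clipL[i] >= cfg@minSoftclip) {
      ## prefix clip: matched block starts at the candidate circle start;
      ## clipped sequence is the end of the circle and must match so that
      ## its end is the circle end, right of the start
      clip <- substr(rseq, 1L, clipL[i])
      w0 <- max(0L, pos0 - 1000L)
      w1 <- min(len, pos0 + cfg@maxSize + 1000L)
      hits <- w0 + Biostrings::start(
        Biostrings::matchPattern(clip, Biostrings::subseq(subject, w0 + 1L, w1),
                                 fixed = TRUE)) - 1L
      if (length(hits) > 1L) diag["ambiguous"] <- diag["ambiguous"] + 1L
      else if (length(hits) == 1L) {
        rightEnd <- hits + clipL[i]
        if (rightEnd > pos0) addSig(chrom, pos0, rightEnd, "split_read",
                                    fragments$read_id[i])
        else diag["inconsistent"] <- diag["inconsistent"] + 1L
      }
    }
  }

  ## outward-pair evidence: leftmost mate reverse, rightmost forward, same
  ## chromosome; emitted once per pair (from the leftmost record)
  ow <- which(fragments$is_paired &
              fragments$chrom == fragments$mate_chrom &
              !is.na(fragments$tlen) & fragments$tlen > 0L &
              fragments$pos <= fragments$mate_pos &
              fragments$strand == "-" &
              bitwAnd(fragments$flag, 0x20) == 0L)
  for (i in ow) {
    impl <- fragments$tlen[i]
    if (impl >= cfg@minSize && impl <= cfg@maxSize)
      addSig(fragments$chrom[i], fragments$pos[i], fragments$pos[i] + impl,
             "outward_pair", fragments$read_id[i])
  }

  out <- if (nsig == 0L) empty else {
    m <- sig[seq_len(nsig)]
    data.frame(chrom = vapply(m, `[[`, "", 1L),
               left_bp = vapply(m, `[[`, 0L, 2L),
               right_bp = vapply(m, `[[`, 0L, 3L),
               evidence = vapply(m, `[[`, "", 4L),
               read_id = vapply(m, `[[`, "", 5L))
  }
  attr(out, "diagnostics") <- diag
  out
}

#' Call eccDNA loci from junction signals
#'
#' Signals with identical (chrom, left_bp, right_bp) are merged into one
#' locus — one locus is one eccDNA species, the unit counted throughout the
#' analyses. Support is the number of distinct read ids (duplicate fragments
#' never double-count). A locus is kept iff support >= \code{minSupport},
#' its size lies in \code{[minSize, maxSize]}, and (when
#' \code{requireSplit}) it has at least one split-read signal. Output is
#' coordinate-sorted and deterministic for a fixed input ordering.
#'
#' @param signals data.frame from \code{\link{extractJunctionSignals}}.
#' @param cfg a \linkS4class{CallerConfig}.
#' @param sample optional \linkS4class{SampleMeta} supplying sample_id and
#'   genotype labels.
#' @param keepReadIds attach supporting read ids per locus as a
#'   \code{CharacterList} metadata column (needed for origin partitioning).
#' @return an \linkS4class{EccDNASet}.
#' @export
callEccDNA <- function(signals, cfg = callerConfig(), sample = NULL,
                       keepReadIds = TRUE) {
  stopifnot(is(cfg, "CallerConfig"))
  sid <- if (is.null(sample)) "sample" else sample@sampleId
  gt <- if (is.null(sample)) "other" else sample@genotype
  if (nrow(signals) == 0L)
    return(EccDNASet(sample_id = sid, genotype = gt))
  key <- paste(signals$chrom, signals$left_bp, signals$right_bp, sep = ":")
  grp <- split(seq_len(nrow(signals)), key)
  chrom <- vapply(grp, function(ix) signals$chrom[ix[1]], "")
  left <- vapply(grp, function(ix) signals$left_bp[ix[1]], 0L)
  right <- vapply(grp, function(ix) signals$right_bp[ix[1]], 0L)
  support <- vapply(grp, function(ix) length(unique(signals$read_id[ix])), 0L)
  hasSplit <- vapply(grp, function(ix) any(signals$evidence[ix] == "split_read"),
                     NA)
  size <- right - left
  keep <- support >= cfg@minSupport & size >= cfg@minSize &
    size <= cfg@maxSize & (!cfg@requireSplit | hasSplit)
  if (!any(keep)) return(EccDNASet(sample_id = sid, genotype = gt))
  ord <- order(chrom[keep], left[keep], right[keep])
  kix <- which(keep)[ord]
  rec <- EccDNASet(chrom[kix], left[kix], right[kix], support = support[kix],
                   sample_id = sid, genotype = gt)
  if (keepReadIds)
    mcols(rec)$read_ids <- IRanges::CharacterList(
      lapply(grp[kix], function(ix) unique(signals$read_id[ix])))
  rec
}

#' Intersect calls made against two colinear strain genomes
#'
#' Keeps only loci identified under both strain references, by exact
#' (chrom, start, end) match — the dual-genome confirmation step of the
#' pregnancy-model analysis. Synthetic strain genomes are colinear (they
#' differ only at SNP substitutions), so coordinates are directly
#' comparable; real strain assemblies would need liftover, which is out of
#' scope.
#'
#' @param recordsA,recordsB \linkS4class{EccDNASet}s called against the two
#'   strain genomes.
#' @param snps ignored; accepted for interface symmetry with pipelines that
#'   pass the strain SNP table alongside.
#' @return the subset of \code{recordsA} also present in \code{recordsB}.
#' @export
callDualGenome <- function(recordsA, recordsB, snps = NULL) {
  stopifnot(is(recordsA, "EccDNASet"), is(recordsB, "EccDNASet"))
  recordsA[lociKeys(recordsA) %in% lociKeys(recordsB)]
}
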
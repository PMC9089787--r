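## Reference-space layout of aligned fragments: sequences are laid onto the
## reference with GenomicAlignments::sequenceLayer (soft clips removed,
## deletions gap-filled) once for the whole set, so base lookups at SNP
## positions reduce to substring indexing.
layoutFragments <- function(fragments) {
  n <- nrow(fragments)
  if (n == 0L)
    return(list(chrom = character(0), pos = integer(0), refw = integer(0),
                seqc = character(0), read_id = character(0)))
  laid <- GenomicAlignments::sequenceLayer(
    Biostrings::DNAStringSet(fragments$seq), fragments$cigar,
    from = "query", to = "reference")
  list(chrom = as.character(fragments$chrom),
       pos = as.integer(fragments$pos),
       refw = Biostrings::width(laid),
       seqc = as.character(laid),
       read_id = as.character(fragments$read_id))
}

## majority-vote allele evidence for one molecule over the SNPs inside its
## interval; fragIdx indexes the molecule's supporting fragments in `layout`
snpVotes <- function(layout, fragIdx, snpsSub) {
  covered <- 0L; nA <- 0L; nB <- 0L; tie <- FALSE
  for (j in seq_len(nrow(snpsSub))) {
    p <- snpsSub$pos[j]
    off <- p - layout$pos[fragIdx] + 1L
    ok <- fragIdx[off >= 1L & off <= layout$refw[fragIdx] &
                  layout$chrom[fragIdx] == snpsSub$chrom[j]]
    if (!length(ok)) next
    b <- substr(layout$seqc[ok], p - layout$pos[ok] + 1L,
                p - layout$pos[ok] + 1L)
    b <- b[b %in% c("A", "C", "G", "T")]
    if (!length(b)) next
    covered <- covered + 1L
    tab <- sort(table(b), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) { tie <- TRUE; next }
    cons <- names(tab)[1]
    if (cons == snpsSub$allele_B[j]) nB <- nB + 1L
    else if (cons == snpsSub$allele_A[j]) nA <- nA + 1L
    ## consensus matching neither allele (sequencing error): uninformative
  }
  origin <- if (covered == 0L || tie) "unassigned"
  else if (nB >= 1L && nA == 0L) "fetal_specific"
  else if (nA >= 1L && nB == 0L) "shared"
  else "unassigned"
  list(origin = origin, informative_snps_covered = covered,
       n_allele_A = nA, n_allele_B = nB)
}

#' Classify the strain origin of one eccDNA molecule
#'
#' In the pregnancy model the mother is homozygous for strain-A alleles at
#' every informative SNP while the (heterozygous) fetus carries strain B on
#' one haplotype. A molecule is
#' \itemize{
#'   \item \code{fetal_specific} iff at least one covered informative SNP
#'     shows the strain-B allele and no covered SNP contradicts that
#'     assignment;
#'   \item \code{shared} iff at least one covered SNP shows the strain-A
#'     allele and none shows strain B (maternal molecules and the
#'     maternal-haplotype half of fetal molecules are indistinguishable);
#'   \item \code{unassigned} iff no informative SNP is covered, or the
#'     evidence is discordant.
#' }
#' Conflicting base observations at one SNP are resolved by majority vote
#' across the supporting reads; a tied vote makes the molecule unassigned.
#' A single discordant SNP vetoes classification (conservative,
#' deterministic; no probabilistic genotyping). SNP positions outside the
#' record interval are ignored.
#'
#' @param record a length-1 \linkS4class{EccDNASet} (or GRanges) interval.
#' @param fragments supporting reads for this molecule, as a
#'   \code{DataFrame} from \code{\link{readAlignments}}.
#' @param snps strain SNP table from \code{\link{readSnpTable}} (0-based
#'   pos).
#' @return list: \code{origin} label, \code{informative_snps_covered},
#'   \code{n_allele_A}, \code{n_allele_B} (consensus votes).
#' @export
classifyOrigin <- function(record, fragments, snps) {
  chrom <- as.character(seqnames(record))[1]
  s0 <- start(record)[1] - 1L
  e0 <- end(record)[1]
  loc <- snps[snps$chrom == chrom & snps$pos >= s0 & snps$pos < e0, ,
              drop = FALSE]
  if (nrow(loc) == 0L)
    return(list(origin = "unassigned", informative_snps_covered = 0L,
                n_allele_A = 0L, n_allele_B = 0L))
  layout <- layoutFragments(fragments)
  snpVotes(layout, seq_along(layout$pos), loc)
}

#' Assign origin labels to every locus of a called set
#'
#' Applies the \code{\link{classifyOrigin}} rules per locus, using the
#' locus's own supporting reads (the \code{read_ids} column kept by
#' \code{\link{callEccDNA}}); falls back to all fragments overlapping the
#' locus interval when read ids were not kept. Fragments are laid onto
#' reference space once for the whole set.
#'
#' @param records an \linkS4class{EccDNASet}.
#' @param fragments \code{DataFrame} from \code{\link{readAlignments}}.
#' @param snps strain SNP table (0-based pos).
#' @return \code{records} with the \code{origin} column filled and an
#'   evidence data.frame attached as
#'   \code{metadata(records)$origin_evidence}.
#' @export
partitionOrigins <- function(records, fragments, snps) {
  stopifnot(is(records, "EccDNASet"))
  if (!length(records)) return(records)
  layout <- layoutFragments(fragments)
  hasIds <- "read_ids" %in% colnames(mcols(records))
  byId <- split(seq_along(layout$read_id), layout$read_id)
  ## SNP table position-sorted per chromosome for findInterval lookups
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  chromOf <- split(seq_len(nrow(snps)), snps$chrom)
  chromR <- as.character(seqnames(records))
  s0 <- start(records) - 1L
  e0 <- end(records)
  fragEnd <- layout$pos + layout$refw
  orig <- character(length(records))
  cov <- nA <- nB <- integer(length(records))
  readIds <- if (hasIds) mcols(records)$read_ids
  for (i in seq_along(records)) {
    ix <- chromOf[[chromR[i]]]
    loc <- if (is.null(ix)) snps[0, ] else {
      pos <- snps$pos[ix]
      lo <- findInterval(s0[i] - 1L, pos) + 1L
      hi <- findInterval(e0[i] - 1L, pos)
      if (hi >= lo) snps[ix[lo:hi], , drop = FALSE] else snps[0, ]
    }
    if (nrow(loc) == 0L) { orig[i] <- "unassigned"; next }
    fragIdx <- if (hasIds)
      unlist(byId[readIds[[i]]], use.names = FALSE)
    else
      which(layout$chrom == chromR[i] & layout$pos < e0[i] &
            fragEnd > s0[i])
    res <- snpVotes(layout, fragIdx, loc)
    orig[i] <- res$origin
    cov[i] <- res$informative_snps_covered
    nA[i] <- res$n_allele_A
    nB[i] <- res$n_allele_B
  }
  origin(records) <- orig
  metadata(records)$origin_evidence <- data.frame(
    informative_snps_covered = cov, n_allele_A = nA, n_allele_B = nB)
  records
}

#' Fetal fraction from origin-labelled molecule counts
#'
#' The corrected estimator is
#' \code{FF = 100 * 2 * n_fetal_specific / (n_fetal_specific + n_shared)}:
#' with a strain-A homozygous mother and a heterozygous fetus, only half of
#' the fetal molecules carry the paternal (strain-B) allele — the other half
#' are counted among the shared molecules — so the fetal-specific count is
#' doubled. The raw (uncorrected) proportion is available with
#' \code{corrected = FALSE}; summaries should report both.
#'
#' @param nFetalSpecific,nShared molecule counts by origin label.
#' @param corrected apply the factor-2 heterozygous-fetus correction.
#' @return fetal fraction, percent. A fully fetal sample
#'   (\code{nFetalSpecific == nShared}) gives 100 under the corrected
#'   estimator.
#' @export
fetalFraction <- function(nFetalSpecific, nShared, corrected = TRUE) {
  denom <- nFetalSpecific + nShared
  if (denom <= 0) stop("fetal fraction undefined: no classified molecules")
  100 * (if (corrected) 2 else 1) * nFetalSpecific / denom
}

#' Size profiles of fetal-specific vs shared molecules
#'
#' Splits an origin-labelled record set and profiles each subset, for the
#' fetal-vs-maternal size comparison. Unassigned molecules are excluded.
#'
#' @param records origin-labelled \linkS4class{EccDNASet}.
#' @param lo,hi profile range, bp.
#' @return named list of \linkS4class{SizeProfile}s
#'   (\code{fetal_specific}, \code{shared}); empty subsets yield flagged
#'   empty profiles.
#' @export
partitionSizeProfiles <- function(records, lo = 0L, hi = 1000L) {
  prof <- function(sub) {
    if (!length(sub)) suppressWarnings(sizeProfile(integer(0), lo, hi))
    else sizeProfile(sub, lo, hi)
  }
  list(fetal_specific = prof(records[origin(records) == "fetal_specific"]),
       shared = prof(records[origin(records) == "shared"]))
}
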
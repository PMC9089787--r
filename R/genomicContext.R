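#' Simulate eccDNA loci at random genomic coordinates
#'
#' Monte-Carlo null model for element enrichment: each simulated locus draws
#' a chromosome with probability proportional to its length, a start uniform
#' on the chromosome, and a size resampled with replacement from the
#' observed eccDNA sizes (so the null controls for the size-dependence of
#' overlap probability). Loci that would run off the chromosome end are
#' redrawn. The frequencies of these loci across genomic elements are the
#' "expected frequencies" against which enrichment is measured.
#'
#' @param seqlens named vector of chromosome lengths, or a
#'   \code{DNAStringSet}.
#' @param sizes observed eccDNA sizes (multiset to resample from), or an
#'   \linkS4class{EccDNASet}.
#' @param nSim number of loci to simulate (>= 1e4 recommended).
#' @param seed optional seed for this stage.
#' @return a \code{GRanges} of \code{nSim} simulated loci.
#' @export
simulateExpectedLoci <- function(seqlens, sizes, nSim, seed = NULL) {
  seqlens <- genomeSeqlengths(seqlens)
  if (is(sizes, "EccDNASet")) sizes <- width(sizes)
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L) stop("no observed sizes to resample")
  if (min(sizes) > max(seqlens))
    stop("smallest size exceeds every chromosome length")
  nSim <- as.integer(nSim)
  withSeed(seed, {
    chromNames <- names(seqlens)
    prob <- seqlens / sum(seqlens)
    out_chrom <- character(nSim); out_start <- integer(nSim)
    out_size <- integer(nSim)
    need <- seq_len(nSim)
    guard <- 0L
    while (length(need)) {
      guard <- guard + 1L
      if (guard > 1000L) stop("could not place simulated loci (sizes too large?)")
      k <- length(need)
      ch <- sample(chromNames, k, replace = TRUE, prob = prob)
      sz <- sample(sizes, k, replace = TRUE)
      st <- floor(stats::runif(k, 0, seqlens[ch]))
      ok <- st + sz <= seqlens[ch]
      out_chrom[need[ok]] <- ch[ok]
      out_start[need[ok]] <- as.integer(st[ok])
      out_size[need[ok]] <- sz[ok]
      need <- need[!ok]
    }
    GRanges(out_chrom, IRanges(start = out_start + 1L,
                               width = out_size))
  })
}

#' Element enrichment of eccDNA loci vs the Monte-Carlo expectation
#'
#' A locus overlaps an element class iff its half-open interval intersects
#' any interval of the class by at least 1 bp. Observed and expected
#' frequencies are computed identically on the real and the simulated loci;
#' \code{fold_change = observed_freq / expected_freq} (missing when the
#' expected frequency is 0). Fold changes > 1 indicate enrichment.
#'
#' @param records an \linkS4class{EccDNASet} (or GRanges) of observed loci.
#' @param elements named \code{GRangesList} of element annotations.
#' @param simulated \code{GRanges} from \code{\link{simulateExpectedLoci}}.
#' @return data.frame with one row per element class: observed_freq,
#'   expected_freq, fold_change, n_obs, n_sim.
#' @export
elementEnrichment <- function(records, elements, simulated) {
  if (length(simulated) == 0L) stop("empty simulated locus set")
  if (length(records) == 0L) stop("no observed loci")
  overlapFreq <- function(loci, el)
    mean(countOverlaps(loci, el, ignore.strand = TRUE) > 0L)
  classes <- names(elements)
  obs <- vapply(classes, function(cl) overlapFreq(records, elements[[cl]]), 0)
  exp_ <- vapply(classes, function(cl) overlapFreq(simulated, elements[[cl]]), 0)
  data.frame(element_class = classes,
             observed_freq = obs,
             expected_freq = exp_,
             fold_change = ifelse(exp_ > 0, obs / exp_, NA_real_),
             n_obs = length(records),
             n_sim = length(simulated),
             row.names = NULL)
}

#' Percent increase between two fold changes
#'
#' The reporting convention for contrasts between samples:
#' \code{100 * (fcB - fcA) / fcA}, e.g. 1.0 vs 1.53 is a +53\% increase.
#'
#' @param fcA,fcB fold changes of samples A and B.
#' @return percent increase of B over A.
#' @export
foldChangeIncrease <- function(fcA, fcB) 100 * (fcB - fcA) / fcA

#' Shared loci between two eccDNA sets
#'
#' Counts loci present in both sets by exact (chrom, start, end) identity
#' after deduplicating each set, and expresses the overlap as a percentage
#' of each set (2 decimal places, the conventional precision).
#'
#' @param setA,setB \linkS4class{EccDNASet}s (or GRanges).
#' @return list with \code{n_shared}, \code{pct_of_a}, \code{pct_of_b}
#'   (percentages are \code{NA} for an empty set, with a warning).
#' @export
sharedLoci <- function(setA, setB) {
  ka <- unique(lociKeys(setA)); kb <- unique(lociKeys(setB))
  n <- length(intersect(ka, kb))
  pa <- if (length(ka)) round(100 * n / length(ka), 2) else {
    warning("set A is empty; percentage undefined"); NA_real_ }
  pb <- if (length(kb)) round(100 * n / length(kb), 2) else {
    warning("set B is empty; percentage undefined"); NA_real_ }
  list(n_shared = n, pct_of_a = pa, pct_of_b = pb)
}

#' Junctional trinucleotide motif combinations
#'
#' For each locus the four junction motifs are the 3-base reference windows
#' anchored at the breakpoints: motif I = [start-3, start) (outside,
#' upstream of the circle start), II = [start, start+3) (inside at the
#' start), III = [end-3, end) (inside at the end), IV = [end, end+3)
#' (outside, downstream of the end). Circles are unstranded, so motifs are
#' always read from the reference forward strand. Loci within
#' \code{window} bp of a chromosome edge are excluded and counted in the
#' \code{"skipped"} attribute. Combinations are counted and ranked by
#' frequency, ties broken lexicographically.
#'
#' @param records an \linkS4class{EccDNASet} (or GRanges).
#' @param genome named \code{DNAStringSet}.
#' @param topK number of top combinations to return (all if \code{Inf}).
#' @param window motif length, bp (default 3).
#' @return data.frame with columns motif_i, motif_ii, motif_iii, motif_iv,
#'   count, rank; attributes \code{"skipped"} and \code{"n_counted"}.
#' @export
junctionMotifs <- function(records, genome, topK = 5L, window = 3L) {
  seqlens <- genomeSeqlengths(genome)
  chrom <- as.character(seqnames(records))
  s0 <- start(records) - 1L
  e0 <- end(records)
  ok <- s0 >= window & e0 + window <= seqlens[chrom]
  skipped <- sum(!ok)
  chrom <- chrom[ok]; s0 <- s0[ok]; e0 <- e0[ok]
  if (!length(chrom)) {
    out <- data.frame(motif_i = character(), motif_ii = character(),
                      motif_iii = character(), motif_iv = character(),
                      count = integer(), rank = integer())
    attr(out, "skipped") <- skipped; attr(out, "n_counted") <- 0L
    return(out)
  }
  mI <- mII <- mIII <- mIV <- character(length(chrom))
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    subj <- genome[[ch]]
    ext <- function(st0) as.character(Biostrings::extractAt(
      subj, IRanges(start = st0 + 1L, width = window)))
    mI[ix]   <- ext(s0[ix] - window)
    mII[ix]  <- ext(s0[ix])
    mIII[ix] <- ext(e0[ix] - window)
    mIV[ix]  <- ext(e0[ix])
  }
  combo <- paste(mI, mII, mIII, mIV, sep = "|")
  tab <- table(combo)
  ord <- order(-as.integer(tab), names(tab))
  tab <- tab[ord]
  k <- min(length(tab), topK)
  parts <- do.call(rbind, strsplit(names(tab)[seq_len(k)], "|", fixed = TRUE))
  out <- data.frame(motif_i = parts[, 1], motif_ii = parts[, 2],
                    motif_iii = parts[, 3], motif_iv = parts[, 4],
                    count = as.integer(tab[seq_len(k)]),
                    rank = seq_len(k))
  attr(out, "skipped") <- skipped
  attr(out, "n_counted") <- length(combo)
  out
}
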
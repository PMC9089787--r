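#' EccDNA abundance per million mappable reads (EPM)
#'
#' Locus counts are normalized by sequencing depth:
#' \code{EPM = n_eccdna / mappable_reads * 1e6}. EPM is invariant to scaling
#' both arguments by the same factor.
#'
#' @param nEccdna number of eccDNA loci identified.
#' @param mappableReads number of mappable read pairs (> 0).
#' @return the EPM value.
#' @examples
#' computeEPM(500, 2e6)  # 250
#' @export
computeEPM <- function(nEccdna, mappableReads) {
  if (length(mappableReads) != 1L || is.na(mappableReads) ||
      mappableReads <= 0)
    stop("mappableReads must be a single positive count")
  nEccdna / mappableReads * 1e6
}

#' Per-1-bp size profile of eccDNA molecules
#'
#' Frequencies are percent of molecules at each integer size:
#' \code{freq[s] = 100 * n(size == s) / n_in_range}. Molecules outside
#' \code{[lo, hi]} are excluded from both numerator and denominator.
#' Pooling samples is concatenating their record sets before profiling;
#' \code{sizeProfile(c(a, b))} equals profiling the pooled records.
#' The 1 bp bin width is what resolves the 10 bp periodic subpeaks.
#'
#' @param records an \linkS4class{EccDNASet}, or an integer vector of sizes.
#' @param lo,hi profile range, bp (default 0-1000).
#' @return a \linkS4class{SizeProfile}. An empty input yields an all-zero
#'   profile with \code{nMolecules = 0}, flagged with a warning.
#' @export
sizeProfile <- function(records, lo = 0L, hi = 1000L) {
  sizes <- if (is(records, "EccDNASet")) width(records) else
    as.integer(records)
  lo <- as.integer(lo); hi <- as.integer(hi)
  sizes <- sizes[sizes >= lo & sizes <= hi]
  n <- length(sizes)
  if (n == 0L) {
    warning("no molecules in [", lo, ", ", hi, "]: empty profile (flagged)")
    return(new("SizeProfile", lo = lo, hi = hi,
               freq = numeric(hi - lo + 1L), nMolecules = 0L))
  }
  counts <- tabulate(sizes - lo + 1L, nbins = hi - lo + 1L)
  new("SizeProfile", lo = lo, hi = hi, freq = 100 * counts / n,
      nMolecules = n)
}

#' Peak-cluster AUC and AUC ratio of a size profile
#'
#' AUC of a window is the summed percentage of molecules with sizes inside
#' it, both ends inclusive. Defaults are the first (150-250 bp) and second
#' (300-450 bp) plasma eccDNA peak clusters; the inter-cluster gap
#' (251-299 bp) belongs to neither, so auc1 + auc2 < 100 in general. The
#' AUC ratio auc2/auc1 summarizes overall size: the higher the ratio, the
#' longer the eccDNA. When auc1 is 0 the ratio is undefined and reported as
#' \code{NA} (never infinity). Ratios are conventionally quoted at 2
#' decimal places; internal arithmetic is full precision.
#'
#' @param profile a \linkS4class{SizeProfile} (normalized, i.e. non-empty).
#' @param window1,window2 integer windows \code{c(lo, hi)}, bp, inclusive.
#' @return a \linkS4class{ClusterAUC}.
#' @export
clusterAUC <- function(profile, window1 = c(150L, 250L),
                       window2 = c(300L, 450L)) {
  stopifnot(is(profile, "SizeProfile"))
  f <- profileFreq(profile)
  s <- profile@lo:profile@hi
  auc1 <- sum(f[s >= window1[1] & s <= window1[2]])
  auc2 <- sum(f[s >= window2[1] & s <= window2[2]])
  ratio <- if (auc1 > 0) auc2 / auc1 else NA_real_
  new("ClusterAUC", window1 = as.integer(window1),
      window2 = as.integer(window2), auc1 = auc1, auc2 = auc2,
      aucRatio = ratio)
}

#' Write / read a size profile as TSV (columns: size, percent)
#' @param profile a \linkS4class{SizeProfile}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
  utils::write.table(
    data.frame(size = profile@lo:profile@hi, percent = profile@freq),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileTsv
#' @param nMolecules molecule count to attach (the TSV stores only the
#'   normalized shape).
#' @export
readProfileTsv <- function(path, nMolecules = 1L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  new("SizeProfile", lo = as.integer(min(df$size)),
      hi = as.integer(max(df$size)), freq = df$percent,
      nMolecules = as.integer(nMolecules))
}

#' Plot a size profile
#'
#' Base-graphics line plot of the per-1-bp frequency curve, with the two
#' peak-cluster windows shaded.
#'
#' @param profile a \linkS4class{SizeProfile}.
#' @param window1,window2 cluster windows to shade.
#' @param main plot title.
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @importFrom graphics plot rect lines
#' @importFrom grDevices adjustcolor
#' @export
plotSizeProfile <- function(profile, window1 = c(150, 250),
                            window2 = c(300, 450), main = "eccDNA size profile",
                            ...) {
  s <- profile@lo:profile@hi
  plot(s, profile@freq, type = "n", xlab = "size (bp)",
       ylab = "frequency (%)", main = main, ...)
  rect(window1[1], 0, window1[2], max(profile@freq) * 1.05,
       col = adjustcolor("steelblue", 0.15), border = NA)
  rect(window2[1], 0, window2[2], max(profile@freq) * 1.05,
       col = adjustcolor("firebrick", 0.15), border = NA)
  lines(s, profile@freq)
  invisible(NULL)
}
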
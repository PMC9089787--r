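#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels
NULL

## Controlled vocabularies shared across the package
GENOTYPES <- c("WT", "Dnase1_KO", "Dnase1l3_KO", "other")
ORIGINS   <- c("unassigned", "fetal_specific", "shared")
TISSUES   <- c("plasma", "liver", "buffy_coat", "other")
LIBRARIES <- c("tagmentation", "rolling_circle")
ELEMENT_CLASSES <- c("five_prime_UTR", "three_prime_UTR", "gene_body",
                     "CpG_island", "repeat")

#' EccDNASet: a set of identified eccDNA loci
#'
#' An \code{EccDNASet} extends \linkS4class{GRanges}; each range is one
#' eccDNA species (a distinct circle locus). Required metadata columns are
#' \code{support} (number of distinct junction-spanning fragments),
#' \code{sample_id}, \code{genotype} and \code{origin}. Coordinates follow
#' the usual GRanges 1-based closed convention internally; the exported
#' constructor and the BED reader/writer speak 0-based half-open, so that
#' circle size equals \code{width()} equals \code{end0 - start0}.
#'
#' @slot ... inherits all GRanges slots.
#' @export
setClass("EccDNASet", contains = "GRanges")

setValidity("EccDNASet", function(object) {
  m <- mcols(object)
  req <- c("support", "sample_id", "genotype", "origin")
  miss <- setdiff(req, colnames(m))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object)) {
    if (any(is.na(m$support)) || any(m$support < 1L))
      return("support must be >= 1 for every record")
    if (!all(m$genotype %in% GENOTYPES))
      return(paste("genotype must be one of:", paste(GENOTYPES, collapse = ", ")))
    if (!all(m$origin %in% ORIGINS))
      return(paste("origin must be one of:", paste(ORIGINS, collapse = ", ")))
    if (any(width(object) < 1L))
      return("every locus must satisfy end > start")
  }
  TRUE
})

#' Construct an EccDNASet from 0-based half-open coordinates
#'
#' @param chrom chromosome names.
#' @param start0 0-based inclusive circle start positions.
#' @param end0 0-based exclusive circle end positions (\code{end0 > start0};
#'   circle size is \code{end0 - start0}).
#' @param support junction support counts (distinct fragments), >= 1.
#' @param sample_id opaque sample labels (recycled).
#' @param genotype one of \code{"WT"}, \code{"Dnase1_KO"},
#'   \code{"Dnase1l3_KO"}, \code{"other"} (recycled).
#' @param origin one of \code{"unassigned"}, \code{"fetal_specific"},
#'   \code{"shared"} (recycled).
#' @param seqlengths optional named vector of chromosome lengths.
#' @return an \linkS4class{EccDNASet}.
#' @examples
#' EccDNASet("chr1", 100, 300, support = 2)
#' @export
EccDNASet <- function(chrom = character(), start0 = integer(),
                      end0 = integer(), support = integer(),
                      sample_id = "sample", genotype = "other",
                      origin = "unassigned", seqlengths = NULL) {
  n <- length(start0)
  if (length(end0) != n) stop("start0 and end0 lengths differ")
  if (n && (any(end0 <= start0) || any(start0 < 0)))
    stop("invalid coordinates: need 0 <= start0 < end0")
  if (length(support) == 0L && n) support <- 1L
  gr <- GRanges(rep_len(chrom, n),
                IRanges(start = as.integer(start0) + 1L,
                        end = as.integer(end0)))
  if (!is.null(seqlengths)) seqlengths(gr) <- seqlengths[seqlevels(gr)]
  mcols(gr)$support   <- as.integer(rep_len(support, n))
  mcols(gr)$sample_id <- rep_len(as.character(sample_id), n)
  mcols(gr)$genotype  <- rep_len(as.character(genotype), n)
  mcols(gr)$origin    <- rep_len(as.character(origin), n)
  new("EccDNASet", gr)
}

#' @describeIn EccDNASet 0-based inclusive starts.
#' @param x an EccDNASet.
#' @export
eccStarts <- function(x) start(x) - 1L

#' @describeIn EccDNASet 0-based exclusive ends.
#' @export
eccEnds <- function(x) end(x)

#' @describeIn EccDNASet circle sizes in bp (\code{end0 - start0}).
#' @export
eccSizes <- function(x) width(x)

#' @describeIn EccDNASet junction support per locus.
#' @export
eccSupport <- function(x) mcols(x)$support

#' @describeIn EccDNASet sample labels.
#' @export
sampleId <- function(x) mcols(x)$sample_id

#' @describeIn EccDNASet genotype labels.
#' @export
genotype <- function(x) mcols(x)$genotype

#' @describeIn EccDNASet per-molecule origin calls.
#' @export
origin <- function(x) mcols(x)$origin

#' @describeIn EccDNASet replace origin calls.
#' @param value replacement values.
#' @export
`origin<-` <- function(x, value) {
  mcols(x)$origin <- rep_len(as.character(value), length(x))
  validObject(x)
  x
}

setMethod("show", "EccDNASet", function(object) {
  cat(sprintf("EccDNASet with %d eccDNA loci (sizes %s bp)\n",
              length(object),
              if (length(object))
                paste(range(width(object)), collapse = "-") else "NA"))
  callNextMethod()
})

#' SizeProfile: per-1-bp size frequency distribution
#'
#' Frequencies are percentages of molecules whose circle size (bp) falls at
#' each integer size within \code{[lo, hi]}; molecules outside the range are
#' excluded from both numerator and denominator. When \code{nMolecules} is 0
#' the profile is all-zero and flagged.
#'
#' @slot lo,hi integer range bounds (bp).
#' @slot freq numeric vector of length \code{hi - lo + 1}, percent.
#' @slot nMolecules number of molecules inside the range.
#' @export
setClass("SizeProfile",
         representation(lo = "integer", hi = "integer",
                        freq = "numeric", nMolecules = "integer"))

setValidity("SizeProfile", function(object) {
  if (object@hi < object@lo) return("hi must be >= lo")
  if (length(object@freq) != object@hi - object@lo + 1L)
    return("freq length must equal hi - lo + 1")
  if (any(object@freq < -1e-9)) return("freq must be non-negative")
  if (object@nMolecules > 0L && abs(sum(object@freq) - 100) > 1e-6)
    return("percentages must sum to 100")
  TRUE
})

setMethod("show", "SizeProfile", function(object) {
  cat(sprintf("SizeProfile over [%d, %d] bp, n = %d molecules%s\n",
              object@lo, object@hi, object@nMolecules,
              if (object@nMolecules == 0L) " (EMPTY, flagged)" else ""))
  if (object@nMolecules > 0L) {
    mode_size <- object@lo + which.max(object@freq) - 1L
    cat(sprintf("  modal size: %d bp (%.2f%%)\n", mode_size, max(object@freq)))
  }
})

#' @describeIn SizeProfile frequencies (percent) named by size.
#' @param x a SizeProfile.
#' @export
profileFreq <- function(x) {
  stats::setNames(x@freq, x@lo:x@hi)
}

#' @describeIn SizeProfile number of molecules inside the profiled range.
#' @export
nMolecules <- function(x) x@nMolecules

#' ClusterAUC: peak-cluster areas and their ratio
#'
#' Area under the normalized size-profile curve inside the first
#' (default 150-250 bp) and second (default 300-450 bp) peak-cluster
#' windows, inclusive on both ends, and the ratio AUC2/AUC1. The ratio is
#' \code{NA} when AUC1 is zero (undefined, never infinity).
#'
#' @slot window1,window2 integer windows \code{c(lo, hi)}, bp, inclusive.
#' @slot auc1,auc2 percent of molecules inside each window.
#' @slot aucRatio auc2/auc1, or NA when auc1 == 0.
#' @export
setClass("ClusterAUC",
         representation(window1 = "integer", window2 = "integer",
                        auc1 = "numeric", auc2 = "numeric",
                        aucRatio = "numeric"))

setValidity("ClusterAUC", function(object) {
  if (object@auc1 < -1e-9 || object@auc1 > 100 + 1e-9 ||
      object@auc2 < -1e-9 || object@auc2 > 100 + 1e-9)
    return("AUC values must lie in [0, 100]")
  TRUE
})

setMethod("show", "ClusterAUC", function(object) {
  cat(sprintf("ClusterAUC: AUC[%d-%d] = %.1f%%, AUC[%d-%d] = %.1f%%, ratio = %s\n",
              object@window1[1], object@window1[2], object@auc1,
              object@window2[1], object@window2[2], object@auc2,
              if (is.na(object@aucRatio)) "NA (AUC1 = 0)"
              else sprintf("%.2f", object@aucRatio)))
})

#' @describeIn ClusterAUC the second/first cluster AUC ratio.
#' @param x a ClusterAUC.
#' @export
aucRatio <- function(x) x@aucRatio

#' @describeIn ClusterAUC both AUC values as a named vector.
#' @export
aucValues <- function(x) c(auc1 = x@auc1, auc2 = x@auc2)

#' CallerConfig: tuning parameters of the junction caller
#'
#' @slot minSize,maxSize admissible circle sizes, bp.
#' @slot minSoftclip minimum soft-clip length to attempt junction
#'   realignment (>= 5 bp).
#' @slot minSupport minimum distinct supporting fragments per locus.
#' @slot requireSplit if TRUE a locus needs at least one split-read signal.
#' @slot mapqMin minimum mapping quality.
#' @export
setClass("CallerConfig",
         representation(minSize = "integer", maxSize = "integer",
                        minSoftclip = "integer", minSupport = "integer",
                        requireSplit = "logical", mapqMin = "integer"))

setValidity("CallerConfig", function(object) {
  if (!(object@minSize > 0L && object@minSize < object@maxSize))
    return("need 0 < minSize < maxSize")
  if (object@minSoftclip < 5L)
    return("minSoftclip must be >= 5")
  if (object@minSupport < 1L) return("minSupport must be >= 1")
  TRUE
})

#' Construct a CallerConfig
#'
#' Defaults: sizes 50-10,000 bp (plasma eccDNA profiles span roughly
#' 100-600 bp; the wide ceiling keeps rarer long species), 10 bp minimum
#' soft clip, support 1, split-read evidence required, MAPQ >= 30.
#'
#' @param minSize,maxSize admissible circle sizes (bp).
#' @param minSoftclip minimum soft-clip length for junction realignment.
#' @param minSupport minimum distinct supporting fragments.
#' @param requireSplit require at least one split-read signal per locus.
#' @param mapqMin minimum mapping quality.
#' @return a \linkS4class{CallerConfig}.
#' @export
callerConfig <- function(minSize = 50L, maxSize = 10000L, minSoftclip = 10L,
                         minSupport = 1L, requireSplit = TRUE,
                         mapqMin = 30L) {
  new("CallerConfig", minSize = as.integer(minSize),
      maxSize = as.integer(maxSize), minSoftclip = as.integer(minSoftclip),
      minSupport = as.integer(minSupport),
      requireSplit = as.logical(requireSplit), mapqMin = as.integer(mapqMin))
}

setMethod("show", "CallerConfig", function(object) {
  cat(sprintf(paste0("CallerConfig: size [%d, %d] bp, softclip >= %d, ",
                     "support >= %d, requireSplit = %s, MAPQ >= %d\n"),
              object@minSize, object@maxSize, object@minSoftclip,
              object@minSupport, object@requireSplit, object@mapqMin))
})

#' SizeLaw: the bimodal, 10-bp-comb size distribution of plasma eccDNA
#'
#' A two-component Gaussian mixture (summits near 202 and 338 bp) thinned
#' by a periodic comb: sizes congruent to \code{combPhase} modulo
#' \code{combPeriod} are kept with probability 1, all other sizes with
#' probability \code{1 - combDepth}. Sampled sizes are bounded below at
#' \code{minSize}.
#'
#' @slot mu,sd length-2 numeric, cluster means and standard deviations (bp).
#' @slot w1 mixture weight of the first (short) cluster, in [0, 1].
#' @slot combPeriod comb period, bp (> 0).
#' @slot combDepth comb depth in [0, 1] (0 = no comb).
#' @slot combPhase residue (mod combPeriod) kept at full probability.
#' @slot minSize smallest admissible size, bp.
#' @export
setClass("SizeLaw",
         representation(mu = "numeric", sd = "numeric", w1 = "numeric",
                        combPeriod = "integer", combDepth = "numeric",
                        combPhase = "integer", minSize = "integer"))

setValidity("SizeLaw", function(object) {
  if (length(object@mu) != 2L || length(object@sd) != 2L)
    return("mu and sd must have length 2")
  if (object@w1 < 0 || object@w1 > 1) return("w1 must lie in [0, 1]")
  if (object@combPeriod <= 0L) return("combPeriod must be > 0")
  if (object@combDepth < 0 || object@combDepth > 1)
    return("combDepth must lie in [0, 1]")
  TRUE
})

#' Construct a SizeLaw
#'
#' @param mu cluster means, bp. Defaults c(202, 338), the reported plasma
#'   eccDNA summit positions.
#' @param sd cluster standard deviations, bp.
#' @param w1 weight of the first cluster.
#' @param combPeriod,combDepth,combPhase 10-bp subpeak comb parameters.
#' @param minSize smallest admissible size, bp.
#' @return a \linkS4class{SizeLaw}.
#' @export
sizeLaw <- function(mu = c(202, 338), sd = c(30, 40), w1 = 0.78,
                    combPeriod = 10L, combDepth = 0.5, combPhase = 2L,
                    minSize = 50L) {
  new("SizeLaw", mu = as.numeric(mu), sd = as.numeric(sd),
      w1 = as.numeric(w1), combPeriod = as.integer(combPeriod),
      combDepth = as.numeric(combDepth), combPhase = as.integer(combPhase),
      minSize = as.integer(minSize))
}

setMethod("show", "SizeLaw", function(object) {
  cat(sprintf(paste0("SizeLaw: N(%g, %g) w=%0.2f + N(%g, %g) w=%0.2f, ",
                     "comb %d bp (depth %.2f, phase %d), min %d bp\n"),
              object@mu[1], object@sd[1], object@w1,
              object@mu[2], object@sd[2], 1 - object@w1,
              object@combPeriod, object@combDepth, object@combPhase,
              object@minSize))
})

#' SampleMeta: per-sample metadata
#'
#' @slot sampleId opaque label.
#' @slot genotype one of the genotype vocabulary.
#' @slot tissue one of plasma, liver, buffy_coat, other.
#' @slot library tagmentation or rolling_circle.
#' @slot mappableReads number of mappable read pairs (must be > 0 before any
#'   EPM computation).
#' @export
setClass("SampleMeta",
         representation(sampleId = "character", genotype = "character",
                        tissue = "character", library = "character",
                        mappableReads = "numeric"))

setValidity("SampleMeta", function(object) {
  if (!object@genotype %in% GENOTYPES) return("unknown genotype")
  if (!object@tissue %in% TISSUES) return("unknown tissue")
  if (!object@library %in% LIBRARIES) return("unknown library type")
  if (object@mappableReads < 0) return("mappableReads must be >= 0")
  TRUE
})

#' Construct a SampleMeta
#' @param sampleId opaque label.
#' @param genotype,tissue,library controlled-vocabulary labels.
#' @param mappableReads mappable read-pair count.
#' @return a \linkS4class{SampleMeta}.
#' @export
sampleMeta <- function(sampleId, genotype = "other", tissue = "plasma",
                       library = "tagmentation", mappableReads = 0) {
  new("SampleMeta", sampleId = as.character(sampleId), genotype = genotype,
      tissue = tissue, library = library,
      mappableReads = as.numeric(mappableReads))
}

#' GroupTestResult: result container for the nonparametric tests
#'
#' @slot statistic the test statistic (H for Kruskal-Wallis, U for the
#'   rank-sum test); NA when undefined (all values identical).
#' @slot pValue two-sided p value.
#' @slot method test description.
#' @slot groupSizes per-group sample sizes.
#' @slot pairwise data.frame of post hoc pairwise results (z, raw and
#'   adjusted p), or a 0-row data.frame when not applicable.
#' @export
setClass("GroupTestResult",
         representation(statistic = "numeric", pValue = "numeric",
                        method = "character", groupSizes = "integer",
                        pairwise = "data.frame"))

setValidity("GroupTestResult", function(object) {
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("p value must lie in [0, 1]")
  TRUE
})

setMethod("show", "GroupTestResult", function(object) {
  cat(sprintf("%s: statistic = %s, p = %s (groups n = %s)\n",
              object@method,
              if (is.na(object@statistic)) "NA"
              else format(object@statistic, digits = 5),
              if (is.na(object@pValue)) "NA"
              else format.pval(object@pValue, digits = 3),
              paste(object@groupSizes, collapse = ", ")))
  if (nrow(object@pairwise)) {
    cat("pairwise:\n")
    print(object@pairwise, row.names = FALSE)
  }
})

#' @describeIn GroupTestResult the p value.
#' @param x a GroupTestResult.
#' @export
pValue <- function(x) x@pValue

#' @describeIn GroupTestResult the test statistic.
#' @export
testStatistic <- function(x) x@statistic

#' @describeIn GroupTestResult pairwise post hoc table.
#' @export
pairwiseResults <- function(x) x@pairwise
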
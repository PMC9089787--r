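#' Read paired-end alignments for eccDNA calling
#'
#' Reads a coordinate-sorted SAM or BAM file and returns the primary,
#' mapped records with mapping quality at least \code{mapqMin} as a
#' \code{DataFrame} of aligned fragments (one row per record). Positions are
#' converted to the package-wide 0-based convention. The number of read
#' pairs in which both mates pass the filter is exposed as
#' \code{metadata(x)$mappable_reads} — the depth normalizer used by
#' \code{\link{computeEPM}}.
#'
#' @param path SAM (plain text) or BAM file, coordinate-sorted.
#' @param mapqMin minimum mapping quality (default 30, a standard
#'   unique-alignment proxy; configurable because the appropriate
#'   mappability filter is protocol-dependent).
#' @return a \code{DataFrame} with columns \code{read_id}, \code{flag},
#'   \code{chrom}, \code{pos} (0-based leftmost), \code{mapq}, \code{cigar},
#'   \code{seq}, \code{strand}, \code{mate_chrom}, \code{mate_pos}
#'   (0-based), \code{tlen}, \code{is_first}, \code{is_paired},
#'   \code{is_proper}; \code{metadata()} carries \code{mappable_reads}.
#' @export
readAlignments <- function(path, mapqMin = 30L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            indexDestination = FALSE, overwrite = TRUE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", "seq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    out <- DataFrame(read_id = character(), flag = integer(),
                     chrom = character(), pos = integer(), mapq = integer(),
                     cigar = character(), seq = character(),
                     strand = character(), mate_chrom = character(),
                     mate_pos = integer(), tlen = integer(),
                     is_first = logical(), is_paired = logical(),
                     is_proper = logical())
    metadata(out)$mappable_reads <- 0L
    return(out)
  }
  flag <- res$flag
  mapped <- !bitwAnd(flag, 0x4)
  ## coordinate-sorted check on mapped records: chromosomes form contiguous
  ## blocks and positions are nondecreasing within each block
  rn <- as.character(res$rname)[mapped]
  po <- res$pos[mapped]
  if (length(rn) > 1L) {
    r <- rle(rn)
    if (anyDuplicated(r$values))
      stop("input is not coordinate-sorted: chromosome blocks recur")
    grp <- rep(seq_along(r$lengths), r$lengths)
    if (any(unlist(tapply(po, grp, function(p) diff(p) < 0), use.names = FALSE)))
      stop("input is not coordinate-sorted: positions decrease")
  }
  primary <- !bitwAnd(flag, 0x100) & !bitwAnd(flag, 0x800)
  keep <- mapped & primary & res$mapq >= mapqMin & !is.na(res$pos)
  out <- DataFrame(
    read_id    = res$qname[keep],
    flag       = flag[keep],
    chrom      = as.character(res$rname)[keep],
    pos        = res$pos[keep] - 1L,
    mapq       = res$mapq[keep],
    cigar      = res$cigar[keep],
    seq        = as.character(res$seq)[keep],
    strand     = ifelse(bitwAnd(flag[keep], 0x10) > 0L, "-", "+"),
    mate_chrom = as.character(res$mrnm)[keep],
    mate_pos   = res$mpos[keep] - 1L,
    tlen       = res$isize[keep],
    is_first   = bitwAnd(flag[keep], 0x40) > 0L,
    is_paired  = bitwAnd(flag[keep], 0x1) > 0L,
    is_proper  = bitwAnd(flag[keep], 0x2) > 0L)
  ## mappable read pairs: qnames whose first and second mate both pass
  paired <- out[out$is_paired, ]
  firsts <- unique(paired$read_id[paired$is_first])
  seconds <- unique(paired$read_id[!paired$is_first])
  metadata(out)$mappable_reads <- length(intersect(firsts, seconds))
  out
}

#' Write eccDNA records as BED6+2
#'
#' Serializes an \linkS4class{EccDNASet} as BED with columns chrom, start,
#' end (0-based half-open, BED native), name = sample_id, score = support,
#' strand = ".", then two extra columns: size (bp) and origin. Records are
#' written in their current order; output is byte-stable for a fixed input.
#'
#' @param records an \linkS4class{EccDNASet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRecordsBed <- function(records, path) {
  stopifnot(is(records, "EccDNASet"))
  validObject(records)
  if (length(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(chrom = as.character(seqnames(records)),
                   start = eccStarts(records),
                   end = eccEnds(records),
                   name = sampleId(records),
                   score = eccSupport(records),
                   strand = ".",
                   size = eccSizes(records),
                   origin = origin(records))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read eccDNA records from BED6+2
#'
#' Inverse of \code{\link{writeRecordsBed}}. Genotype is not serialized in
#' BED and comes back as \code{"other"}.
#'
#' @param path BED6+2 file written by \code{\link{writeRecordsBed}}.
#' @return an \linkS4class{EccDNASet}.
#' @export
readRecordsBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L)
    return(EccDNASet())
  gr <- rtracklayer::import(path, format = "bed",
                            extraCols = c(size = "integer",
                                          origin = "character"))
  rec <- EccDNASet(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   support = as.integer(gr$score),
                   sample_id = gr$name, genotype = "other",
                   origin = gr$origin)
  if (!all(eccSizes(rec) == gr$size))
    stop("size column inconsistent with coordinates in ", path)
  rec
}

#' Read a strain-discriminating SNP table
#'
#' The TSV carries a header and columns \code{chrom}, \code{pos} (1-based in
#' the file, converted to 0-based), \code{allele_A} (maternal strain) and
#' \code{allele_B} (paternal strain). Alleles must be single A/C/G/T bases
#' and differ at every row.
#'
#' @param path TSV file.
#' @return data.frame with columns chrom, pos (0-based), allele_A, allele_B.
#' @export
readSnpTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer",
                                         "character", "character"))
  names(df) <- c("chrom", "pos", "allele_A", "allele_B")
  bad <- which(!(df$allele_A %in% c("A", "C", "G", "T")) |
               !(df$allele_B %in% c("A", "C", "G", "T")))
  if (length(bad))
    stop("non-ACGT allele in SNP table at row ", bad[1])
  same <- which(df$allele_A == df$allele_B)
  if (length(same))
    stop("identical alleles in SNP table at row ", same[1])
  df$pos <- df$pos - 1L
  df
}

#' Write a strain SNP table (1-based positions on disk)
#' @param snps data.frame with 0-based pos as returned by
#'   \code{\link{readSnpTable}}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeSnpTable <- function(snps, path) {
  out <- data.frame(chrom = snps$chrom, pos = snps$pos + 1L,
                    allele_A = snps$allele_A, allele_B = snps$allele_B)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic-element annotations (one BED per class)
#'
#' @param paths named character vector of BED paths; names must be element
#'   classes among five_prime_UTR, three_prime_UTR, gene_body, CpG_island,
#'   repeat.
#' @return a named \code{GRangesList}, one sorted \code{GRanges} per class.
#' @export
readElementsBed <- function(paths) {
  if (is.null(names(paths)) || !all(names(paths) %in% ELEMENT_CLASSES))
    stop("element paths must be named by class: ",
         paste(ELEMENT_CLASSES, collapse = ", "))
  grl <- lapply(paths, function(p) sort(rtracklayer::import(p, format = "bed")))
  GRangesList(grl)
}
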
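## ---- synthetic-data generator -------------------------------------------
## Stand-ins for the study's sequencing data: toy genomes for two colinear
## strains, element annotations, strain SNP tables, circle populations with
## the bimodal 10-bp-comb size structure, and pre-aligned junction-bearing
## reads in tagmentation or rolling-circle style, all with truth logs.

randomDna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## plant non-overlapping intervals of `elLen` bp per class totalling ~frac of
## the genome (per chromosome, proportionally)
plantElements <- function(seqlens, frac, elLen) {
  grs <- lapply(names(seqlens), function(ch) {
    len <- seqlens[[ch]]
    target <- frac * len
    nEl <- max(1L, round(target / elLen))
    taken <- IRanges()
    out <- IRanges()
    guard <- 0L
    while (length(out) < nEl && guard < 50L * nEl) {
      guard <- guard + 1L
      st <- sample.int(len - elLen, 1L)
      cand <- IRanges(start = st, width = elLen)
      if (!length(IRanges::findOverlaps(cand, taken))) {
        taken <- c(taken, cand)
        out <- c(out, cand)
      }
    }
    GRanges(ch, sort(out))
  })
  sort(unlist(GRangesList(grs), use.names = FALSE))
}

#' Generate a toy two-strain genome with annotations and SNPs
#'
#' Produces a random strain-A genome, non-overlapping planted element
#' intervals per class, a strain-B genome that differs from strain A only at
#' the emitted SNP positions (colinear, so coordinates are shared), and the
#' corresponding SNP table. Byte-identical output for a fixed seed.
#'
#' @param lengths named or unnamed chromosome lengths (>= 10 kb each).
#' @param gc GC content of the random sequence.
#' @param elementFractions named fractions of the genome to cover per
#'   element class.
#' @param nSnps number of strain-discriminating SNPs (distinct positions).
#' @param seed mandatory seed.
#' @param outDir optional directory; when given, writes genome_A.fa,
#'   genome_B.fa, one BED per element class, and snps.tsv.
#' @return list: \code{genomeA}, \code{genomeB} (\code{DNAStringSet}s),
#'   \code{snps} (data.frame, 0-based pos), \code{elements}
#'   (\code{GRangesList}), \code{achievedFractions}, and file paths when
#'   \code{outDir} was given.
#' @export
makeGenome <- function(lengths = c(chrA = 300000L, chrB = 200000L),
                       gc = 0.42,
                       elementFractions = c(five_prime_UTR = 0.01,
                                            three_prime_UTR = 0.015,
                                            gene_body = 0.25,
                                            CpG_island = 0.01,
                                            "repeat" = 0.08),
                       nSnps = 2000L, seed, outDir = NULL) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  if (any(lengths < 10000L)) stop("chromosome lengths must be >= 10 kb")
  if (is.null(names(lengths)))
    names(lengths) <- paste0("chr", seq_along(lengths))
  elLens <- c(five_prime_UTR = 150L, three_prime_UTR = 300L,
              gene_body = 3000L, CpG_island = 500L, "repeat" = 300L)
  withSeed(seed, {
    genomeA <- Biostrings::DNAStringSet(
      vapply(lengths, randomDna, "", gc = gc))
    names(genomeA) <- names(lengths)
    elements <- GRangesList(lapply(
      stats::setNames(names(elementFractions), names(elementFractions)),
      function(cl) plantElements(lengths, elementFractions[[cl]],
                                 elLens[[cl]])))
    achieved <- vapply(elements, function(gr)
      sum(width(gr)) / sum(lengths), 0)
    ## SNPs: distinct genome-wide positions, allele_B drawn from the other
    ## three bases
    perChrom <- round(nSnps * lengths / sum(lengths))
    perChrom[length(perChrom)] <- nSnps - sum(perChrom[-length(perChrom)])
    snps <- do.call(rbind, lapply(names(lengths), function(ch) {
      k <- perChrom[[ch]]
      pos <- sort(sample.int(lengths[[ch]], k)) - 1L
      refb <- strsplit(getSeq0(genomeA, ch, 0L, lengths[[ch]]), "")[[1]][pos + 1L]
      altb <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      data.frame(chrom = ch, pos = pos, allele_A = refb, allele_B = altb,
                 row.names = NULL)
    }))
    genomeB <- genomeA
    for (ch in names(lengths)) {
      ix <- snps$chrom == ch
      if (any(ix))
        genomeB[[ch]] <- Biostrings::replaceLetterAt(
          genomeB[[ch]], snps$pos[ix] + 1L,
          paste(snps$allele_B[ix], collapse = ""))
    }
    out <- list(genomeA = genomeA, genomeB = genomeB, snps = snps,
                elements = elements, achievedFractions = achieved)
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      out$paths <- c(
        genome_A = file.path(outDir, "genome_A.fa"),
        genome_B = file.path(outDir, "genome_B.fa"),
        snps = file.path(outDir, "snps.tsv"))
      Biostrings::writeXStringSet(genomeA, out$paths[["genome_A"]])
      Biostrings::writeXStringSet(genomeB, out$paths[["genome_B"]])
      writeSnpTable(snps, out$paths[["snps"]])
      for (cl in names(elements)) {
        p <- file.path(outDir, paste0("elements_", cl, ".bed"))
        rtracklayer::export(elements[[cl]], p, format = "bed")
        out$paths[paste0("elements_", cl)] <- p
      }
    }
    out
  })
}

#' Sample circle sizes from a SizeLaw
#'
#' Draws from the two-Gaussian mixture, rounds to integer bp, rejects sizes
#' below \code{minSize}, then thins by the periodic comb: sizes congruent to
#' the comb phase are always kept, others with probability
#' \code{1 - combDepth}.
#'
#' @param law a \linkS4class{SizeLaw}.
#' @param n number of sizes.
#' @param seed optional stage seed.
#' @return integer vector of n sizes.
#' @export
sampleSizes <- function(law, n, seed = NULL) {
  stopifnot(is(law, "SizeLaw"))
  withSeed(seed, {
    out <- integer(0)
    while (length(out) < n) {
      k <- max(1000L, 2L * (n - length(out)))
      comp <- 1L + (stats::runif(k) > law@w1)
      sz <- as.integer(round(stats::rnorm(k, law@mu[comp], law@sd[comp])))
      sz <- sz[sz >= law@minSize]
      keep <- (sz %% law@combPeriod == law@combPhase) |
        (stats::runif(length(sz)) > law@combDepth)
      out <- c(out, sz[keep])
    }
    out[seq_len(n)]
  })
}

## mixture CDF (comb depth 0) used as the KS reference for size-law recovery
mixtureCdf <- function(law) {
  function(q) {
    raw <- function(x) law@w1 * stats::pnorm(x, law@mu[1], law@sd[1]) +
      (1 - law@w1) * stats::pnorm(x, law@mu[2], law@sd[2])
    lowMass <- raw(law@minSize - 0.5)
    pmax(0, (raw(q) - lowMass) / (1 - lowMass))
  }
}

#' Sample circle loci on a genome
#'
#' Sizes come from the size law; chromosomes are drawn with probability
#' proportional to length and starts uniform such that the circle fits.
#'
#' @param genome \code{DNAStringSet} or named seqlengths.
#' @param law a \linkS4class{SizeLaw}.
#' @param n number of circles.
#' @param seed optional stage seed.
#' @return a \code{GRanges} truth set with a \code{circle_id} column
#'   (coordinates exact; export with \code{rtracklayer::export} for a truth
#'   BED).
#' @export
sampleCircles <- function(genome, law, n, seed = NULL) {
  seqlens <- genomeSeqlengths(genome)
  withSeed(seed, {
    sizes <- sampleSizes(law, n)
    ch <- sample(names(seqlens), n, replace = TRUE,
                 prob = seqlens / sum(seqlens))
    st <- vapply(seq_len(n), function(i)
      sample.int(seqlens[[ch[i]]] - sizes[i], 1L) - 1L, 0L)
    gr <- GRanges(ch, IRanges(start = st + 1L, width = sizes))
    mcols(gr)$circle_id <- sprintf("circ%06d", seq_len(n))
    gr
  })
}

#' Scenario configuration for read emission
#'
#' @param genotype mouse genotype of the sample.
#' @param law maternal-plasma size law; defaults to the genotype's law
#'   (\code{\link{genotypeSizeLaw}}).
#' @param nCircles circles per sample.
#' @param backgroundPairs concordant inward-facing linear-DNA read pairs.
#' @param readLength read length, bp.
#' @param coverage junction fragments per circle (tagmentation); RCA
#'   multiplies this by \code{rcaCopies}.
#' @param errorRate per-base substitution error rate.
#' @param library \code{"tagmentation"} or \code{"rolling_circle"}.
#' @param rcaCopies concatemer passes per circle in RCA mode.
#' @param fetalProp fraction of circles of fetal origin (pregnancy).
#' @param fetalLaw size law of fetal circles (default: same as \code{law}).
#' @param seed mandatory seed.
#' @return a scenario config list.
#' @export
scenarioConfig <- function(genotype = "WT", law = NULL, nCircles = 500L,
                           backgroundPairs = 1000L, readLength = 75L,
                           coverage = 4L, errorRate = 1e-3,
                           library = "tagmentation", rcaCopies = 3L,
                           fetalProp = 0, fetalLaw = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  if (is.null(law)) law <- genotypeSizeLaw(genotype)
  stopifnot(library %in% LIBRARIES, fetalProp >= 0, fetalProp <= 1)
  list(genotype = genotype, law = law, nCircles = as.integer(nCircles),
       backgroundPairs = as.integer(backgroundPairs),
       readLength = as.integer(readLength), coverage = as.integer(coverage),
       errorRate = errorRate, library = library,
       rcaCopies = as.integer(rcaCopies), fetalProp = fetalProp,
       fetalLaw = if (is.null(fetalLaw)) law else fetalLaw,
       seed = as.integer(seed))
}

#' Default size law per mouse genotype
#'
#' Wild-type plasma eccDNA is dominated by the first (short) cluster
#' (w1 = 0.78); Dnase1l3 knockouts shift mass to the second cluster
#' (w1 = 0.30); Dnase1 knockouts behave like wild type.
#'
#' @param genotype one of the genotype vocabulary.
#' @return a \linkS4class{SizeLaw}.
#' @export
genotypeSizeLaw <- function(genotype = GENOTYPES) {
  genotype <- match.arg(genotype)
  switch(genotype,
         Dnase1l3_KO = sizeLaw(w1 = 0.30),
         sizeLaw(w1 = 0.78))
}

mutateBases <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit)
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

samLine <- function(qname, flag, rname, pos0, mapq, cigar, rnext, pnext0,
                    tlen, seq) {
  paste(qname, flag, rname, pos0 + 1L, mapq, cigar, rnext, pnext0 + 1L,
        tlen, seq, strrep("I", nchar(seq)), sep = "\t")
}

#' Emit pre-aligned reads for a circle population
#'
#' Writes a coordinate-sorted SAM file representing what an aligner would
#' report for junction-bearing libraries, so the calling pipeline is
#' testable without an external aligner:
#' \itemize{
#'   \item each circle yields junction fragments whose first read traverses
#'     the junction; the alignment representation is a soft-clipped split at
#'     the breakpoints (the longer arm aligned, the shorter soft-clipped),
#'     with the mate placed fully inside the circle on the reverse strand;
#'   \item rolling-circle mode emits \code{rcaCopies} times more junction
#'     reads per circle (concatemer passes hit the same junction
#'     repeatedly), raising support at identical breakpoints;
#'   \item linear background reads are concordant inward-facing pairs with a
#'     166 bp-centred fragment-length law;
#'   \item in pregnancy mode each circle carries a haplotype: reads of
#'     strain-B-haplotype molecules are drawn from the strain-B genome, so
#'     they expose paternal alleles at the strain SNPs.
#' }
#' Circles shorter than the read length produce no junction reads and are
#' recorded as undetectable in the truth log. Base errors are applied at the
#' configured rate. Identical seeds give byte-identical SAM output.
#'
#' @param circles \code{GRanges} truth set from \code{\link{sampleCircles}}.
#' @param genome strain-A \code{DNAStringSet}.
#' @param scenario list from \code{\link{scenarioConfig}}.
#' @param samPath output SAM path.
#' @param genomeB optional strain-B genome (pregnancy mode).
#' @param haplotype per-circle haplotype, "A" or "B" (default all "A").
#' @param truthPath optional JSON truth-log path.
#' @return invisibly, a truth list: per-circle table (coordinates, size,
#'   haplotype, junction-read count, detectable flag), background pair count
#'   and total mappable pair count.
#' @export
emitReads <- function(circles, genome, scenario, samPath, genomeB = NULL,
                      haplotype = NULL, truthPath = NULL) {
  R <- scenario$readLength
  if (is.null(haplotype)) haplotype <- rep("A", length(circles))
  stopifnot(length(haplotype) == length(circles))
  if (any(haplotype == "B") && is.null(genomeB))
    stop("strain-B haplotypes need genomeB")
  seqlens <- genomeSeqlengths(genome)
  withSeed(scenario$seed, {
    lines <- character(0)
    acc <- vector("list", 4096L); nacc <- 0L
    add <- function(chrom, pos0, line) {
      nacc <<- nacc + 1L
      if (nacc > length(acc)) length(acc) <<- 2L * nacc
      acc[[nacc]] <<- list(chrom, pos0, line)
    }
    njr <- integer(length(circles))
    nJuncPerCircle <- scenario$coverage *
      if (scenario$library == "rolling_circle") scenario$rcaCopies else 1L
    minPad <- 15L
    for (i in seq_along(circles)) {
      ch <- as.character(seqnames(circles))[i]
      s0 <- start(circles)[i] - 1L
      e0 <- end(circles)[i]
      L <- e0 - s0
      g <- if (haplotype[i] == "B") genomeB else genome
      if (L < R || R < 2L * minPad) next   # undetectable at this read length
      for (j in seq_len(nJuncPerCircle)) {
        qn <- sprintf("c%06d_j%03d", i, j)
        o <- sample(minPad:(R - minPad), 1L)   # bases before the junction
        readSeq <- paste0(getSeq0(g, ch, e0 - o, e0),
                          getSeq0(g, ch, s0, s0 + R - o))
        readSeq <- mutateBases(readSeq, scenario$errorRate)
        if (o >= R - o) { pos1 <- e0 - o; cig1 <- sprintf("%dM%dS", o, R - o) }
        else { pos1 <- s0; cig1 <- sprintf("%dS%dM", o, R - o) }
        st2 <- s0 + sample.int(L - R + 1L, 1L) - 1L
        mateSeq <- mutateBases(getSeq0(g, ch, st2, st2 + R),
                               scenario$errorRate)
        add(ch, pos1, samLine(qn, 97L, ch, pos1, 60L, cig1, "=", st2, 0L,
                              readSeq))
        add(ch, st2, samLine(qn, 145L, ch, st2, 60L, sprintf("%dM", R), "=",
                             pos1, 0L, mateSeq))
        njr[i] <- njr[i] + 1L
      }
    }
    ## linear background: concordant inward-facing pairs
    nb <- scenario$backgroundPairs
    if (nb > 0L) {
      bch <- sample(names(seqlens), nb, replace = TRUE,
                    prob = seqlens / sum(seqlens))
      fl <- pmax(100L, pmin(400L, as.integer(round(stats::rnorm(nb, 166, 20)))))
      for (i in seq_len(nb)) {
        ch <- bch[i]
        st <- sample.int(seqlens[[ch]] - fl[i], 1L) - 1L
        qn <- sprintf("bg%07d", i)
        p2 <- st + fl[i] - R
        s1 <- mutateBases(getSeq0(genome, ch, st, st + R), scenario$errorRate)
        s2 <- mutateBases(getSeq0(genome, ch, p2, p2 + R), scenario$errorRate)
        add(ch, st, samLine(qn, 99L, ch, st, 60L, sprintf("%dM", R), "=", p2,
                            fl[i], s1))
        add(ch, p2, samLine(qn, 147L, ch, p2, 60L, sprintf("%dM", R), "=", st,
                            -fl[i], s2))
      }
    }
    acc <- acc[seq_len(nacc)]
    ord <- order(match(vapply(acc, `[[`, "", 1L), names(seqlens)),
                 vapply(acc, `[[`, 0L, 2L))
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens),
                "@PG\tID:eccTools\tPN:eccTools")
    writeLines(c(header, vapply(acc[ord], `[[`, "", 3L)), samPath)
    truth <- list(
      circles = data.frame(
        circle_id = mcols(circles)$circle_id,
        chrom = as.character(seqnames(circles)),
        start0 = start(circles) - 1L,
        end0 = end(circles),
        size = width(circles),
        haplotype = haplotype,
        n_junction_reads = njr,
        detectable = njr > 0L),
      background_pairs = nb,
      mappable_pairs = sum(njr) + nb,
      library = scenario$library,
      seed = scenario$seed)
    if (!is.null(truthPath))
      jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA)
    invisible(truth)
  })
}

#' Preset end-to-end scenarios
#'
#' \code{wt}, \code{d1ko} and \code{d1l3ko} are single-genotype plasma
#' samples (Dnase1 knockout shares the wild-type law). The pregnancy presets
#' model maternal plasma of the three mating groups: \code{pregnancy_wtxwt}
#' (wild-type law), \code{pregnancy_koxko} (knockout law), and
#' \code{pregnancy_koxhet}, where fetal DNASE1L3 partially restores the
#' wild-type size law systemically (intermediate first-cluster weight
#' w1 = 0.55 applied to all molecules in maternal plasma). Pregnancy presets
#' use a 25\% fetal molecule proportion.
#'
#' @param name preset name.
#' @param seed mandatory seed.
#' @param ... overrides passed to \code{\link{scenarioConfig}}.
#' @return a scenario config list.
#' @export
scenarioPreset <- function(name = c("wt", "d1ko", "d1l3ko",
                                    "pregnancy_wtxwt", "pregnancy_koxko",
                                    "pregnancy_koxhet"), seed, ...) {
  name <- match.arg(name)
  base <- switch(name,
    wt     = list(genotype = "WT"),
    d1ko   = list(genotype = "Dnase1_KO"),
    d1l3ko = list(genotype = "Dnase1l3_KO"),
    pregnancy_wtxwt = list(genotype = "WT", fetalProp = 0.25),
    pregnancy_koxko = list(genotype = "Dnase1l3_KO", fetalProp = 0.25),
    pregnancy_koxhet = list(genotype = "Dnase1l3_KO", fetalProp = 0.25,
                            law = sizeLaw(w1 = 0.55)))
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(scenarioConfig, args)
}

#' Simulate a full sample for a preset scenario
#'
#' Builds (or reuses) a two-strain toy genome, samples maternal and —
#' in pregnancy scenarios — fetal circles, assigns fetal haplotypes
#' (A or B with equal probability, the heterozygous fetus), and emits the
#' aligned reads plus truth logs into \code{outDir}.
#'
#' @param scenario a config list from \code{\link{scenarioPreset}} or
#'   \code{\link{scenarioConfig}}.
#' @param outDir output directory (created).
#' @param genomeData optional result of \code{\link{makeGenome}} to reuse;
#'   generated from \code{scenario$seed} otherwise.
#' @return list: \code{sam}, \code{truth}, \code{circles} (GRanges with
#'   \code{origin_truth}), \code{genome} (the makeGenome list),
#'   \code{scenario}.
#' @export
simulateSample <- function(scenario, outDir, genomeData = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(genomeData))
    genomeData <- makeGenome(seed = scenario$seed, outDir = outDir)
  nFet <- as.integer(round(scenario$nCircles * scenario$fetalProp))
  nMat <- scenario$nCircles - nFet
  mat <- sampleCircles(genomeData$genomeA, scenario$law, nMat,
                       seed = scenario$seed + 1L)
  circles <- mat
  hap <- rep("A", nMat)
  originTruth <- rep("maternal", nMat)
  if (nFet > 0L) {
    fet <- sampleCircles(genomeData$genomeA, scenario$fetalLaw, nFet,
                         seed = scenario$seed + 2L)
    mcols(fet)$circle_id <- sprintf("fetal%06d", seq_len(nFet))
    circles <- c(mat, fet)
    hap <- c(hap, withSeed(scenario$seed + 3L,
                           sample(c("A", "B"), nFet, replace = TRUE)))
    originTruth <- c(originTruth, rep("fetal", nFet))
  }
  mcols(circles)$haplotype <- hap
  mcols(circles)$origin_truth <- originTruth
  samPath <- file.path(outDir, "reads.sam")
  truth <- emitReads(circles, genomeData$genomeA, scenario, samPath,
                     genomeB = genomeData$genomeB, haplotype = hap,
                     truthPath = file.path(outDir, "truth.json"))
  rtracklayer::export(circles, file.path(outDir, "truth_circles.bed"),
                      format = "bed")
  list(sam = samPath, truth = truth, circles = circles,
       genome = genomeData, scenario = scenario)
}
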
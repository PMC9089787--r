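test_that("a junction-spanning split read pins both breakpoints", {
  g <- tinyGenome(len = 20000L, seed = 7L)
  cfg <- callerConfig()
  ## truth circle [5000, 5350); read with 40 bases before the junction
  rec <- junctionRead(g, "chrT", 5000L, 5350L, o = 40L)
  sam <- tempfile(fileext = ".sam")
  writeSam(rec, c(chrT = 20000L), sam)
  fr <- readAlignments(sam, mapqMin = 0L)
  sig <- extractJunctionSignals(fr, g, cfg)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$evidence, "split_read")
  expect_equal(sig$left_bp, 5000L)
  expect_equal(sig$right_bp, 5350L)

  ## the prefix-clip representation (short arm before the junction) pins the
  ## same breakpoints
  rec2 <- junctionRead(g, "chrT", 5000L, 5350L, o = 20L, qname = "jr2")
  writeSam(rec2, c(chrT = 20000L), sam)
  sig2 <- extractJunctionSignals(readAlignments(sam, 0L), g, cfg)
  expect_equal(sig2$left_bp, 5000L)
  expect_equal(sig2$right_bp, 5350L)
})

test_that("concordant inward pairs and missing references are handled", {
  g <- tinyGenome()
  seqlens <- c(chrT = 20000L)
  ## fully concordant inward-facing pair: no signal
  recs <- rbind(
    samRecord("p1", 99L, "chrT", 1000L, "75M", seq0(g, "chrT", 1000, 1075),
              pnext = 1125L, tlen = 200L),
    samRecord("p1", 147L, "chrT", 1125L, "75M", seq0(g, "chrT", 1125, 1200),
              pnext = 1000L, tlen = -200L))
  sam <- tempfile(fileext = ".sam")
  writeSam(recs, seqlens, sam)
  sig <- extractJunctionSignals(readAlignments(sam, 0L), g, callerConfig())
  expect_equal(nrow(sig), 0L)

  ## unknown chromosome in the fragments -> explicit error
  fr <- readAlignments(sam, 0L)
  fr$chrom <- "chrMISSING"
  expect_error(extractJunctionSignals(fr, g, callerConfig()),
               "missing genome sequence")
})

test_that("outward-facing pairs bracket a circle", {
  g <- tinyGenome()
  seqlens <- c(chrT = 20000L)
  ## 200 bp circle [3000, 3200): leftmost mate reverse, rightmost forward
  recs <- rbind(
    samRecord("ow1", 81L, "chrT", 3000L, "75M",
              seq0(g, "chrT", 3000, 3075), pnext = 3125L, tlen = 200L),
    samRecord("ow1", 161L, "chrT", 3125L, "75M",
              seq0(g, "chrT", 3125, 3200), pnext = 3000L, tlen = -200L))
  sam <- tempfile(fileext = ".sam")
  writeSam(recs, seqlens, sam)
  sig <- extractJunctionSignals(readAlignments(sam, 0L), g, callerConfig())
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$evidence, "outward_pair")
  expect_equal(sig$left_bp, 3000L)
  expect_equal(sig$right_bp, 3200L)
  ## outward evidence alone does not pass a split-requiring caller
  expect_equal(length(callEccDNA(sig, callerConfig(requireSplit = TRUE))), 0L)
  expect_equal(length(callEccDNA(sig, callerConfig(requireSplit = FALSE))), 1L)
})

test_that("ambiguous clip placements are dropped and tallied", {
  ## genome with an exact 20 bp repeat so the clip matches twice
  unit <- "ACGTACGGTTCAGGCATGCA"
  mid <- paste(rep("T", 500), collapse = "")
  gseq <- paste0(strrep("GATC", 250), unit, mid, unit,
                 strrep("CTGA", 2000))
  g <- Biostrings::DNAStringSet(gseq); names(g) <- "chrT"
  len <- Biostrings::width(g)
  ## suffix-clipped read ending at a junction whose clip equals the repeat
  anchor0 <- 3000L
  readSeq <- paste0(seq0(g, "chrT", anchor0 - 55L, anchor0), unit)
  rec <- samRecord("amb1", 0L, "chrT", anchor0 - 55L, "55M20S", readSeq)
  sam <- tempfile(fileext = ".sam")
  writeSam(rec, c(chrT = len), sam)
  sig <- extractJunctionSignals(readAlignments(sam, 0L), g, callerConfig())
  expect_equal(nrow(sig), 0L)
  expect_equal(unname(attr(sig, "diagnostics")["ambiguous"]), 1L)
})

test_that("signals merge by breakpoint identity; duplicates never double-count", {
  sig <- data.frame(
    chrom = "chrT",
    left_bp = c(5000L, 5000L, 5000L),
    right_bp = c(5350L, 5350L, 5350L),
    evidence = "split_read",
    read_id = c("r1", "r2", "r2"))   # r2 appears twice (duplicate fragment)
  rec <- callEccDNA(sig, callerConfig())
  expect_equal(length(rec), 1L)
  expect_equal(eccSupport(rec), 2L)
  expect_equal(eccStarts(rec), 5000L)
  expect_equal(eccEnds(rec), 5350L)
  ## empty in, empty out
  expect_equal(length(callEccDNA(sig[0, ], callerConfig())), 0L)
  ## min_support filter
  expect_equal(length(callEccDNA(sig, callerConfig(minSupport = 3L))), 0L)
})

test_that("caller recovers simulated circles and respects size bounds", {
  td <- tempfile(); dir.create(td)
  scen <- scenarioConfig(nCircles = 100L, backgroundPairs = 200L, seed = 21L)
  sim <- simulateSample(scen, td)
  fr <- readAlignments(sim$sam, mapqMin = 30L)
  cfg <- callerConfig()
  sig <- extractJunctionSignals(fr, sim$genome$genomeA, cfg)
  rec <- callEccDNA(sig, cfg)
  sc <- scoreCalls(rec, sim$circles)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.99)
  ## every call inside the configured bounds; size == end - start
  expect_true(all(eccSizes(rec) >= cfg@minSize & eccSizes(rec) <= cfg@maxSize))
  expect_equal(eccSizes(rec), eccEnds(rec) - eccStarts(rec))
  ## sorted output
  expect_false(is.unsorted(eccStarts(rec)[as.character(seqnames(rec)) ==
                                          as.character(seqnames(rec))[1]]))
  ## deterministic for fixed input ordering
  rec2 <- callEccDNA(extractJunctionSignals(fr, sim$genome$genomeA, cfg), cfg)
  expect_identical(lociKeySet(rec), lociKeySet(rec2))
  ## true-positive calls carry exactly the generating sizes
  tk <- lociKeySet(sim$circles)
  expect_true(all(lociKeySet(rec)[lociKeySet(rec) %in% tk] %in% tk))
})

test_that("tagmentation and rolling-circle libraries agree on size structure", {
  gen <- makeGenome(seed = 31L)
  circ <- sampleCircles(gen$genomeA, sizeLaw(), 150L, seed = 32L)
  mcols(circ)$circle_id <- sprintf("c%04d", seq_along(circ))
  callFor <- function(lib, seed) {
    scen <- scenarioConfig(nCircles = length(circ), backgroundPairs = 0L,
                           library = lib, coverage = 2L, seed = seed)
    sam <- tempfile(fileext = ".sam")
    emitReads(circ, gen$genomeA, scen, sam)
    fr <- readAlignments(sam, 30L)
    callEccDNA(extractJunctionSignals(fr, gen$genomeA), callerConfig())
  }
  tag <- callFor("tagmentation", 33L)
  rca <- callFor("rolling_circle", 34L)
  ## concatemer passes raise support at identical breakpoints
  expect_gt(mean(eccSupport(rca)), mean(eccSupport(tag)))
  aucT <- clusterAUC(sizeProfile(tag))
  aucR <- clusterAUC(sizeProfile(rca))
  expect_lt(abs(aucT@auc1 - aucR@auc1), 5)
  expect_lt(abs(aucT@auc2 - aucR@auc2), 5)
})

test_that("dual-genome confirmation keeps loci callable under both strains", {
  ## identical and disjoint sets first
  a <- EccDNASet("chr1", c(0L, 100L), c(50L, 400L), support = 1L)
  b <- EccDNASet("chr1", c(0L, 100L), c(50L, 400L), support = 1L)
  expect_equal(lociKeySet(callDualGenome(a, b)), lociKeySet(a))
  d <- EccDNASet("chr1", 900L, 1200L, support = 1L)
  expect_equal(length(callDualGenome(a, d)), 0L)

  ## simulated sample with sparse SNPs away from breakpoints: calling under
  ## either strain genome then intersecting retains >= 99% of calls
  gen <- makeGenome(nSnps = 120L, seed = 41L)
  law <- sizeLaw()
  circ <- sampleCircles(gen$genomeA, law, 250L, seed = 42L)
  ## keep circles with no SNP within a read length of either breakpoint
  near <- function(p0) any(abs(gen$snps$pos - p0) <= 80L)
  ok <- !vapply(seq_along(circ), function(i) {
    sn <- gen$snps[gen$snps$chrom == as.character(seqnames(circ))[i], ]
    any(abs(sn$pos - (start(circ)[i] - 1L)) <= 80L) ||
      any(abs(sn$pos - end(circ)[i]) <= 80L)
  }, NA)
  circ <- circ[ok]
  mcols(circ)$circle_id <- sprintf("c%04d", seq_along(circ))
  hap <- withr_seed(43L, sample(c("A", "B"), length(circ), replace = TRUE))
  scen <- scenarioConfig(nCircles = length(circ), backgroundPairs = 0L,
                         errorRate = 0, seed = 44L)
  sam <- tempfile(fileext = ".sam")
  emitReads(circ, gen$genomeA, scen, sam, genomeB = gen$genomeB,
            haplotype = hap)
  fr <- readAlignments(sam, 30L)
  recA <- callEccDNA(extractJunctionSignals(fr, gen$genomeA), callerConfig())
  recB <- callEccDNA(extractJunctionSignals(fr, gen$genomeB), callerConfig())
  both <- callDualGenome(recA, recB)
  expect_gte(length(both) / length(recA), 0.99)
})
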
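## small two-haplotype world shared by the partition tests
partitionWorld <- function(nSnps = 400L, seed = 201L) {
  makeGenome(lengths = c(chrP = 50000L), nSnps = nSnps, seed = seed)
}

test_that("origin classification follows the allele rules", {
  gen <- partitionWorld()
  snps <- gen$snps
  ## a record covering no SNP is unassigned
  gapStart <- 0L
  repeat {  # find a 60 bp SNP-free window
    if (!any(snps$pos >= gapStart & snps$pos < gapStart + 60L)) break
    gapStart <- gapStart + 60L
  }
  recNone <- EccDNASet("chrP", gapStart, gapStart + 60L, support = 1L)
  res <- classifyOrigin(recNone, moleculeFragments(
    recNone, list(A = gen$genomeA), "A"), snps)
  expect_equal(res$origin, "unassigned")
  expect_equal(res$informative_snps_covered, 0L)

  ## a record whose read shows the strain-B allele is fetal-specific
  p <- snps$pos[10]
  recB <- EccDNASet("chrP", p - 20L, p + 40L, support = 1L)
  resB <- classifyOrigin(recB, moleculeFragments(
    recB, list(B = gen$genomeB), "B"), snps)
  expect_equal(resB$origin, "fetal_specific")
  expect_gte(resB$n_allele_B, 1L)
  expect_equal(resB$n_allele_A, 0L)

  ## the same interval read from strain A is shared
  resA <- classifyOrigin(recB, moleculeFragments(
    recB, list(A = gen$genomeA), "A"), snps)
  expect_equal(resA$origin, "shared")

  ## discordant consensus across two SNPs vetoes the call
  twoIx <- which(diff(snps$pos) < 200 & diff(snps$pos) > 10)[1]
  p1 <- snps$pos[twoIx]; p2 <- snps$pos[twoIx + 1L]
  recD <- EccDNASet("chrP", p1 - 10L, p2 + 10L, support = 1L)
  ## chimeric evidence: one read from each strain, clipped so each covers
  ## only one SNP
  fr <- rbind(
    moleculeFragments(EccDNASet("chrP", p1 - 10L, p1 + 5L, support = 1L),
                      list(A = gen$genomeA), "A"),
    moleculeFragments(EccDNASet("chrP", p2 - 5L, p2 + 10L, support = 1L),
                      list(B = gen$genomeB), "B"))
  fr$read_id <- c("rA", "rB")
  resD <- classifyOrigin(recD, fr, snps)
  expect_equal(resD$origin, "unassigned")
  expect_equal(resD$n_allele_A, 1L)
  expect_equal(resD$n_allele_B, 1L)

  ## a tied vote at one SNP makes the molecule unassigned
  frTie <- rbind(moleculeFragments(recB, list(A = gen$genomeA), "A"),
                 moleculeFragments(recB, list(B = gen$genomeB), "B"))
  frTie$read_id <- c("r1", "r2")
  expect_equal(classifyOrigin(recB, frTie, snps)$origin, "unassigned")
})

test_that("fetal_specific calls always carry strain-B observations", {
  gen <- partitionWorld(seed = 202L)
  rec <- sampleCircles(gen$genomeA, sizeLaw(), 300L, seed = 203L)
  hap <- withr_seed(204L, sample(c("A", "B"), 300L, replace = TRUE))
  recs <- EccDNASet(as.character(seqnames(rec)), start(rec) - 1L, end(rec),
                    support = 1L)
  fr <- moleculeFragments(recs, list(A = gen$genomeA, B = gen$genomeB), hap)
  mcols(recs)$read_ids <- IRanges::CharacterList(as.list(fr$read_id))
  lab <- partitionOrigins(recs, fr, gen$snps)
  ev <- metadata(lab)$origin_evidence
  fet <- origin(lab) == "fetal_specific"
  expect_true(all(ev$n_allele_B[fet] >= 1L))
  expect_true(all(ev$n_allele_B[origin(lab) == "shared"] == 0L))
  ## strain-B molecules never classify as shared and vice versa
  expect_true(all(origin(lab)[fet] %in% "fetal_specific"))
  expect_true(all(hap[fet] == "B"))
})

test_that("the fetal-fraction estimator behaves at its boundary cases", {
  expect_equal(fetalFraction(0, 100), 0)
  ## fully fetal sample: half the molecules carry the paternal allele
  expect_equal(fetalFraction(50, 50), 100)
  expect_equal(fetalFraction(25, 75, corrected = FALSE), 25)
  expect_equal(fetalFraction(25, 75, corrected = TRUE), 50)
  expect_error(fetalFraction(0, 0), "undefined")
})

test_that("fetal fraction is recovered from a simulated mixture", {
  gen <- partitionWorld(nSnps = 600L, seed = 205L)
  n <- 1500L; ffTrue <- 25
  nFet <- round(n * ffTrue / 100)
  hap <- c(rep("A", n - nFet),
           withr_seed(206L, sample(c("A", "B"), nFet, replace = TRUE)))
  circ <- sampleCircles(gen$genomeA, sizeLaw(), n, seed = 207L)
  recs <- EccDNASet(as.character(seqnames(circ)), start(circ) - 1L, end(circ),
                    support = 1L)
  fr <- moleculeFragments(recs, list(A = gen$genomeA, B = gen$genomeB), hap)
  mcols(recs)$read_ids <- IRanges::CharacterList(as.list(fr$read_id))
  lab <- partitionOrigins(recs, fr, gen$snps)
  nF <- sum(origin(lab) == "fetal_specific")
  nS <- sum(origin(lab) == "shared")
  ## fetal-specific count within a binomial 99% CI of its expectation
  covered <- origin(lab) != "unassigned"
  pB <- mean(hap[covered] == "B")
  expect_lt(abs(nF - sum(covered) * pB), 1e-9)  # classification is exact here
  est <- fetalFraction(nF, nS)
  expect_lt(abs(est - ffTrue), 3)
})

test_that("size profiles partition by origin label", {
  ## all unassigned: both profiles empty and flagged
  rec <- EccDNASet("chr1", c(0L, 10L), c(200L, 350L), support = 1L)
  pr <- partitionSizeProfiles(rec)
  expect_equal(nMolecules(pr$fetal_specific), 0L)
  expect_equal(nMolecules(pr$shared), 0L)

  ## shared size law: cluster AUCs agree within 3 percentage points
  szF <- sampleSizes(sizeLaw(), 3000L, seed = 208L)
  szS <- sampleSizes(sizeLaw(), 3000L, seed = 209L)
  rec2 <- EccDNASet("chr1", s <- seq_len(6000L) * 10L,
                    s + c(szF, szS), support = 1L,
                    origin = rep(c("fetal_specific", "shared"), each = 3000L))
  pr2 <- partitionSizeProfiles(rec2)
  aF <- clusterAUC(pr2$fetal_specific); aS <- clusterAUC(pr2$shared)
  expect_lt(abs(aF@auc1 - aS@auc1), 3)
  expect_lt(abs(aF@auc2 - aS@auc2), 3)

  ## a planted -50 bp fetal shift lowers the fetal AUC ratio
  szF3 <- sampleSizes(sizeLaw(mu = c(152, 288)), 3000L, seed = 210L)
  rec3 <- EccDNASet("chr1", s, s + c(szF3, szS), support = 1L,
                    origin = rep(c("fetal_specific", "shared"), each = 3000L))
  pr3 <- partitionSizeProfiles(rec3)
  expect_lt(aucRatio(clusterAUC(pr3$fetal_specific)),
            aucRatio(clusterAUC(pr3$shared)))
})
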
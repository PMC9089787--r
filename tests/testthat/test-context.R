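test_that("expected-locus simulation matches its sampling law", {
  ## single 1000 bp chromosome, all sizes 100: starts uniform on [0, 900]
  sim <- simulateExpectedLoci(c(chr1 = 1000L), rep(100L, 10), 4000L, seed = 81L)
  expect_equal(length(sim), 4000L)
  expect_true(all(width(sim) == 100L))
  st <- start(sim) - 1L
  expect_true(all(st >= 0 & st + 100 <= 1000))
  ks <- suppressWarnings(stats::ks.test(st + runif(length(st)), "punif",
                                        0, 901))
  expect_gt(ks$p.value, 0.01)

  ## chromosomes drawn proportionally to length: fraction on the 2L
  ## chromosome within a binomial 99% CI of 2/3
  sim2 <- simulateExpectedLoci(c(c1 = 50000L, c2 = 100000L), rep(100L, 5),
                               1e5, seed = 82L)
  frac <- mean(as.character(seqnames(sim2)) == "c2")
  ci <- 2.58 * sqrt(2 / 9 / 1e5)
  expect_lt(abs(frac - 2 / 3), ci + 0.002)  # small edge-redraw allowance

  ## impossible sizes error
  expect_error(simulateExpectedLoci(c(chr1 = 1000L), 5000L, 10L),
               "exceeds every chromosome")
})

test_that("expected frequencies converge with the simulation size", {
  gen <- makeGenome(seed = 83L)
  sizes <- sampleSizes(sizeLaw(), 500L, seed = 84L)
  f <- function(n, seed) {
    sim <- simulateExpectedLoci(gen$genomeA, sizes, n, seed = seed)
    vapply(names(gen$elements), function(cl)
      mean(countOverlaps(sim, gen$elements[[cl]]) > 0L), 0)
  }
  e1 <- f(50000L, 85L)
  e2 <- f(100000L, 86L)
  expect_true(all(abs(e1 - e2) < 0.005))
})

test_that("element enrichment is 1 under the null and for full coverage", {
  gen <- makeGenome(seed = 91L)
  sizes <- sampleSizes(sizeLaw(), 1000L, seed = 92L)
  simA <- simulateExpectedLoci(gen$genomeA, sizes, 50000L, seed = 93L)
  simB <- simulateExpectedLoci(gen$genomeA, sizes, 50000L, seed = 94L)
  ## observed loci drawn by the null simulator itself: fold change near 1
  enr <- elementEnrichment(simA, gen$elements, simB)
  expect_true(all(enr$fold_change > 0.9 & enr$fold_change < 1.1))

  ## elements covering the whole genome: all frequencies 1
  sl <- setNames(width(gen$genomeA), names(gen$genomeA))
  whole <- GRangesList(gene_body = GRanges(names(sl), IRanges(1L, sl)))
  enrW <- elementEnrichment(simA, whole, simB)
  expect_equal(enrW$observed_freq, 1)
  expect_equal(enrW$expected_freq, 1)
  expect_equal(enrW$fold_change, 1)

  expect_error(elementEnrichment(simA, gen$elements, GRanges()), "empty")
  ## the percent-increase reporting convention
  expect_equal(foldChangeIncrease(1.0, 1.53), 53)
})

test_that("shared-locus counting is exact, symmetric and monotone", {
  a <- EccDNASet("chr1", c(0L, 100L, 200L), c(50L, 150L, 260L), support = 1L)
  b <- EccDNASet("chr1", c(100L, 200L, 300L), c(150L, 260L, 360L), support = 1L)
  res <- sharedLoci(a, b)
  expect_equal(res$n_shared, 2L)
  expect_equal(sharedLoci(b, a)$n_shared, res$n_shared)   # symmetry
  ## removing loci never increases the shared count
  expect_lte(sharedLoci(a[1:2], b)$n_shared, res$n_shared)
  ## identical sets share 100%
  resAA <- sharedLoci(a, a)
  expect_equal(resAA$pct_of_a, 100)
  expect_equal(resAA$pct_of_b, 100)
  ## empty set: NA percentage with a warning
  expect_warning(r0 <- sharedLoci(a[0], b), "empty")
  expect_true(is.na(r0$pct_of_a))
})

test_that("junction motifs are extracted with inside/outside orientation", {
  g <- Biostrings::DNAStringSet("AAACCCGGGTTTAAACCCGGGTTT")
  names(g) <- "chrM"
  rec <- EccDNASet("chrM", 6L, 15L, support = 1L)
  m <- junctionMotifs(rec, g, topK = 5L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$motif_i, "CCC")    # outside, upstream of the start
  expect_equal(m$motif_ii, "GGG")   # inside at the start
  expect_equal(m$motif_iii, "AAA")  # inside at the end
  expect_equal(m$motif_iv, "CCC")   # outside, downstream of the end
  expect_equal(m$count, 1L)
  expect_equal(m$rank, 1L)

  ## records within 3 bp of a chromosome edge are skipped but tallied
  rec2 <- EccDNASet("chrM", c(6L, 1L), c(15L, 10L), support = 1L)
  m2 <- junctionMotifs(rec2, g)
  expect_equal(attr(m2, "skipped"), 1L)
  expect_equal(attr(m2, "n_counted") + attr(m2, "skipped"), 2L)
})

test_that("a planted junction motif ranks first", {
  gen <- makeGenome(seed = 95L)
  g <- gen$genomeA
  len <- width(g)[1]
  ## plant circles whose breakpoints all sit immediately after "CCATCC"-style
  ## context: pick positions and force identical flanks by construction
  withr_seed(96L, {
    starts <- sample(2000:(len - 3000), 60)
  })
  sizes <- sampleSizes(sizeLaw(), 60L, seed = 97L)
  ## rewrite the genome so every breakpoint shares one motif combination
  chseq <- as.character(g[[1]])
  for (i in seq_along(starts)) {
    s0 <- starts[i]; e0 <- starts[i] + sizes[i]
    substr(chseq, s0 - 2, s0 + 3) <- "CCATCC"
    substr(chseq, e0 - 2, e0 + 3) <- "GGATGG"
  }
  g2 <- Biostrings::DNAStringSet(chseq); names(g2) <- names(g)[1]
  rec <- EccDNASet(names(g2), starts, starts + sizes, support = 1L)
  m <- junctionMotifs(rec, g2, topK = 3L)
  expect_equal(m$motif_ii[1], "TCC")
  expect_equal(m$motif_iii[1], "GGA")
  expect_gte(m$count[1], 30L)   # collisions can rewrite a few flanks
  expect_equal(m$rank, seq_len(nrow(m)))
})
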
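#' Pipeline run configuration
#'
#' @param scenarios character vector of scenario preset names (see
#'   \code{\link{scenarioPreset}}); each becomes one sample group.
#' @param nSamples samples per scenario.
#' @param nCircles circles per sample.
#' @param backgroundPairs linear background read pairs per sample.
#' @param caller a \linkS4class{CallerConfig}.
#' @param window1,window2 peak-cluster AUC windows, bp.
#' @param nSim Monte-Carlo loci for expected element frequencies.
#' @param topMotifs junction motif combinations to report.
#' @param library library style for the simulator.
#' @param seed master seed; all per-sample seeds derive from it.
#' @param outDir run directory.
#' @return config list (serializable to JSON and archived with the run).
#' @export
pipelineConfig <- function(scenarios = "wt", nSamples = 3L, nCircles = 300L,
                           backgroundPairs = 500L, caller = callerConfig(),
                           window1 = c(150L, 250L), window2 = c(300L, 450L),
                           nSim = 20000L, topMotifs = 5L,
                           library = "tagmentation", seed = 1L,
                           outDir = tempfile("eccrun")) {
  list(scenarios = scenarios, nSamples = as.integer(nSamples),
       nCircles = as.integer(nCircles),
       backgroundPairs = as.integer(backgroundPairs), caller = caller,
       window1 = window1, window2 = window2, nSim = as.integer(nSim),
       topMotifs = as.integer(topMotifs), library = library,
       seed = as.integer(seed), outDir = outDir)
}

serializableConfig <- function(config) {
  cc <- config$caller
  config$caller <- list(minSize = cc@minSize, maxSize = cc@maxSize,
                        minSoftclip = cc@minSoftclip,
                        minSupport = cc@minSupport,
                        requireSplit = cc@requireSplit, mapqMin = cc@mapqMin)
  config$version <- as.character(utils::packageVersion("eccTools"))
  config
}

#' Run the full eccDNA pipeline on simulated scenarios
#'
#' Orchestrates simulate -> call -> profile -> AUC -> enrich -> motifs ->
#' (partition) -> stats into a reproducible run directory. Per sample:
#' read alignments, extract junction signals, call loci, write a BED, and
#' compute EPM and cluster AUCs; per scenario: pooled size profile (plot +
#' TSV), element enrichment against the Monte-Carlo expectation, junction
#' motifs, and — for pregnancy scenarios — origin partitioning with fetal
#' fractions (raw and corrected). Across scenarios, per-sample AUC ratios
#' are compared with the Kruskal-Wallis test plus Dunn post hoc (>= 3
#' groups) or the Wilcoxon rank-sum test (2 groups). The exact config and
#' package version are archived as config.json; a structured log records
#' stage timings and record counts. Identical config and seed reproduce the
#' summary exactly.
#'
#' @param config from \code{\link{pipelineConfig}}.
#' @return (invisibly) list: \code{summary} data.frame (one row per sample:
#'   EPM, auc1, auc2, auc_ratio, fetal fractions where applicable),
#'   \code{pooled} per-scenario results, \code{stats} the group test, and
#'   \code{outDir}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(serializableConfig(config),
                       file.path(config$outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logPath <- file.path(config$outDir, "run.log")
  logLine <- function(...) cat(sprintf("[%s] %s\n",
                                       format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)),
                               file = logPath, append = TRUE)
  rows <- list()
  pooled <- list()
  aucBySc <- list()
  for (si in seq_along(config$scenarios)) {
    sc <- config$scenarios[si]
    genomeSeed <- config$seed + 100000L * si
    genomeData <- makeGenome(seed = genomeSeed)
    allRecs <- NULL
    aucs <- numeric(0)
    for (s in seq_len(config$nSamples)) {
      t0 <- proc.time()[["elapsed"]]
      sampleSeed <- config$seed + 100000L * si + 100L * s
      scen <- scenarioPreset(sc, seed = sampleSeed,
                             nCircles = config$nCircles,
                             backgroundPairs = config$backgroundPairs,
                             library = config$library)
      sdir <- file.path(config$outDir, sprintf("%s_s%02d", sc, s))
      sim <- simulateSample(scen, sdir, genomeData = genomeData)
      frag <- readAlignments(sim$sam, mapqMin = config$caller@mapqMin)
      mappable <- metadata(frag)$mappable_reads
      sig <- extractJunctionSignals(frag, genomeData$genomeA, config$caller)
      meta <- sampleMeta(sprintf("%s_s%02d", sc, s), genotype = scen$genotype,
                         library = if (scen$library == "tagmentation")
                           "tagmentation" else "rolling_circle",
                         mappableReads = mappable)
      rec <- callEccDNA(sig, config$caller, sample = meta)
      writeRecordsBed(rec, file.path(sdir, "loci.bed"))
      epm <- if (mappable > 0) computeEPM(length(rec), mappable) else NA_real_
      prof <- if (length(rec)) sizeProfile(rec) else
        suppressWarnings(sizeProfile(integer(0)))
      writeProfileTsv(prof, file.path(sdir, "profile.tsv"))
      auc <- clusterAUC(prof, config$window1, config$window2)
      ffRaw <- ffCorr <- NA_real_
      if (scen$fetalProp > 0) {
        rec <- partitionOrigins(rec, frag, genomeData$snps)
        writeRecordsBed(rec, file.path(sdir, "loci_labeled.bed"))
        nF <- sum(origin(rec) == "fetal_specific")
        nS <- sum(origin(rec) == "shared")
        if (nF + nS > 0) {
          ffRaw <- fetalFraction(nF, nS, corrected = FALSE)
          ffCorr <- fetalFraction(nF, nS, corrected = TRUE)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, sample = meta@sampleId, genotype = scen$genotype,
        n_loci = length(rec), mappable_reads = mappable, epm = epm,
        auc1 = auc@auc1, auc2 = auc@auc2, auc_ratio = auc@aucRatio,
        ff_raw = ffRaw, ff_corrected = ffCorr)
      aucs <- c(aucs, auc@aucRatio)
      allRecs <- if (is.null(allRecs)) rec else c(allRecs, rec)
      logLine("%s sample %d: %d loci from %d pairs (%.1fs)", sc, s,
              length(rec), mappable, proc.time()[["elapsed"]] - t0)
    }
    ## pooled, per scenario
    pooledProf <- if (length(allRecs)) sizeProfile(allRecs) else
      suppressWarnings(sizeProfile(integer(0)))
    writeProfileTsv(pooledProf,
                    file.path(config$outDir, sprintf("%s_pooled_profile.tsv", sc)))
    grDevices::png(file.path(config$outDir,
                             sprintf("%s_pooled_profile.png", sc)),
                   width = 800, height = 400)
    plotSizeProfile(pooledProf, config$window1, config$window2,
                    main = sprintf("%s pooled size profile", sc))
    grDevices::dev.off()
    pooledAuc <- clusterAUC(pooledProf, config$window1, config$window2)
    enr <- motifs <- NULL
    if (length(allRecs)) {
      simLoci <- simulateExpectedLoci(genomeData$genomeA, allRecs,
                                      config$nSim,
                                      seed = config$seed + 7L * si)
      enr <- elementEnrichment(allRecs, genomeData$elements, simLoci)
      utils::write.table(enr, file.path(config$outDir,
                                        sprintf("%s_enrichment.tsv", sc)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      motifs <- junctionMotifs(allRecs, genomeData$genomeA,
                               topK = config$topMotifs)
      utils::write.table(motifs, file.path(config$outDir,
                                           sprintf("%s_motifs.tsv", sc)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    pooled[[sc]] <- list(profile = pooledProf, auc = pooledAuc,
                         enrichment = enr, motifs = motifs,
                         records = allRecs)
    aucBySc[[sc]] <- aucs
    logLine("%s pooled: %d loci, AUC ratio %s", sc,
            length(allRecs),
            format(pooledAuc@aucRatio, digits = 3))
  }
  summary <- do.call(rbind, rows)
  utils::write.table(summary, file.path(config$outDir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stats <- NULL
  groups <- lapply(aucBySc, function(v) v[!is.na(v)])
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) >= 3L) stats <- dunnPosthoc(groups)
  else if (length(groups) == 2L)
    stats <- wilcoxonRankSum(groups[[1]], groups[[2]])
  invisible(list(summary = summary, pooled = pooled, stats = stats,
                 outDir = config$outDir))
}
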
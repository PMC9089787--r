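# eccTools

Detection and fragmentomic analysis of cell-free extrachromosomal
circular DNA (eccDNA) from paired-end sequencing alignments.

## The problem

Plasma cell-free DNA contains, besides the dominant ~166 bp linear
fragments, a minor population of small chromosome-derived circles
(eccDNA). Their size distribution is bimodal — peak clusters summiting
near 202 bp and 338 bp, with 10 bp periodic subpeaks — and is reshaped by
circulating nucleases: animals deficient in DNASE1L3 accumulate longer
plasma eccDNA, and DNASE1L3 produced by a fetus can act systemically on
eccDNA in the maternal circulation. Quantifying these effects requires a
pipeline that (i) identifies circles at base resolution from junction
evidence, (ii) summarizes abundance and size structure, (iii) places
circles in genomic context, (iv) partitions maternal from fetal molecules
with strain-informative SNPs, and (v) tests group contrasts
nonparametrically. `eccTools` implements all five stages for analysts
working with such data, plus a deterministic synthetic-data generator so
the whole pipeline is testable without animal sequencing data.

## Core statistics and algorithms

* **Junction calling** — a split read whose soft-clipped arm (≥ 10 bp)
  realigns exactly at the opposite boundary pins a circle's breakpoints
  `(left, right)` at base resolution; outward-facing read pairs
  corroborate. Loci merge by exact breakpoint identity, with support =
  number of distinct fragments. One locus = one eccDNA species.
* **Abundance** — EPM = n_eccDNA / mappable read pairs x 10^6.
* **Size structure** — 1 bp resolution profiles (percent of molecules per
  size); cluster AUCs over 150–250 bp and 300–450 bp (inclusive); the
  AUC ratio AUC2/AUC1 as the size-shift statistic (higher = longer
  eccDNA).
* **Genomic context** — element enrichment as observed/expected overlap
  frequency, the expectation from Monte-Carlo loci (length-proportional
  chromosome, uniform start, sizes resampled from the observed sizes);
  junctional trinucleotide motifs I–IV anchored inside/outside both
  breakpoints; shared-locus percentages between samples.
* **Fetal/maternal partitioning** — molecules showing a paternal-strain
  allele at a covered SNP (majority vote across supporting reads,
  discordance vetoes) are fetal-specific; fetal fraction
  FF = 100 x 2·n_fetal / (n_fetal + n_shared), the factor 2 because a
  heterozygous fetus shows the paternal allele on only half its
  molecules.
* **Group tests** — tie-corrected Kruskal–Wallis, Dunn post hoc (Holm
  adjustment by default), Wilcoxon rank-sum with an exact enumeration
  branch for small tie-free samples.

## Worked example

Simulate a Dnase1l3-knockout plasma sample, call circles, and summarize:

```r
library(eccTools)

td <- tempfile("demo"); dir.create(td)
scen <- scenarioPreset("d1l3ko", seed = 7, nCircles = 300,
                       backgroundPairs = 500)
sim <- simulateSample(scen, td)                  # SAM + truth logs
fr  <- readAlignments(sim$sam, mapqMin = 30)
mappable <- S4Vectors::metadata(fr)$mappable_reads

sig <- extractJunctionSignals(fr, sim$genome$genomeA, callerConfig())
rec <- callEccDNA(sig, callerConfig(),
                  sample = sampleMeta("d1l3ko_1", "Dnase1l3_KO",
                                      mappableReads = mappable))
length(rec)                                   # 300 loci (all truth circles)
computeEPM(length(rec), mappable)             # 176470.6
clusterAUC(sizeProfile(rec))
#> ClusterAUC: AUC[150-250] = 30.3%, AUC[300-450] = 59.7%, ratio = 1.97
```

All 300 simulated circles are recovered at exact coordinates. The
knockout scenario's AUC ratio (1.97) reflects its long-shifted size law;
the wild-type law under the same settings gives a ratio of 0.25
(first cluster 73.3%), reproducing the qualitative knockout-vs-wild-type
contrast. (EPM is large here only because the toy sample has 1,700 read
pairs rather than millions.)

`runPipeline(pipelineConfig(scenarios = c("wt", "d1l3ko"), seed = 1))`
orchestrates the same steps over multiple samples and scenarios into a
run directory with per-sample BEDs and profiles, pooled profiles and
plots, element enrichment, junction motifs, fetal fractions for
pregnancy scenarios, a `summary.tsv`, and the archived `config.json`.
A command-line wrapper lives at `inst/scripts/eccpipe.R`.

See the methods vignette (`vignettes/eccdna-methods.Rmd`) for the models,
parameter choices, and what the synthetic data do and do not emulate.

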
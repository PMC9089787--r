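---
title: "Methods: junction-based eccDNA detection and fragmentomics"
author: "eccTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-based eccDNA detection and fragmentomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccTools)
```

## The problem

Cell-free DNA in plasma is mostly linear (modal size ~166 bp), but a
minority of molecules are extrachromosomal circular DNA (eccDNA): small
circles excised from chromosomal sequence. Plasma eccDNA has a
characteristic bimodal size distribution, with peak clusters summiting
near 202 bp and 338 bp and sharp 10 bp periodic subpeaks within each
cluster, suggesting nucleosomal involvement in their biogenesis. The
circulating nuclease DNASE1L3 degrades eccDNA extracellularly: animals
lacking it accumulate longer plasma eccDNA, and fetally produced DNASE1L3
can shorten eccDNA in the maternal circulation. `eccTools` implements the
computational side of this biology: junction-based circle detection from
paired-end alignments, abundance and size-profile statistics, genomic
context analyses, strain-SNP fetal/maternal partitioning for the mouse
pregnancy model, and the nonparametric group comparisons used to contrast
genotypes — together with a synthetic-data generator that stands in for
animal sequencing data.

## Junction detection

A circle [start, end) betrays itself in two ways in an alignment file.

**Split reads.** A read traversing the junction aligns with one arm matched
and the other soft-clipped. `extractJunctionSignals()` takes every primary
alignment with a soft clip of at least `minSoftclip` bases (default 10) and
realigns the clipped sequence by exact string match on the same chromosome
and strand, inside a window of the candidate breakpoint ± 1 kb extended by
`maxSize` on the side where the partner breakpoint may lie. A suffix clip
whose clipped sequence matches *upstream* of the matched block's end — so
the sequence leaves the locus end and continues from the locus start — pins
(left, right) at base resolution; a prefix clip is the mirror case. Clips
with two or more exact placements in the window are ambiguous and are
dropped into a diagnostics tally rather than guessed at; placements
inconsistent with circular traversal are tallied separately. Exact matching
(no mismatches) keeps the operator deterministic; it costs sensitivity on
reads whose clipped arm carries a sequencing error, which support from
additional junction reads absorbs.

**Outward-facing pairs.** Both mates on the same chromosome, leftmost mate
on the reverse strand and rightmost on the forward strand, are the
read-pair signature of a fragment spanning the junction. These only
bracket the breakpoints (the implied size comes from the template length),
so by default (`requireSplit = TRUE`) they corroborate split-read loci
rather than founding loci of their own.

`callEccDNA()` merges signals with identical (chrom, left, right) into one
locus — one locus is one eccDNA species, the counting unit everywhere —
with support equal to the number of *distinct* read ids, so duplicate
fragments and rolling-circle concatemer passes never double-count a
molecule but do raise support. Loci are filtered by support, size window
and (optionally) split-read evidence, and emerge coordinate-sorted.
Rolling-circle libraries need no special handling at the locus level:
concatemer reads hit the same junction repeatedly and simply raise
support.

Internally all coordinates are 0-based half-open, so a circle's size is
`end − start` and equals the BED arithmetic; 1-based conventions (SAM,
SNP tables) are converted at the parsers. Records serialize as BED6+2
(name = sample, score = support, extra columns size and origin).

The dual-genome confirmation of the pregnancy model — keeping only loci
identified under both strain references — is an exact coordinate
intersection (`callDualGenome()`), valid because the synthetic strain
genomes are colinear; real strain assemblies would need liftover, which is
out of scope.

## Abundance and size statistics

Abundance is reported as eccDNA per million mappable reads,
`EPM = n / mappable_reads × 1e6`, with the mappable-read count taken as
the number of read pairs whose mates both pass the MAPQ filter (default
30 — the original protocol states only "mappable reads", so the
uniqueness proxy is configurable).

Size profiles (`sizeProfile()`) are per-1-bp percentage histograms over
[0, 1000] bp by default; the 1 bp bin is what resolves the 10 bp
subpeaks. Pooling samples is concatenation of record sets before
profiling. `clusterAUC()` sums the profile inside the first (150–250 bp)
and second (300–450 bp) peak-cluster windows, inclusive on both ends; the
inter-cluster gap (251–299 bp) belongs to neither, which is why the two
AUCs do not sum to 100. The AUC ratio (second/first) is the headline
size-shift statistic — higher means longer eccDNA. A zero first-cluster
AUC makes the ratio undefined; it is reported as missing, never infinity,
and excluded from group tests. Ratios are conventionally quoted at 2
decimals; arithmetic is full precision. Per-sample profiles feed dot
plots and group tests; pooled profiles feed the figures — both are
exposed, since the choice is not dictated by the statistics.

## Genomic context

Element enrichment compares the fraction of eccDNA loci overlapping an
element class (5′ UTR, 3′ UTR, gene body, CpG island, repeat) with the
same fraction computed on Monte-Carlo loci: chromosome drawn
proportional to length, start uniform, size resampled with replacement
from the observed sizes so the null controls for the size-dependence of
overlap probability, and loci running off a chromosome end redrawn.
Overlap means ≥ 1 bp intersection of the circle interval (the published
analysis does not state its criterion; junction-point containment is the
conceivable alternative and the interval rule is the package's choice).
Fold change is observed/expected frequency, missing if the expected
frequency is zero; contrasts between samples are reported as percent
increases, `100 × (fcB − fcA)/fcA`.

Junctional motifs are the four trinucleotides anchored at the
breakpoints: I = [start−3, start) outside-upstream, II = [start, start+3)
inside at the start, III = [end−3, end) inside at the end,
IV = [end, end+3) outside-downstream. Circles are unstranded, so motifs
read from the reference forward strand; loci within 3 bp of a chromosome
edge are excluded and tallied. Combinations are ranked by count with
lexicographic tie-breaks.

## Strain partitioning and fetal fraction

With a strain-A (C57BL/6-like) mother and a strain-B (BALB/c-like)
father, the fetus is heterozygous at every strain-discriminating SNP. A
molecule showing a strain-B allele at any covered SNP, with no
contradicting observation, is fetal-specific; one showing only strain-A
alleles is shared (maternal molecules plus the maternal-haplotype half of
fetal molecules); molecules covering no SNP, or with discordant evidence,
are unassigned. Conflicting base observations at one SNP are resolved by
majority vote across the locus's supporting reads, ties vetoing the call
— a deterministic, conservative rule in place of probabilistic
genotyping; base qualities are not weighted (extension point, not a
default).

Because only half the fetal molecules carry the paternal allele, the
fetal fraction doubles the fetal-specific count:
`FF = 100 × 2·n_fetal / (n_fetal + n_shared)`. The published analysis
states fractions without a formula, so both the corrected and the raw
proportion are reported; the corrected estimator is unbiased on
simulated mixtures across true fractions of 10–40%, which the acceptance
suite checks within ±3 percentage points at n = 5,000 molecules.

## Group statistics

The genotype contrasts use the Kruskal–Wallis test (H on mid-ranks with
the standard tie correction, chi-square reference with k−1 df) followed by
Dunn's multiple-comparison z tests on the pooled mid-ranks, and the
two-sided Wilcoxon rank-sum test for two groups, with an exact
enumeration branch when the smaller sample has ≤ 8 values and there are
no ties, otherwise a tie-corrected normal approximation with continuity
correction. These are implemented from the rank formulas rather than
wrapped, because tie handling and the exact branch are part of the
contract; base R's `kruskal.test`/`wilcox.test` serve as independent
cross-checks in the test suite. The original analyses used Prism, whose
Dunn adjustment is not stated; Holm is the default here (it dominates
Bonferroni and is deterministic), with Bonferroni and no adjustment
selectable. All tests are two-sided with significance at 0.05.
Degenerate inputs (all values tied) yield an undefined statistic with
p = 1 rather than an error.

## The synthetic-data generator

The generator emulates the features of the study data that the pipeline's
correctness depends on, and nothing more:

* **Size law** (`sizeLaw()`): a two-Gaussian mixture with means 202 and
  338 bp (the reported summit positions) and standard deviations 30 and
  40 bp, thinned by a 10 bp comb (sizes congruent to the comb phase kept
  with probability 1, others with probability 1 − depth, default 0.5),
  floored at 50 bp. The genotype presets set the first-cluster weight to
  0.78 for wild type and Dnase1 knockout and 0.30 for Dnase1l3 knockout,
  echoing the published median first-cluster AUCs (77.9% vs 30.3%) —
  scenario parameters, not claims about the original data. The
  `pregnancy_koxhet` preset uses an intermediate weight of 0.55, chosen
  a priori as a mid-grid value between the two laws to model the partial
  restoration produced by fetal DNASE1L3 acting systemically on maternal
  plasma.
* **Genomes**: random-sequence chromosomes (default 300 kb + 200 kb,
  GC 0.42), planted non-overlapping element intervals per class with
  recorded achieved fractions, and a colinear strain-B genome differing
  from strain A only at the emitted SNP positions (default 2,000 SNPs,
  roughly one per 250 bp — far denser per base than the real
  inter-strain SNP set is sparse, because the toy genome is four orders
  of magnitude smaller).
* **Reads** (`emitReads()`): junction fragments rendered exactly as an
  aligner would report them — soft-clipped splits at the breakpoints with
  the longer arm matched — plus inward-facing concordant background pairs
  (166 ± 20 bp fragments), per-base substitution errors (default 1e-3),
  tagmentation vs rolling-circle modes (the latter multiplying junction
  reads per circle), and haplotype-aware sequences over the strain SNPs
  in pregnancy mode (fetal molecules drawn from either haplotype with
  equal probability). Emitting pre-aligned SAM makes the pipeline
  testable with no aligner and no binary fixtures; circles shorter than
  the read length are recorded as undetectable in the truth log.

All randomness flows from one mandatory seed, with derived per-stage
seeds, so any stage reproduces byte-identically in isolation.

What the generator does *not* emulate — mapping ambiguity from genuine
repeats, indels and structural differences between real strain genomes,
PCR duplicates, realistic quality-dependent error profiles, chimeric
multi-fragment circles — bounds what passing tests show: they validate
the operators' logic and statistics under clean alignments, not
robustness to the full messiness of real libraries.

## Numerical choices and problem sizes

Simulation scales in the tests and acceptance script are chosen for a
desk-scale laptop run: 500-circle samples for caller scoring, 5,000
molecules for fetal-fraction recovery, 4,000 sizes per grid point for
the AUC-ratio monotonicity check, 1e5 Monte-Carlo loci for the
enrichment null, and 2,000 replicates for type-I-error calibration.
Kolmogorov–Smirnov comparisons of integer size samples jitter both
samples uniformly on ±0.5 to remove discreteness before the continuous
test. Ties in motif ranking break lexicographically; ties in rank tests
use mid-ranks. Degenerate inputs are flagged (empty profiles), reported
as missing (undefined AUC ratios), or vetoed (tied SNP votes) rather
than silently repaired.

## Known limitations

Single-fragment circles only (no chimeric or multi-locus circles, no
mitochondrial or megabase cancer ecDNA); exact-match clip realignment
(mismatch-tolerant realignment is a config extension, not implemented);
exact-coordinate locus identity (no fuzzy merging of near-identical
breakpoints); colinear strain genomes only; no CRAM, no remote fetch,
no liftover.
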
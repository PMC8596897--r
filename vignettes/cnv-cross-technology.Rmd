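---
title: "Cross-technology characterization of CNV callsets: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-technology characterization of CNV callsets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(cnvtriad)
```

## The problem

Copy number variants (CNVs) — deletions and duplications of genomic
segments — are called from three very different data types: SNP-array
probe intensities, short-read sequencing and long-read sequencing. Each
technology has its own size range, breakpoint precision, false-call
profile and caller-specific scores, and callsets for the same genome
disagree substantially. `cnvtriad` implements a reference-free way to
characterize such a heterogeneous collection for one individual: instead
of comparing every callset to a gold standard, it (i) collapses
redundant calls into non-redundant regions and loci, stratified by an
objective quality score, and (ii) goes back to the raw data of *every*
technology to ask whether each region is supported there.

## Pipeline model

**Per-call preparation.** Calls of 500 bp or less are discarded
(strictly greater-than, matching the convention of keeping only calls
"> 500 bp"), as is any call overlapping an exclusion region
(telomeres, centromeres, blacklisted intervals) by at least one
basepair. Every surviving call receives two duphold-style depth fold
changes computed from a binned short-read depth track:

* **DHFFC** — median per-basepair depth inside the call divided by the
  median over two 1-kb flanking windows pooled (flanks truncated at
  chromosome ends; undefined, hence `NA`, when the flank median is 0);
* **DHBFC** — the same numerator divided by the median depth of all
  genome bins whose GC fraction is within ±0.05 of the call's mean GC.

A deletion is **HQ** iff DHFFC < 0.7; a duplication is **HQ** iff
DHBFC > 1.3 (strict inequalities, the thresholds recommended by the
duphold author); anything else, including calls with a missing score,
is **LQ**. Missing-score calls are LQ because the HQ definitions are
positive criteria — absence of evidence never upgrades a call.

**CNVR aggregation.** Within one technology, one CNV type and one
quality bin, CNV regions (CNVRs) are the connected components of the
overlap graph at a ≥ 1 bp criterion, spanning the outermost member
breakpoints. Splitting by quality *before* merging prevents a single
low-quality segment from bridging two well-supported regions into one
artefact. Arrays invert the order: replicate chips and multiple callers
produce heavily redundant calls, so array calls are first collapsed
within each dataset, each collapsed segment is relabeled from the
median fold change of its members, and only then are segments split by
quality and merged across datasets. Book-ended intervals (sharing 0 bp)
never merge. Each CNVR records its member calls, the count of distinct
datasets, a `single`/`multi` support class (single iff derived from
exactly one call — dataset count is reported separately because both
framings are useful and differ for replicate-heavy arrays), and
median-propagated intrinsic and fold-change scores (even member counts
take the mean of the central pair).

**CNV loci.** Same-type CNVRs from all technologies are merged once
more (≥ 1 bp) into CNV loci under four regimes: `all`; `above1` and
`above5`, keeping long-read CNVRs only when their median intrinsic
score strictly exceeds 1 or 5 (long-read callers emit floods of
sub-score-1 calls); and `above1_HQ`, additionally keeping only HQ
CNVRs of every technology. Locus boundaries legitimately differ
between regimes, so locus ids are regenerated per set and cross-set
comparisons must join on interval overlap, not id. Per locus we report
the technology set, the between-technology support (1–3) and the
percentage span — total member-CNVR length over locus length × 100 —
computed separately per quality bin, because HQ and LQ CNVRs of one
technology may overlap while same-bin CNVRs are disjoint (keeping the
span ≤ 100).

**Evidence assays.** Each CNVR, regardless of origin, is assayed in
representative raw data of all three technologies:

* *Array*: Log R Ratio (LRR) of probes inside the region versus the 50
  nearest probes up- and downstream (pooled), compared by Hellinger
  distance, plus the median in-region LRR (≈ −0.5 for a heterozygous
  deletion, ≈ +0.3 for a duplication). Regions spanning fewer than 5
  usable probes yield a null record with a reason.
* *Short reads*: the inherited median DHFFC/DHBFC.
* *Long reads*: a genotype per region from a validator-style table;
  0/1 and 1/1 are *concordant* with the CNV, 0/0 or no genotype
  *discordant*.

Plus database lookup — present iff a same-type database record covers
at least 50% of the CNVR's length (one-directional, per the stated
rule; among qualifying records the largest overlap wins, ties broken
by highest frequency) — and genomic context: fraction covered by the
merged segmental-duplication track, GC and repeat presence in 100-bp
breakpoint flanks, and length-weighted mean mappability.

**Copy-number typing of untyped regions** uses 70% reciprocal overlap
against typed reference sets; a region matching references of both
types stays untyped (no region ever carries two types), and untyped
regions are excluded downstream.

## Numerical choices

* **Hellinger distance.** Only the name of the distance is standard;
  how to evaluate it on two LRR samples is a package choice. Both
  samples are histogrammed on 20 equal-width bins shared over the
  pooled range, normalized to probability vectors `p`, `q`, and the
  distance is `sqrt(1 - sum(sqrt(p*q)))`. Identical samples give 0,
  disjoint supports give 1, and a degenerate pooled range (all values
  equal) gives 0. The bin count is configurable; tests pin the
  definition against an independent `hist()`-based implementation.
* **Depth medians** are per-basepair medians computed as weighted
  medians over bins, with weights equal to overlapped basepairs, so
  partial edge bins count proportionally.
* **Consensus-score normalization.** A consensus callset reporting
  `n` of at most 7 supporting approaches is mapped linearly to the
  0–100 intrinsic-score scale (`n/7 × 100`); "loosely normalized" is
  not otherwise specified, and a linear map is the least structured
  choice. GRIDSS-style scores are divided by 100.
* **Score-bin boundaries** are left-closed: `<1`, `[1,5)`, `≥5`; the
  locus-set score filters are strict (`>1`, `>5`), matching their
  names.
* **Ties in the rank-sum test** use the normal approximation of
  `stats::wilcox.test`; the fully tied degenerate case is reported as
  p = 1.
* **Merge core.** Connected components are computed by a single sorted
  sweep per chromosome (new component when the next start reaches the
  running maximum end), which for intervals equals the transitive
  closure of the overlap graph; tests compare it to an O(n²) oracle.

## The synthetic data model

The generator's defaults define the study conditions used by the tests
and the acceptance script: a toy diploid genome of two 5-Mb
chromosomes; 200 truth CNVs (60% deletions, 80% heterozygous) with
log-uniform sizes of 600 bp–20 kb; three datasets per technology with
sensitivity 0.9, 0.5 false calls per Mb and 50-bp Gaussian breakpoint
jitter; technology-specific false-call size profiles (arrays large,
short reads small); a 30× depth track with bin depth ~
Poisson(coverage × CN/2); probe grids at 1.2 kb and 3 kb spacing with
LRR ~ Normal(shift(CN), 0.2) where shift is −0.5/+0.3 for heterozygous
deletion/duplication (−2/+0.75 for homozygous); long-read intrinsic
scores drawn high (log-normal, median 10) for truth-derived calls and
low (exponential, mean 0.5) for false calls, mimicking the
low-score-flood behaviour of long-read callers; genotyping error 0.05;
and two synthetic databases including truth variants with probability
0.7/0.5 and Beta(1, 9) frequencies. Same-type truth variants never
overlap, keeping recovery accounting unambiguous; opposite types may.
Truth is placed outside the fixed telomere/centromere masks, emulating
a confident-region truth set — calls there are artefacts by
construction. One shared depth track and one genotype table serve all
evidence assays, mirroring the use of one representative dataset per
technology. These sizes keep the default test suite around a minute
and a full pipeline run under half a minute.

What the generator does **not** emulate: locus-specific mapping
artefacts (false calls are uniform, not repeat-seeded), correlated
errors between datasets of one technology, B-allele frequencies, read
length/insert-size structure, and mosaic states. Passing tests
therefore demonstrate that the pipeline's bookkeeping and statistics
behave as specified under a known truth — not that the thresholds are
optimal for any real genome.

## Limitations

* Database frequency is taken from the single best-matching record,
  not aggregated over all matches.
* Quality labeling leans entirely on one short-read alignment's depth,
  so the evidence inherits short-read biases; the array and long-read
  assays exist precisely to give orthogonal views.
* The VCF adapter ingests only symbolic DEL/DUP records with an `END`
  key; breakend notation is out of scope.
* Copy-number rescue of untyped calls by re-validation in raw chip
  data is out of scope; only the reciprocal-overlap annotation is
  implemented.

## Reproducing a run

```{r run, eval = FALSE}
res <- run_pipeline(list(simulate = list(seed = 2024)), "results/run")
head(res$cnvrs)
res$table1
```

The numbered scripts under `analysis/` execute the same stages
step-by-step against files on disk, and `scripts/acceptance.R --seed 1
--out results/acceptance.json` recomputes the headline quantities from
scratch.
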
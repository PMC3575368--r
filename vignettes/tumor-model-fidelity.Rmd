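---
title: "Assessing the genetic fidelity of patient-derived tumor models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the genetic fidelity of patient-derived tumor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorfidelity)
```

## The question

Targeted cancer therapies are developed and tested on pre-clinical models
derived from patient tumors: serum-free neurosphere cultures, adherent cell
cultures on laminin, or tumor fragments expanded as xenografts in
immunocompromised mice. The therapies themselves are chosen by DNA markers,
so the models are only useful if they preserve the primary tumor's genetics
— its somatic point mutations (including subclonal ones) and its copy-number
aberrations. `tumorfidelity` implements an analysis pipeline that answers,
from exome-style sequencing of a matched trio (patient blood, primary tumor,
derived model), whether the model is genetically faithful, while dealing
with three practical obstacles that can masquerade as genetic differences:
sequencing artifacts, contaminating mouse DNA in xenografts, and normal-cell
contamination of the primary specimen.

Every stage operates on plain tabular data — per-site allele counts, per-read
dual-genome alignment summaries, per-probe coverages — so the pipeline is
agnostic to the upstream aligner and caller. A synthetic cohort generator
(`simulate_cohort()`) produces all three data types with full ground truth,
which is how the package tests itself.

## Base-quality mixture filtering

Variant calls whose supporting reads carry systematically low base qualities
at the alternate allele are usually sequencing errors. At *known* germline
polymorphisms the mean alternate-allele base quality is unimodal; at novel
calls it is bimodal, the lower mode being dominated by artifacts.
`fit_quality_mixture()` fits one- and two-component Gaussian mixtures by EM
(quantile-split initialisation, 10 restarts, relative log-likelihood
tolerance 1e-8, at most 500 iterations) and selects among {1 component,
2 equal-variance, 2 free-variance} by BIC — mirroring the behaviour of
model-based clustering over a small family. When two components win, members
of the lower-mean component are discarded. Known variants are exempt
(`quality_filter()`), since the bimodality is a property of novel calls.

```{r mixture}
set.seed(1)
q <- c(rnorm(250, 12, 2), rnorm(250, 30, 2))
fit_quality_mixture(q, seed = 1)
```

## Xenograft read deconvolution

A xenograft specimen contains mouse stroma; its reads are captured and
align to the human reference at orthologous genes, creating hundreds of
spurious "somatic" calls. Each read is summarised against both genomes and
classified by a fixed cascade: mapping status (a read aligning one genome
only belongs to it), then proper pairing, then the match score
`M = matches − mismatches`. Ties on both pairing and score are *ambiguous*
and discarded — "better alignment" is read strictly, which sacrifices a few
reads in strongly conserved regions rather than leaking mouse evidence into
human calls. The same filter is meant to be applied to all samples of a
xenografted patient, so that coverage remains comparable.

With the simulator's defaults (mismatch rates Poisson(0.5) against a read's
own genome, Poisson(4) against the other; imperfect mapping and pairing),
the cascade removes ≥95% of mouse reads while losing ≤5% of human reads,
and the inflated somatic call count of a 40%-contaminated xenograft drops
by roughly half after recounting — the direction and magnitude expected
when contamination roughly doubles the apparent mutation load.

## Somatic calling

`call_variants()` applies the filter set to tumor–normal allele counts:

* right-tailed Fisher exact p ≤ 0.05 for alternate-read enrichment in the
  tumor (`fisher_right_tail()`, the exact hypergeometric tail);
* normal alternate fraction ≤ 5% — removes germline variants miscalled
  somatic;
* coverage ≥ 8 in both samples and ≥ 2 tumor alternate reads for SNVs
  (the upstream caller's "default filters" are not published; these floors
  are the package's documented defaults and are configurable through
  `somatic_thresholds()`);
* indels are held to stricter floors: tumor coverage ≥ 10, ≥ 3 supporting
  reads, germline alternate fraction < 5%.

Sites with a normal alternate fraction ≥ 20% are germline; germline-het
sites whose tumor allele balance collapses toward 0 or 1 with a two-sided
Fisher p ≤ 0.05 are flagged LOH. The LOH rule is the minimal consistent
choice, since only the call categories, not the rule, are fixed by
convention. `restrict_to_targets()` keeps sites on capture targets using
the BED half-open convention (`start < pos ≤ end`).

## Comparing primary and model

At every site called somatic in either sample, `compare_site()` computes a
two-sided Fisher exact p on the primary-vs-model count table. Significance
is **not** judged at a fixed level: `permutation_fdr()` builds a per-site
null by pooling the two samples' reads and redrawing the split with both
depths preserved (hypergeometric resampling — the standard exchangeable
null for 2×2 count data), and estimates `FDR(t)` as the mean number of null
sites at `p ≤ t` over the observed number. The returned threshold is the
largest `t` in the observed p-grid with estimated FDR at or below the
target (0.05). This plug-in functional was chosen over Benjamini–Hochberg
because the discrete, depth-dependent null of count tables is exactly what
the permutation captures.

`classify_records()` then assigns the fidelity classes: *shared constant*
(detected in both, no significant change), *shared changing* (detected in
both, significant change), *primary only* / *model only* (detected in one,
with significant evidence of absence in the other). Detection requires ≥ 2
alternate reads and ≥ 5% mutant allele fraction — the same floors as the
caller. A site detected in one sample whose difference is not significant
is insufficient evidence of absence and stays *shared constant*; sites
below detection in both (possible after re-counting) default there too.

Two summaries mirror the fidelity analysis: `maf_correlation()` (Pearson by
default, Spearman available; the correlation flavour is not fixed by
convention) over sites covered ≥ 30× in both samples, and
`estimate_contamination()`. At a copy-neutral het somatic site in a pure
model, `primary_maf ≈ model_maf × (1 − c)` where `c` is the normal-DNA
fraction of the primary; `c` is one minus the median per-site frequency
ratio over shared sites, clamped to [0, 1], restricted to copy-neutral
segments when a segment file is available (the cancer-cell fraction cancels
in the ratio, so subclonal sites are fine). The exact published estimator
is in an unavailable supplement; this median-ratio reconstruction recovers
simulated contaminations of 9–41% within ±5 points at 150 sites × 60×, and
is unbiased to within 0.02 at c = 0.25 over 50 replicates.

## Copy-number calling from probe coverage

Coverage-based exome CNA calling works on `logR = log2` of the normalised
tumor/normal coverage ratio per capture probe, after GC correction:
`gc_correct()` divides each sample's coverage by the median of its 1%-wide
GC bin (bins under 10 probes merged with neighbours) and rescales by the
global median. Capture GC bias is library-specific — the simulator gives
tumor libraries a stronger GC bow for exactly that reason — and the
correction drives the logR–GC correlation from >0.3 to <0.05 on biased
data.

`segment_probes()` is a circular-binary-segmentation-style recursive
splitter: within each chromosome it finds the arc maximising the
two-sample t statistic of mean logR against its complement and accepts the
split when a label-permutation p (default 1000 permutations, α = 0.01) is
significant, recursing into the parts. The arc (two-boundary) statistic is
used rather than a single best split because a short focal amplification
flanked by neutral sequence on both sides is invisible to single splits.
Runs under 5 callable probes are never tested; probes with normal coverage
< 10 are *not callable* (`nc`) and are carried but ignored. A sequential
early stop abandons permutation once the exceedance count guarantees
p > α; this never changes an accept/reject decision.

`call_segments()` grades segments: `neutral` within ±0.2 logR (the
copy-neutral band is not fixed by convention; 0.2 is the package default
and configurable), `amp`/`del` otherwise — subject to a significance guard:
a segment whose mean is within 4.5 standard errors of zero stays neutral.
The guard level is calibrated to the post-selection null scale — the
maximal purely random arc reaches ≈ 4.3 se, so offspring of a spurious
split are not mistaken for events, while the weakest simulated true event
(whole-chromosome trisomy at 59% purity) stands ≈ 5 se out. This is the
analogue of established exome-CNA callers only calling events their
coverage can support. High-confidence (HC) grade goes to amplifications
above the 95th (deletions below the 5th) percentile of the copy-neutral
segments' logR values. Arm-level events (`call_arms()`) require >20% of an
arm's targeted base pairs in segments consistently called in one direction;
mixed amp/del patchwork never fakes an arm event. `call_loh()` flags
segments where ≥10 germline-het sites have a median tumor B-allele
fraction at least 0.2 away from ½.

Fidelity of copy-number profiles is scored by `cna_concordance()`: over
targeted base pairs inside HC segments of either sample, the per-probe
calls of the two samples are cross-tabulated and the consistent fraction is
the agreeing (non-`nc`) diagonal. `cluster_samples()` builds an
average-linkage, Euclidean-distance dendrogram over the samples × HC-union
mean-logR matrix; with faithful models every primary's nearest neighbour is
its own model.

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defaults describe the emulated study: four patients
(neurosphere, adherent, two xenografts), 60× mean on-target coverage,
primary purities 0.91 / 0.89 / 0.75 / 0.59 against pure models, 40% murine
reads in xenograft tissue, 160 somatic sites per patient of which 30% are
subclonal (cancer-cell fraction 0.4 — the true subclonal architecture of
such tumors is unknown, so these are free parameters, documented as such),
1000 germline sites (90% flagged known), ~10% artifact sites, and a shared
copy-number backbone (chr7 gain, chr10 loss — the classic glioblastoma
pattern) plus one patient-specific focal 6-copy amplification and one arm
deletion, on a toy genome of 22 two-armed, 10-Mb chromosomes with 200
probes each.

The generative assumptions are the ones the statistics rely on: a somatic
site's expected mutant allele fraction is
`f = m·CCF·p / (CN_t·p + 2(1−p))` and alternate counts are Binomial(depth,
f); probe and site depths are negative binomial (size 5) with a quadratic
GC bow peaking at 0.45; artifact sites draw ~8% alternate fractions in
*every* sample and low base qualities (modes 30 vs 12, sd 2); transitions
occur with probability 0.756 at genuine variants (Ts/Tv ≈ 3.1) and 0.5 at
artifacts; the germline probe coverage is drawn once per patient and shared
by both logR computations, as in a matched design with one blood library.
Mouse-contamination sites carry their model-sample alternate support as
individually identified reads, so read filtering genuinely changes the
counts.

What the generator does *not* emulate: read-level sequences and alignment
(mapping bias, indel realignment), capture chemistry, correlated noise
along the genome, multi-allelic sites, and real subclonal phylogenies.
Passing tests therefore demonstrate the statistical machinery — error
control, parameter recovery, classification behaviour — under the stated
model, not robustness to every artifact of real instruments.

## Numerical and design notes

* All randomness flows from explicit integer seeds; the cohort, the
  permutation FDR, segmentation and the end-to-end report are byte-identical
  under a fixed seed. The RNG state of the caller is never disturbed.
* Fisher machinery uses exact hypergeometric tails; the test suite checks
  both tails against brute-force enumeration over every 2×2 table with
  margins ≤ 30 at 1e-10.
* EM degeneracies are handled by variance floors (1e-6); the per-iteration
  log-likelihood is retained and asserted non-decreasing.
* Zero-transversion Ts/Tv and zero-synonymous NS/S ratios are reported as
  `Inf` with a warning; empty inputs error.
* Percentages are rounded half away from zero; ratios print to two
  decimals. Because published conventions differ on whether splice-site
  mutations count as non-synonymous, `class_distribution()` reports both
  totals.
* Problem sizes in the tests (200 probes/chromosome, 500–1000 permutations,
  1000-site null panels, 150-site contamination panels) were chosen as the
  smallest sizes at which the binomial/permutation Monte-Carlo error is
  comfortably below the tolerances being asserted.

## Known limitations

* The contamination estimator assumes a pure model; a contaminated model
  biases `c` downward.
* Coverage-based CNA calling cannot resolve allele-specific copy number or
  breakpoints between probes; whole-genome (off-target) bins are out of
  scope.
* The comparison treats sites independently; clonal deconvolution and
  phylogenies are out of scope.
* Multi-allelic sites are reduced to their first alternate allele.

## A complete run

```{r pipeline, eval = FALSE}
cfg <- cohort_config(seed = 11)
report <- run_pipeline(cfg, out_dir = "fidelity_report")
print(report)
```

The report bundles, per patient: filter-by-filter input/output counts, the
FDR threshold, fidelity class counts, the contamination estimate, the
30×-site MAF correlation, both samples' segment tables and their base-pair
concordance; cohort-wide it adds the HC-segment dendrogram in newick form.
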
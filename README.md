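# tumorfidelity

Is a patient-derived pre-clinical tumor model — a neurosphere culture, an
adherent cell culture, or a mouse xenograft — genetically faithful to the
primary tumor it came from? Targeted therapies are selected on DNA markers,
so a model is only as useful as its preservation of the primary's somatic
mutations and copy-number aberrations. `tumorfidelity` implements the
analysis pipeline for answering that question from exome-style sequencing
of matched trios (blood / primary / model), together with the quality
machinery that keeps technical noise from masquerading as genetic
divergence:

* **Somatic calling** from tumor–normal allele counts: right-tailed Fisher
  exact test (p ≤ 0.05), ≤ 5% alternate fraction in the normal, coverage and
  alt-read floors, stricter rules for indels (10× coverage, 3 supporting
  reads), plus germline and LOH status.
* **Base-quality artifact filtering**: a 1- vs 2-component Gaussian mixture
  (EM, BIC-selected) on mean alternate-allele base qualities; calls in the
  low-quality mode are discarded, known polymorphisms are exempt.
* **Xenograft mouse-read removal**: each read is classified human / mouse /
  ambiguous by a cascade over dual-genome mapping status, proper pairing and
  the match score `M = matches − mismatches`.
* **Primary-vs-model comparison**: a two-sided Fisher exact test on mutant
  allele frequencies at every somatic site, thresholded at an FDR of 0.05
  estimated by per-site hypergeometric permutation; sites are classified
  *shared constant*, *shared changing*, *primary only* or *model only*,
  and the primary's normal-DNA contamination `c` is estimated from
  `primary_maf ≈ model_maf · (1 − c)` (median ratio, pure-model assumption).
* **Exome copy-number calling**: GC-corrected tumor/normal coverage logR per
  capture probe, CBS-style segmentation with permutation p-values,
  neutral/amp/del calls with high-confidence grading by the copy-neutral
  percentile rule, >20%-of-arm calls, LOH flags, base-pair concordance
  between primary and model, and an HC-segment logR dendrogram relating all
  samples.
* **A synthetic matched-cohort generator** with complete ground truth
  (per-site status and cancer-cell fraction, per-read species, per-probe
  copy number), emulating 60× GC-biased negative-binomial coverage, purity
  dilution of allele fractions, bimodal base qualities and 0–60% murine
  contamination — every stage of the pipeline is validated against it.

## Worked example

```r
library(tumorfidelity)

cfg <- cohort_config(seed = 11)   # 4 patients: neurosphere, adherent, 2 xenografts
report <- run_pipeline(cfg)
print(report)
#> tumorfidelity pipeline report
#>   P01 (neurosphere): 159 compared sites, 100% shared, contamination 0.07, CNA concordance 0.97
#>   P02 (adherent): 160 compared sites, 100% shared, contamination 0.15, CNA concordance 0.98
#>   P03 (xenograft): 158 compared sites, 100% shared, contamination 0.27, CNA concordance 0.92
#>   P04 (xenograft): 153 compared sites, 100% shared, contamination 0.40, CNA concordance 0.67
```

Reading the output: virtually all somatic mutations found in each primary
are shared with its model (the few *shared changing* sites move
unidirectionally toward the purer model), and the contamination estimates
recover the fractions the cohort was simulated with (truth: 0.09 / 0.11 /
0.25 / 0.41). The three high-cellularity pairs agree on 92–98% of base
pairs in high-confidence copy-number segments; the heavily contaminated
P04 primary (59% purity) drops to 0.67 because normal DNA mutes its
copy-number signal below the calling threshold while the pure model still
detects the events — a sensitivity effect of specimen purity, not genetic
divergence, and the expected signature of a contaminated primary. The
xenograft patients' logs additionally show the somatic call count dropping
by ~half after mouse-read filtering (e.g. 301 → 155 candidate model calls
for P03), the signature of murine contamination.

Individual stages are exported: `fit_quality_mixture()`,
`filter_read_set()`, `call_variants()`, `permutation_fdr()`,
`classify_records()`, `estimate_contamination()`, `gc_correct()`,
`segment_probes()`, `call_segments()`, `cna_concordance()`,
`cluster_samples()`, and friends. A thin command-line wrapper lives at
`inst/cli/tumorfidelity.R` (`simulate`, `report`, `xenofilter`
subcommands). The methods vignette
(`vignettes/tumor-model-fidelity.Rmd`) documents the models, defaults and
design choices.

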
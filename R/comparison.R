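# Primary-vs-model comparison: at every site called somatic in either
# sample, the mutant allele frequencies of primary and model are compared by
# a two-sided Fisher exact test; the significance threshold is set by a
# permutation estimate of the false discovery rate; each mutation is then
# classified as shared-constant, shared-changing, or unique to one sample.

#' Two-sided Fisher comparison of one site's primary and model counts
#'
#' @param primary,model Length-2 vectors `c(ref, alt)` of read counts.
#' @return Two-sided Fisher exact p-value.
#' @export
compare_site <- function(primary, model) {
  fisher_two_sided(primary[1], primary[2], model[1], model[2])
}

#' Build the primary-vs-model comparison table
#'
#' One row per site called somatic in at least one of the two call sets,
#' with both samples' counts, mutant allele fractions and the two-sided
#' Fisher p-value.
#'
#' @param primary_calls,model_calls Outputs of [call_variants()] for the
#'   primary and model samples of the same patient (same site universe).
#' @return A comparison data.frame (one ComparisonRecord per row).
#' @export
build_comparison <- function(primary_calls, model_calls) {
  som <- primary_calls$status == "somatic" | model_calls$status == "somatic"
  if (!identical(primary_calls$site_id, model_calls$site_id)) {
    shared <- intersect(primary_calls$site_id, model_calls$site_id)
    primary_calls <- primary_calls[match(shared, primary_calls$site_id), ]
    model_calls <- model_calls[match(shared, model_calls$site_id), ]
    som <- primary_calls$status == "somatic" | model_calls$status == "somatic"
  }
  p <- primary_calls[som, , drop = FALSE]
  m <- model_calls[som, , drop = FALSE]
  rec <- data.frame(
    site_id = p$site_id, patient = p$patient, chrom = p$chrom, pos = p$pos,
    primary_ref = p$primary_ref, primary_alt = p$primary_alt,
    model_ref = m$model_ref, model_alt = m$model_alt,
    somatic_in_primary = p$status == "somatic",
    somatic_in_model = m$status == "somatic",
    stringsAsFactors = FALSE
  )
  rec$primary_maf <- with(rec, ifelse(primary_ref + primary_alt > 0,
                                      primary_alt / (primary_ref + primary_alt), 0))
  rec$model_maf <- with(rec, ifelse(model_ref + model_alt > 0,
                                    model_alt / (model_ref + model_alt), 0))
  rec$p_two_sided <- fisher_two_sided(rec$primary_ref, rec$primary_alt,
                                      rec$model_ref, rec$model_alt)
  rec
}

# Conditional null distribution of one site's 2x2 table: pooled alternate
# reads re-split between the two samples preserving both depths. Returns the
# support of the primary alt count and the two-sided p attached to each
# support point, so permutations are a draw plus a lookup.
site_null_support <- function(pref, palt, mref, malt) {
  A <- palt + malt
  N <- pref + palt + mref + malt
  n1 <- pref + palt
  k <- max(0, A - (N - n1)):min(A, n1)
  pr <- stats::dhyper(k, A, N - A, n1)
  p_two <- vapply(seq_along(k), function(i) {
    min(1, sum(pr[pr <= pr[i] * (1 + 1e-7)]))
  }, numeric(1))
  list(k = k, prob = pr, p_two = p_two, A = A, N = N, n1 = n1)
}

#' Permutation estimate of the FDR-controlling p-value threshold
#'
#' The null is built per site by pooling primary and model reads and
#' redrawing the primary/model split with both depths preserved
#' (hypergeometric resampling), which keeps the total alternate-read count
#' and per-sample coverage of every site fixed. For each candidate threshold
#' `t` in the observed p-value grid, `FDR(t)` is the mean number of null
#' sites at `p <= t` divided by the observed number; the returned threshold
#' is the largest `t` with `FDR(t)` at most `target_fdr`.
#'
#' @param records Comparison table from [build_comparison()] (or any table
#'   with `primary_ref`, `primary_alt`, `model_ref`, `model_alt` and
#'   optionally `p_two_sided`).
#' @param n_permutations Number of permutations (at least 100).
#' @param seed Integer seed; results are deterministic given it.
#' @param target_fdr Target false discovery rate.
#' @return An object of class `tf_fdr`: `p_threshold`, `n_permutations`,
#'   `estimated_fdr_at_threshold`, `seed`, `target_fdr` and the evaluation
#'   `grid`. When no threshold achieves the target, the threshold is 0 with
#'   a warning (nothing significant).
#' @export
permutation_fdr <- function(records, n_permutations = 1000, seed = 1L,
                            target_fdr = 0.05) {
  if (nrow(records) < 1) validation_error("need at least one record")
  if (n_permutations < 100) {
    validation_error("n_permutations must be at least 100")
  }
  if (is.null(records$p_two_sided)) {
    records$p_two_sided <- fisher_two_sided(
      records$primary_ref, records$primary_alt,
      records$model_ref, records$model_alt)
  }
  p_obs <- records$p_two_sided
  n <- nrow(records)
  null_p <- matrix(NA_real_, nrow = n_permutations, ncol = n)
  with_seed(seed, {
    for (j in seq_len(n)) {
      sup <- site_null_support(records$primary_ref[j], records$primary_alt[j],
                               records$model_ref[j], records$model_alt[j])
      draws <- stats::rhyper(n_permutations, sup$A, sup$N - sup$A, sup$n1)
      null_p[, j] <- sup$p_two[draws - sup$k[1] + 1]
    }
  })
  grid <- sort(unique(p_obs))
  null_sorted <- sort(as.vector(null_p))
  null_count <- findInterval(grid, null_sorted) / n_permutations
  obs_count <- findInterval(grid, sort(p_obs))
  fdr_hat <- pmin(1, null_count / obs_count)
  ok <- which(fdr_hat <= target_fdr)
  if (length(ok) == 0) {
    warning("no p-value threshold achieves the target FDR; ",
            "threshold set to 0 (nothing significant)")
    threshold <- 0
    est <- 0
  } else {
    threshold <- max(grid[ok])
    est <- fdr_hat[max(ok)]
  }
  structure(list(
    p_threshold = threshold, n_permutations = as.integer(n_permutations),
    estimated_fdr_at_threshold = est, seed = as.integer(seed),
    target_fdr = target_fdr,
    grid = data.frame(p = grid, n_observed = obs_count,
                      mean_null = null_count, fdr = fdr_hat)
  ), class = "tf_fdr")
}

#' @export
print.tf_fdr <- function(x, ...) {
  cat(sprintf(
    "Permutation FDR: threshold p <= %.4g (estimated FDR %.3f, target %.2f, %d permutations)\n",
    x$p_threshold, x$estimated_fdr_at_threshold, x$target_fdr,
    x$n_permutations))
  invisible(x)
}

#' Classify compared mutations into fidelity classes
#'
#' A mutation detected in both samples is `shared_constant` when its
#' frequency change is not significant at the FDR threshold and
#' `shared_changing` when it is; a mutation detected in exactly one sample
#' with a significant frequency difference is `primary_only` / `model_only`;
#' detection in one sample without a significant difference is insufficient
#' evidence of absence and stays `shared_constant`. Detection requires at
#' least `min_alt_reads` alternate reads and `min_alt_fraction` mutant
#' allele fraction. The four classes are exhaustive and exclusive.
#'
#' @param records Comparison table with p-values.
#' @param fdr A [permutation_fdr()] result (or a list with `p_threshold`).
#' @param detection Detection floor: list with `min_alt_reads`,
#'   `min_alt_fraction`.
#' @return `records` with a `q_class` column.
#' @export
classify_records <- function(records, fdr,
                             detection = list(min_alt_reads = 2,
                                              min_alt_fraction = 0.05)) {
  thr <- fdr$p_threshold
  det_p <- records$primary_alt >= detection$min_alt_reads &
    records$primary_maf >= detection$min_alt_fraction
  det_m <- records$model_alt >= detection$min_alt_reads &
    records$model_maf >= detection$min_alt_fraction
  sig <- records$p_two_sided <= thr
  q <- ifelse(det_p & det_m, ifelse(sig, "shared_changing", "shared_constant"),
       ifelse(det_p & !det_m & sig, "primary_only",
       ifelse(det_m & !det_p & sig, "model_only", "shared_constant")))
  records$q_class <- q
  records
}

#' Mutant allele frequency correlation between primary and model
#'
#' @param records Comparison table.
#' @param min_depth Minimum read depth required in both samples.
#' @param method Correlation flavour; Pearson by default, Spearman offered.
#' @return A list with `r` and `n_used`.
#' @export
maf_correlation <- function(records, min_depth = 30,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  dp <- records$primary_ref + records$primary_alt
  dm <- records$model_ref + records$model_alt
  use <- dp >= min_depth & dm >= min_depth
  if (sum(use) < 3) {
    insufficient_data_error(sprintf(
      "need >= 3 records covered at %dx in both samples, got %d",
      min_depth, sum(use)))
  }
  list(r = stats::cor(records$primary_maf[use], records$model_maf[use],
                      method = method),
       n_used = sum(use))
}

#' Estimate normal-DNA contamination of the primary tumor
#'
#' Assuming a pure model sample, the mutant allele frequency of a shared
#' somatic mutation at a copy-neutral site satisfies
#' `primary_maf ~ model_maf * (1 - c)` where `c` is the fraction of normal
#' DNA in the primary; `c` is estimated as one minus the median of the
#' per-site frequency ratio, clamped to `[0, 1]`. When copy-number segments
#' are supplied, only sites inside copy-neutral segments qualify; otherwise
#' all shared sites are used with a warning.
#'
#' @param records Classified comparison table (needs `q_class`).
#' @param segments Optional segment table (columns `chrom`, `start`, `end`,
#'   `call`) from the copy-number module; only `call == "neutral"` segments
#'   are used.
#' @return Estimated contamination fraction in `[0, 1]`.
#' @export
estimate_contamination <- function(records, segments = NULL) {
  if (is.null(records$q_class)) {
    validation_error("records must be classified (run classify_records first)")
  }
  qual <- records$q_class %in% c("shared_constant", "shared_changing") &
    records$model_maf > 0
  if (!is.null(segments)) {
    neutral <- segments[segments$call == "neutral", , drop = FALSE]
    if (nrow(neutral) == 0) {
      warning("no copy-neutral segments supplied; using all shared sites")
    } else {
      q <- GenomicRanges::GRanges(records$chrom,
                                  IRanges::IRanges(records$pos, records$pos))
      s <- GenomicRanges::GRanges(neutral$chrom,
                                  IRanges::IRanges(neutral$start + 1,
                                                   neutral$end))
      qual <- qual & GenomicRanges::countOverlaps(q, s) > 0
    }
  } else {
    warning("no segments supplied; contamination estimated from all shared sites")
  }
  if (sum(qual) < 10) {
    insufficient_data_error(sprintf(
      "need >= 10 qualifying shared sites, got %d", sum(qual)))
  }
  ratio <- records$primary_maf[qual] / records$model_maf[qual]
  min(1, max(0, 1 - stats::median(ratio)))
}
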
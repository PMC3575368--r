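# Somatic variant calling from matched tumor-normal allele counts: a
# right-tailed Fisher exact test on the 2x2 count table plus the filter set
# (<=5% alternate fraction in the normal, coverage and alt-read floors);
# germline and LOH status from the same counts.

check_counts <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(!is.finite(c(a, b, c, d)))) {
    validation_error("allele counts must be non-negative finite numbers")
  }
  if (any(a + b + c + d == 0)) {
    validation_error("2x2 table must contain at least one read")
  }
}

#' Right-tailed Fisher exact p-value for tumor alternate enrichment
#'
#' For the 2x2 table (normal ref/alt = a/b; tumor ref/alt = c/d) this is the
#' exact hypergeometric tail probability of observing `d` or more alternate
#' reads in the tumor, conditional on all margins. Vectorised.
#'
#' @param a,b Normal reference / alternate read counts.
#' @param c,d Tumor reference / alternate read counts.
#' @return p-value(s) in `(0, 1]`.
#' @export
fisher_right_tail <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  stats::phyper(d - 1, b + d, a + c, c + d, lower.tail = FALSE)
}

#' Two-sided Fisher exact p-value for a 2x2 count table
#'
#' The standard conditional test: the sum of hypergeometric probabilities of
#' all tables (with the observed margins) no more likely than the observed
#' one. Vectorised over tables.
#'
#' @param a,b First sample's reference / alternate counts.
#' @param c,d Second sample's reference / alternate counts.
#' @return p-value(s) in `(0, 1]`.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    A <- b[i] + d[i]
    N <- a[i] + b[i] + c[i] + d[i]
    n1 <- a[i] + b[i]
    k <- max(0, A - (N - n1)):min(A, n1)
    pr <- stats::dhyper(k, A, N - A, n1)
    obs <- stats::dhyper(b[i], A, N - A, n1)
    min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Thresholds for the somatic caller
#'
#' The filter set: a somatic SNV needs right-tailed Fisher p <= `p_somatic`,
#' at most `max_normal_alt` alternate fraction in the normal, coverage of at
#' least `min_coverage` in both samples and at least `min_alt_reads` tumor
#' alternate reads. Indels use the more stringent `indel_min_coverage` /
#' `indel_min_alt_reads` floors. A normal alternate fraction of at least
#' `het_threshold` marks a germline variant; germline-het sites whose tumor
#' allele balance departs toward 0 or 1 with two-sided Fisher p <=
#' `p_somatic` are flagged LOH.
#'
#' @param p_somatic Fisher p-value ceiling for somatic (and LOH) calls.
#' @param max_normal_alt Maximum alternate fraction tolerated in the normal.
#' @param min_coverage Minimum read depth in both samples (SNVs).
#' @param min_alt_reads Minimum tumor alternate reads (SNVs).
#' @param het_threshold Normal alternate fraction marking a germline variant.
#' @param indel_min_coverage Minimum tumor depth for indel calls.
#' @param indel_min_alt_reads Minimum tumor alternate reads for indel calls.
#' @return A list of thresholds.
#' @export
somatic_thresholds <- function(p_somatic = 0.05,
                               max_normal_alt = 0.05,
                               min_coverage = 8,
                               min_alt_reads = 2,
                               het_threshold = 0.2,
                               indel_min_coverage = 10,
                               indel_min_alt_reads = 3) {
  list(p_somatic = p_somatic, max_normal_alt = max_normal_alt,
       min_coverage = min_coverage, min_alt_reads = min_alt_reads,
       het_threshold = het_threshold,
       indel_min_coverage = indel_min_coverage,
       indel_min_alt_reads = indel_min_alt_reads)
}

#' Call variant status from tumor-normal allele counts
#'
#' Applies the somatic filter set per site and labels each site `somatic`,
#' `germline`, `loh` or `reference`. SNVs and indels are handled according to
#' their `variant_type`, indels with the stricter coverage/support floors.
#'
#' @param sites Site table carrying `germline_ref`, `germline_alt` and the
#'   chosen tumor sample's `<tumor>_ref` / `<tumor>_alt` columns.
#' @param tumor Which tumor sample to call against the germline:
#'   "primary" or "model".
#' @param thresholds A [somatic_thresholds()] list.
#' @return The site table plus `normal_af`, `tumor_af`, `somatic_p`,
#'   `status` and `filters_failed` (semicolon-separated names of somatic
#'   filters the site failed; empty for passing sites).
#' @export
call_variants <- function(sites, tumor = c("primary", "model"),
                          thresholds = somatic_thresholds()) {
  tumor <- match.arg(tumor)
  a <- sites$germline_ref
  b <- sites$germline_alt
  c <- sites[[paste0(tumor, "_ref")]]
  d <- sites[[paste0(tumor, "_alt")]]
  check_counts(a, b, c, d)
  n_depth <- a + b
  t_depth <- c + d
  normal_af <- ifelse(n_depth > 0, b / n_depth, 0)
  tumor_af <- ifelse(t_depth > 0, d / t_depth, 0)
  p <- fisher_right_tail(a, b, c, d)
  is_indel <- sites$variant_type == "indel"
  th <- thresholds

  min_cov <- ifelse(is_indel, th$indel_min_coverage, th$min_coverage)
  min_alt <- ifelse(is_indel, th$indel_min_alt_reads, th$min_alt_reads)

  fail <- list(
    fisher = p > th$p_somatic,
    normal_fraction = normal_af > th$max_normal_alt,
    coverage = t_depth < min_cov | (!is_indel & n_depth < th$min_coverage),
    alt_support = d < min_alt
  )
  somatic <- !Reduce(`|`, fail)
  germline <- !somatic & normal_af >= th$het_threshold

  status <- ifelse(somatic, "somatic",
                   ifelse(germline, "germline", "reference"))

  # LOH: germline-het site whose tumor allele balance collapses toward an
  # extreme, judged by a two-sided Fisher test on the same counts
  het <- germline & normal_af <= 1 - th$het_threshold
  if (any(het)) {
    p2 <- fisher_two_sided(a[het], b[het], c[het], d[het])
    departs <- abs(tumor_af[het] - 0.5) > abs(normal_af[het] - 0.5)
    status[het][p2 <= th$p_somatic & departs] <- "loh"
  }

  out <- sites
  out$tumor_sample <- tumor
  out$normal_af <- normal_af
  out$tumor_af <- tumor_af
  out$somatic_p <- p
  out$status <- status
  out$filters_failed <- vapply(seq_along(a), function(i) {
    if (status[i] == "somatic") "" else
      paste(names(fail)[vapply(fail, `[[`, logical(1), i)], collapse = ";")
  }, character(1))
  out
}

#' Restrict sites to exome capture targets
#'
#' BED intervals are 0-based half-open; a 1-based site position `pos` is on
#' target when `start < pos <= end`. Input order is preserved.
#'
#' @param sites Site table with `chrom` and `pos`.
#' @param targets Data.frame of BED intervals (`chrom`, `start`, `end`).
#' @return The on-target subset of `sites`.
#' @export
restrict_to_targets <- function(sites, targets) {
  if (nrow(targets) == 0 || nrow(sites) == 0) {
    return(sites[0, , drop = FALSE])
  }
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, sites$pos))
  s <- GenomicRanges::GRanges(targets$chrom,
                              IRanges::IRanges(targets$start + 1, targets$end))
  hit <- GenomicRanges::countOverlaps(q, s) > 0
  sites[hit, , drop = FALSE]
}
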
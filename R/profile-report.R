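# Cohort-level summaries and the end-to-end pipeline: mutation class
# distribution and non-synonymous/synonymous ratio, gene-list overlap, and
# the orchestrated simulate -> xenofilter -> quality filter -> call ->
# compare -> copy-number -> summary run.

coding_classes <- c("missense", "nonsense", "frameshift",
                    "inframe_deletion", "splice", "synonymous")

#' Mutation class distribution and non-synonymous/synonymous ratio
#'
#' Counts coding/splice somatic mutations per consequence class, reports
#' integer percentages (rounded half up) and the non-synonymous to
#' synonymous ratio `(missense + nonsense + frameshift + inframe_deletion +
#' splice) / synonymous`, printed to two decimals. Because usage varies on
#' whether splice sites count as non-synonymous, both the including and the
#' excluding total are reported.
#'
#' @param calls A [call_variants()] result (somatic coding/splice calls are
#'   summarised), or `NULL` when `counts` is given.
#' @param counts Alternatively, a named vector of per-class counts
#'   (names from missense, nonsense, frameshift, inframe_deletion, splice,
#'   synonymous).
#' @return A list with `counts`, `percentages`, `total_coding`,
#'   `ns_s_ratio` (2 decimals), `n_nonsyn_incl_splice`,
#'   `n_nonsyn_excl_splice`.
#' @export
class_distribution <- function(calls = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.null(calls)) validation_error("supply calls or counts")
    som <- calls[calls$status == "somatic" &
                   calls$consequence %in% coding_classes, , drop = FALSE]
    counts <- vapply(coding_classes,
                     function(k) sum(som$consequence == k), numeric(1))
  } else {
    full <- stats::setNames(numeric(length(coding_classes)), coding_classes)
    full[names(counts)] <- counts
    counts <- full
  }
  total <- sum(counts)
  if (total == 0) validation_error("no coding/splice somatic mutations")
  pct <- round_half_up(100 * counts / total)
  n_syn <- counts[["synonymous"]]
  n_ns_incl <- total - n_syn
  n_ns_excl <- n_ns_incl - counts[["splice"]]
  if (n_syn == 0) {
    warning("no synonymous mutations; NS/S ratio undefined (Inf)")
    ratio <- Inf
  } else {
    ratio <- round_half_up(n_ns_incl / n_syn, 2)
  }
  list(counts = counts, percentages = pct, total_coding = total,
       ns_s_ratio = ratio,
       n_nonsyn_incl_splice = n_ns_incl,
       n_nonsyn_excl_splice = n_ns_excl)
}

#' Overlap of somatic calls with a gene list
#'
#' Counts non-synonymous or splice-site somatic mutations whose gene symbol
#' appears in the supplied list (case-insensitive, whitespace-stripped), and
#' the number of distinct genes hit.
#'
#' @param calls A [call_variants()] result.
#' @param gene_list Character vector of gene symbols.
#' @return List with `n_mutations` and `n_genes`.
#' @export
gene_list_overlap <- function(calls, gene_list) {
  norm <- function(x) tolower(trimws(x))
  listed <- norm(gene_list)
  ns <- calls$status == "somatic" &
    calls$consequence %in% setdiff(coding_classes, "synonymous")
  hit <- ns & norm(calls$gene) %in% listed
  list(n_mutations = sum(hit), n_genes = length(unique(norm(calls$gene[hit]))))
}

#' Run the full fidelity pipeline on a simulated cohort
#'
#' For every patient: filter xenograft reads and recount mouse-supported
#' sites, quality-filter candidate variants by the base-quality mixture,
#' call variants for primary and model against the germline, compare the
#' somatic mutant allele frequencies under a permutation-FDR threshold,
#' classify each mutation, estimate the primary's normal-DNA contamination,
#' and call GC-corrected copy-number segments for both samples with
#' concordance scoring. Cohort-wide, samples are clustered on their
#' high-confidence copy-number signature. Deterministic under the
#' configuration seed; every filter's input/output counts are logged.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, the report JSON, per-site
#'   TSVs and SEG files are written there.
#' @param n_permutations Permutations for the comparison FDR.
#' @param segmentation_perms Label permutations per tested split.
#' @return A report list (class `tf_report`) with per-patient results and
#'   cohort summaries.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_permutations = 500,
                         segmentation_perms = 1000) {
  cohort <- simulate_cohort(config)
  patients <- config$patients
  per_patient <- list()
  sample_results <- list()
  all_primary_calls <- list()

  for (i in seq_along(patients)) {
    pat <- patients[i]
    log <- list()
    sites <- cohort$sites[cohort$sites$patient == pat, , drop = FALSE]
    log$candidate_sites <- nrow(sites)

    if (config$model_type[i] == "xenograft" && !is.null(cohort$reads)) {
      reads <- cohort$reads[cohort$reads$patient == pat, , drop = FALSE]
      pre_model <- call_variants(sites, "model")
      log$model_somatic_before_read_filter <-
        sum(pre_model$status == "somatic")
      fr <- filter_read_set(reads)
      log$reads_in <- fr$stats$n_input
      log$reads_kept <- length(fr$kept_ids)
      sites <- recount_model_alt(sites, reads, fr$kept_ids)
    }

    qf <- quality_filter(sites, seed = config$seed + i)
    log$quality_kept <- nrow(qf$kept)
    log$quality_discarded <- nrow(qf$discarded)

    primary_calls <- call_variants(qf$kept, "primary")
    model_calls <- call_variants(qf$kept, "model")
    log$primary_somatic <- sum(primary_calls$status == "somatic")
    log$model_somatic <- sum(model_calls$status == "somatic")
    all_primary_calls[[pat]] <- primary_calls

    records <- build_comparison(primary_calls, model_calls)
    fdr <- permutation_fdr(records, n_permutations = n_permutations,
                           seed = config$seed + 100L + i)
    records <- classify_records(records, fdr)
    log$compared_sites <- nrow(records)

    # copy-number profiles of both samples
    cna <- list()
    for (s in c("primary", "model")) {
      pr <- cohort$probes[cohort$probes$patient == pat &
                            cohort$probes$sample == s, , drop = FALSE]
      pr <- gc_correct(pr)
      pr <- compute_logr(pr)
      seg <- segment_probes(pr, n_perm = segmentation_perms,
                            seed = config$seed + 200L + 10L * i +
                              (s == "model"))
      seg$segments <- call_segments(seg$segments)
      het <- primary_calls[primary_calls$status %in% c("germline", "loh") &
                             primary_calls$normal_af >= 0.2 &
                             primary_calls$normal_af <= 0.8, , drop = FALSE]
      if (nrow(het)) {
        het_tab <- data.frame(chrom = het$chrom, pos = het$pos,
                              tumor_ref = het[[paste0(s, "_ref")]],
                              tumor_alt = het[[paste0(s, "_alt")]])
        seg$segments <- call_loh(het_tab, seg$segments)
      }
      cna[[s]] <- seg
      sample_results[[paste0(pat, "_", s)]] <- seg
    }
    conc <- cna_concordance(cna$primary, cna$model)

    contamination <- tryCatch(
      estimate_contamination(
        records, segments = cna$primary$segments),
      tf_error = function(e) NA_real_)
    corr <- tryCatch(maf_correlation(records),
                     tf_error = function(e) list(r = NA_real_, n_used = 0L))

    per_patient[[pat]] <- list(
      patient = pat, model_type = config$model_type[i], log = log,
      fdr = fdr, records = records,
      class_counts = table(records$q_class),
      contamination = contamination,
      maf_r = corr$r, maf_n = corr$n_used,
      cna = cna, concordance = conc,
      primary_profile = tryCatch(class_distribution(primary_calls),
                                 tf_error = function(e) NULL)
    )
  }

  dendro <- tryCatch(cluster_samples(build_logr_matrix(sample_results)),
                     tf_error = function(e) NULL)

  shared_pct <- vapply(per_patient, function(p) {
    prim <- p$records$somatic_in_primary
    if (!any(prim)) return(NA_real_)
    100 * mean(p$records$q_class[prim] %in%
                 c("shared_constant", "shared_changing"))
  }, numeric(1))

  report <- structure(list(
    config_seed = config$seed,
    patients = per_patient,
    dendrogram = dendro,
    shared_mutation_pct = shared_pct,
    cohort = cohort
  ), class = "tf_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' JSON summary plus per-patient comparison TSVs and SEG files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    seed = report$config_seed,
    shared_mutation_pct = as.list(report$shared_mutation_pct),
    dendrogram = if (!is.null(report$dendrogram))
      report$dendrogram$newick else NULL,
    patients = lapply(report$patients, function(p) {
      list(model_type = p$model_type,
           log = p$log,
           fdr_threshold = p$fdr$p_threshold,
           class_counts = as.list(p$class_counts),
           contamination = p$contamination,
           maf_r = p$maf_r, maf_n = p$maf_n,
           cna_consistent_fraction = p$concordance$consistent_fraction)
    })
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (pat in names(report$patients)) {
    p <- report$patients[[pat]]
    utils::write.table(p$records, file.path(dir, paste0(pat, "_comparison.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_seg(p$cna$primary$segments, paste0(pat, "_primary"),
              file.path(dir, paste0(pat, "_primary.seg")))
    write_seg(p$cna$model$segments, paste0(pat, "_model"),
              file.path(dir, paste0(pat, "_model.seg")))
  }
  invisible(dir)
}

#' @export
print.tf_report <- function(x, ...) {
  cat("tumorfidelity pipeline report\n")
  for (pat in names(x$patients)) {
    p <- x$patients[[pat]]
    cat(sprintf(
      "  %s (%s): %d compared sites, %.0f%% shared, contamination %.2f, CNA concordance %.2f\n",
      pat, p$model_type, nrow(p$records),
      x$shared_mutation_pct[[pat]], p$contamination,
      p$concordance$consistent_fraction))
  }
  invisible(x)
}
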
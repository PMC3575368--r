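# Readers and writers for the pipeline's plain-text interchange formats:
# multi-sample VCF and TSV site tables, dual-alignment read TSV, probe
# BED/TSV, cytoband TSV, SEG segment files and JSON reports.

#' Write a site table as a multi-sample VCF
#'
#' One record per site with per-sample allele depths in an AD-style FORMAT
#' field (GERMLINE, PRIMARY, MODEL columns), plus site annotations in INFO.
#'
#' @param sites Site table from [simulate_cohort()] or [read_sites_tsv()].
#' @param path Output path.
#' @export
write_sites_vcf <- function(sites, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tumorfidelity",
    "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"Known variant\">",
    "##INFO=<ID=QALT,Number=1,Type=Float,Description=\"Mean alt base quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "GERMLINE", "PRIMARY", "MODEL", sep = "\t")
  )
  info <- sprintf("VT=%s;CSQ=%s;GENE=%s;QALT=%.2f%s",
                  sites$variant_type, sites$consequence, sites$gene,
                  sites$mean_alt_quality,
                  ifelse(sites$known, ";KNOWN", ""))
  body <- paste(
    sites$chrom, sites$pos, sites$site_id, sites$ref, sites$alt, ".", ".",
    info, "AD",
    paste0(sites$germline_ref, ",", sites$germline_alt),
    paste0(sites$primary_ref, ",", sites$primary_alt),
    paste0(sites$model_ref, ",", sites$model_alt),
    sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read a site table as TSV
#'
#' @param sites Site table.
#' @param path File path.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  if (!file.exists(path)) validation_error(paste("file not found:", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a read table as TSV
#'
#' @param reads Read table.
#' @param path File path.
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write probe intervals as BED (0-based half-open)
#'
#' @param probes Probe table with `chrom`, `start`, `end`.
#' @param path File path.
#' @export
write_probes_bed <- function(probes, path) {
  utils::write.table(unique(probes[, c("chrom", "start", "end")]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write / read a cytoband table (UCSC cytoBand format)
#'
#' @param cytobands Cytoband table (chrom, start, end, band, stain).
#' @param path File path.
#' @export
write_cytobands_tsv <- function(cytobands, path) {
  utils::write.table(cytobands, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cytobands_tsv
#' @export
read_cytobands_tsv <- function(path) {
  if (!file.exists(path)) validation_error(paste("file not found:", path))
  cb <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(cb)[1:5] <- c("chrom", "start", "end", "band", "stain")
  cb
}

#' Write called segments in SEG format
#'
#' Columns: sample, chrom, start, end, n_probes, mean_logr (plus call and
#' confidence when present).
#'
#' @param segments Called segment table.
#' @param sample Sample name for the first column.
#' @param path File path.
#' @export
write_seg <- function(segments, sample, path) {
  cols <- intersect(c("chrom", "start", "end", "n_probes", "mean_logr",
                      "call", "confidence", "loh"), names(segments))
  out <- cbind(sample = sample, segments[, cols, drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to a directory of interchange files
#'
#' Emits the site table as VCF and TSV, reads as TSV, probes as BED + TSV,
#' cytobands in UCSC format and the ground truth as JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sites_vcf(cohort$sites, file.path(dir, "sites.vcf"))
  write_sites_tsv(cohort$sites, file.path(dir, "sites.tsv"))
  if (!is.null(cohort$reads)) {
    write_reads_tsv(cohort$reads, file.path(dir, "reads.tsv"))
  }
  write_probes_bed(cohort$probes, file.path(dir, "probes.bed"))
  utils::write.table(cohort$probes, file.path(dir, "probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_cytobands_tsv(cohort$cytobands, file.path(dir, "cytoBand.txt"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
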
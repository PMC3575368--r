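# Xenograft read deconvolution: each sequenced fragment of a xenograft
# sample is aligned to both the graft (human) and host (mouse) genomes; a
# filter cascade over mapping status, proper pairing and match score assigns
# it to a species. Only human calls are kept downstream.

#' Alignment match score
#'
#' `M = matches - mismatches`; the score used to choose between the human and
#' mouse alignments of a read when mapping status and pairing do not decide.
#'
#' @param matches,mismatches Non-negative counts (vectorised).
#' @return Integer vector of scores (may be negative).
#' @export
match_score <- function(matches, mismatches) {
  if (any(matches < 0, na.rm = TRUE) || any(mismatches < 0, na.rm = TRUE)) {
    validation_error("matches and mismatches must be non-negative")
  }
  as.integer(matches) - as.integer(mismatches)
}

#' Classify reads as human, mouse or ambiguous
#'
#' Cascade: (1) a read mapped to only one genome belongs to that genome;
#' (2) when mapped to both, the properly-paired genome wins if pairing
#' differs; (3) with pairing tied, the strictly greater match score wins;
#' (4) exact ties are ambiguous. "Better alignment" is read strictly, so
#' reads tying on both pairing and score are discarded rather than kept --
#' conservative against leakage at strongly orthologous regions.
#'
#' @param reads Data.frame with columns `read_id`, `human_mapped`,
#'   `human_proper_pair`, `human_matches`, `human_mismatches` and the four
#'   `mouse_*` counterparts.
#' @return Data.frame with `read_id`, `call` (human/mouse/ambiguous) and
#'   `reason` (cascade stage: mapped_one_genome, proper_pair, match_score,
#'   tie).
#' @export
classify_reads <- function(reads) {
  n <- nrow(reads)
  hm <- reads$human_mapped
  mm <- reads$mouse_mapped
  if (any(!hm & !mm)) {
    validation_error("every read must be mapped to at least one genome")
  }
  call <- character(n)
  reason <- character(n)

  only_h <- hm & !mm
  only_m <- mm & !hm
  call[only_h] <- "human"
  call[only_m] <- "mouse"
  reason[only_h | only_m] <- "mapped_one_genome"

  both <- hm & mm
  hp <- reads$human_proper_pair %in% TRUE
  mp <- reads$mouse_proper_pair %in% TRUE
  pair_h <- both & hp & !mp
  pair_m <- both & !hp & mp
  call[pair_h] <- "human"
  call[pair_m] <- "mouse"
  reason[pair_h | pair_m] <- "proper_pair"

  tied <- both & (hp == mp)
  if (any(tied)) {
    m_h <- match_score(reads$human_matches[tied], reads$human_mismatches[tied])
    m_m <- match_score(reads$mouse_matches[tied], reads$mouse_mismatches[tied])
    cc <- ifelse(m_h > m_m, "human", ifelse(m_m > m_h, "mouse", "ambiguous"))
    call[tied] <- cc
    reason[tied] <- ifelse(cc == "ambiguous", "tie", "match_score")
  }
  data.frame(read_id = reads$read_id, call = call, reason = reason,
             stringsAsFactors = FALSE)
}

#' Filter a read set to its human fraction
#'
#' @param reads Read table as for [classify_reads()].
#' @return A list: `kept_ids` (read ids called human), `calls` (the full
#'   classification) and `stats` (counts per call and per cascade reason;
#'   the call counts sum to the input size).
#' @export
filter_read_set <- function(reads) {
  if (is.null(reads) || nrow(reads) == 0) {
    return(list(
      kept_ids = character(0),
      calls = data.frame(read_id = character(0), call = character(0),
                         reason = character(0), stringsAsFactors = FALSE),
      stats = list(n_input = 0L,
                   by_call = c(human = 0L, mouse = 0L, ambiguous = 0L),
                   by_reason = integer(0))
    ))
  }
  calls <- classify_reads(reads)
  by_call <- vapply(c("human", "mouse", "ambiguous"),
                    function(k) sum(calls$call == k), integer(1))
  list(
    kept_ids = calls$read_id[calls$call == "human"],
    calls = calls,
    stats = list(n_input = nrow(reads), by_call = by_call,
                 by_reason = c(table(calls$reason)))
  )
}

#' Recompute model-sample allele counts after read filtering
#'
#' Candidate sites whose alternate support is carried by individually
#' identified reads (the `site_id` column of the read table) get their model
#' alternate count replaced by the number of supporting reads that survived
#' filtering. Sites without read-level support are untouched.
#'
#' @param sites Site table of one patient.
#' @param reads Read table of the same patient.
#' @param kept_ids Read ids retained by [filter_read_set()].
#' @return The site table with updated `model_alt`.
#' @export
recount_model_alt <- function(sites, reads, kept_ids) {
  sup <- reads[!is.na(reads$site_id), , drop = FALSE]
  if (nrow(sup) == 0) return(sites)
  affected <- unique(sup$site_id)
  kept <- sup[sup$read_id %in% kept_ids, , drop = FALSE]
  counts <- table(factor(kept$site_id, levels = affected))
  idx <- match(affected, sites$site_id)
  ok <- !is.na(idx)
  sites$model_alt[idx[ok]] <- as.integer(counts)[ok]
  sites
}

#' Read a dual-alignment summary TSV
#'
#' Column schema: read_id, human_mapped, human_proper_pair, human_matches,
#' human_mismatches, mouse_mapped, mouse_proper_pair, mouse_matches,
#' mouse_mismatches.
#'
#' @param path Path to the TSV file.
#' @return A read table suitable for [classify_reads()].
#' @export
read_dual_alignment_tsv <- function(path) {
  if (!file.exists(path)) validation_error(paste("file not found:", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}

cigar_aligned_bases <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    kinds <- sub("^[0-9]+", "", toks)
    sum(lens[kinds %in% c("M", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

parse_sam_summary <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(read_id = character(0), mapped = logical(0),
                      proper_pair = logical(0), matches = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t")
  qname <- vapply(fields, `[[`, character(1), 1)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2))
  cigar <- vapply(fields, `[[`, character(1), 6)
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f, value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else 0L
  }, integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  proper <- bitwAnd(flag, 2L) != 0L
  aligned <- cigar_aligned_bases(cigar)
  # NM counts mismatches (plus indel bases); aligned-base count minus NM is
  # the portable match count
  data.frame(read_id = qname, mapped = mapped, proper_pair = proper,
             matches = ifelse(mapped, pmax(0L, aligned - nm), NA_integer_),
             mismatches = ifelse(mapped, nm, NA_integer_),
             stringsAsFactors = FALSE)
}

#' Build a dual-alignment read table from two SAM files
#'
#' Adapter for the common case where the human and mouse alignments live in
#' separate SAM files. Matches are derived as aligned M-bases minus the NM
#' tag and mismatches as NM; a record absent from one file is treated as
#' unmapped in that genome.
#'
#' @param human_sam,mouse_sam Paths to SAM files of the same read set aligned
#'   to the human and mouse references.
#' @return A read table suitable for [classify_reads()].
#' @export
read_dual_alignment_sam <- function(human_sam, mouse_sam) {
  for (p in c(human_sam, mouse_sam)) {
    if (!file.exists(p)) validation_error(paste("file not found:", p))
  }
  h <- parse_sam_summary(human_sam)
  m <- parse_sam_summary(mouse_sam)
  ids <- union(h$read_id, m$read_id)
  hi <- match(ids, h$read_id)
  mi <- match(ids, m$read_id)
  pick <- function(df, i, col, default) {
    out <- df[[col]][i]
    out[is.na(i)] <- default
    out
  }
  data.frame(
    read_id = ids,
    human_mapped = pick(h, hi, "mapped", FALSE) %in% TRUE,
    human_proper_pair = pick(h, hi, "proper_pair", NA),
    human_matches = pick(h, hi, "matches", NA_integer_),
    human_mismatches = pick(h, hi, "mismatches", NA_integer_),
    mouse_mapped = pick(m, mi, "mapped", FALSE) %in% TRUE,
    mouse_proper_pair = pick(m, mi, "proper_pair", NA),
    mouse_matches = pick(m, mi, "matches", NA_integer_),
    mouse_mismatches = pick(m, mi, "mismatches", NA_integer_),
    stringsAsFactors = FALSE
  )
}
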
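# Exome copy-number calling: GC-corrected tumor/normal coverage log-ratios
# per capture probe, recursive binary segmentation with permutation
# p-values, segment and chromosome-arm calls, LOH flags, primary-vs-model
# base-pair concordance and sample relatedness by hierarchical clustering.

#' Correct probe coverages for GC content
#'
#' Coverage is divided by the median coverage of the probe's GC bin and
#' rescaled by the global median, separately per sample column. Bins with
#' fewer than `min_bin` probes are merged with their neighbours, so the
#' correction never rests on a handful of probes.
#'
#' @param probes Probe table with a `gc` column and the coverage columns.
#' @param bin_width GC bin width.
#' @param min_bin Minimum probes per bin before merging.
#' @param cols Coverage columns to correct.
#' @return The probe table with corrected coverages.
#' @export
gc_correct <- function(probes, bin_width = 0.01, min_bin = 10,
                       cols = c("normal_cov", "tumor_cov")) {
  if (any(probes$gc < 0 | probes$gc > 1)) {
    validation_error("gc must be a fraction in [0, 1]")
  }
  bin <- floor(probes$gc / bin_width)
  lev <- sort(unique(bin))
  counts <- table(factor(bin, levels = lev))
  # greedy left-to-right merge of small bins
  group <- integer(length(lev))
  g <- 1L
  acc <- 0L
  for (i in seq_along(lev)) {
    group[i] <- g
    acc <- acc + counts[i]
    if (acc >= min_bin && i < length(lev)) {
      g <- g + 1L
      acc <- 0L
    }
  }
  if (acc < min_bin && g > 1) {      # fold a small trailing group back
    group[group == g] <- g - 1L
  }
  grp <- group[match(bin, lev)]
  for (cl in cols) {
    x <- probes[[cl]]
    gm <- stats::median(x)
    med <- tapply(x, grp, stats::median)
    scale <- gm / med[as.character(grp)]
    scale[!is.finite(scale)] <- 1
    probes[[cl]] <- x * as.numeric(scale)
  }
  probes
}

#' Compute per-probe logR ratios
#'
#' `logr = log2((tumor_cov / sum(tumor_cov)) / (normal_cov / sum(normal_cov)))`.
#' Probes whose normal coverage is below `min_normal` (or with zero tumor
#' coverage) are flagged not-callable (`nc`) and carry `NA` logR.
#'
#' @param probes Probe table with `normal_cov` and `tumor_cov`.
#' @param min_normal Minimum normal coverage for a callable probe.
#' @return The probe table with `logr` and logical `nc` columns.
#' @export
compute_logr <- function(probes, min_normal = 10) {
  nt <- probes$tumor_cov / sum(probes$tumor_cov)
  nn <- probes$normal_cov / sum(probes$normal_cov)
  probes$nc <- probes$normal_cov < min_normal | probes$tumor_cov <= 0
  probes$logr <- ifelse(probes$nc, NA_real_, log2(nt / nn))
  probes
}

# Circular binary segmentation statistic: the maximal two-sample t
# statistic comparing the arc x[(i+1):j] against its complement, maximised
# over all boundary pairs 0 <= i < j <= n (excluding the full sequence).
# j = n reduces to an ordinary single split, so focal events flanked on
# both sides are caught as well as step changes. The boundary-pair index
# cache is built once per sequence length and reused across permutations.
cbs_pair_cache <- function(n) {
  ii <- rep(0:(n - 1), times = n:1)
  jj <- sequence(n:1) + ii
  k <- jj - ii
  keep <- k < n
  ii <- ii[keep]
  jj <- jj[keep]
  k <- k[keep]
  list(n = n, ii = ii, jj = jj, k = k, nk = n - k,
       w = 1 / k + 1 / (n - k))
}

cbs_stat <- function(x, cache) {
  n <- cache$n
  S <- c(0, cumsum(x))
  Q <- c(0, cumsum(x^2))
  sum_in <- S[cache$jj + 1] - S[cache$ii + 1]
  ss_raw <- Q[cache$jj + 1] - Q[cache$ii + 1]
  m_in <- sum_in / cache$k
  m_out <- (S[n + 1] - sum_in) / cache$nk
  ss <- (ss_raw - cache$k * m_in^2) +
    ((Q[n + 1] - ss_raw) - cache$nk * m_out^2)
  sp2 <- pmax(ss / max(n - 2, 1), 1e-12)
  tt <- abs(m_in - m_out) / sqrt(sp2 * cache$w)
  best <- which.max(tt)
  list(stat = tt[best], i = cache$ii[best], j = cache$jj[best])
}

# Permutation p-value of the best arc; sequential early stop once the
# exceedance count already guarantees p > alpha (never changes the
# accept/reject decision, only the resolution of clearly null p-values).
split_pvalue <- function(x, n_perm, alpha) {
  cache <- cbs_pair_cache(length(x))
  obs <- cbs_stat(x, cache)
  stop_at <- ceiling(alpha * (n_perm + 1))
  exceed <- 0L
  done <- 0L
  for (b in seq_len(n_perm)) {
    done <- b
    if (cbs_stat(sample(x), cache)$stat >= obs$stat) {
      exceed <- exceed + 1L
      if (exceed > stop_at) break
    }
  }
  list(p = (1 + exceed) / (1 + done), i = obs$i, j = obs$j)
}

#' Segment per-probe logR values into copy-number segments
#'
#' Circular-binary-segmentation-style recursive splitting: within each
#' chromosome the probe sequence is split at the position maximising the
#' two-sample t statistic of mean logR, a split being accepted when its
#' permutation p-value (label permutations of the probe values) is at most
#' `alpha`; accepted parts are split recursively. Runs with fewer than
#' `min_probes` callable probes form a single segment without testing.
#' Not-callable probes are carried by the enclosing segment but excluded
#' from its statistics.
#'
#' @param probes Probe table with `logr` (from [compute_logr()]), ordered or
#'   orderable by `chrom` and `start`.
#' @param alpha Split acceptance level.
#' @param n_perm Number of label permutations per tested split.
#' @param seed Integer seed.
#' @param min_probes Minimum callable probes for a split test.
#' @return A list: `segments` (chrom, start, end, n_probes, n_informative,
#'   mean_logr, segment_id) and `probes` (the input with a `segment_id`
#'   column). Segment probe counts sum to the probe total per chromosome.
#' @export
segment_probes <- function(probes, alpha = 0.01, n_perm = 1000, seed = 1L,
                           min_probes = 5) {
  probes <- probes[order(probes$chrom, probes$start), , drop = FALSE]
  probes$segment_id <- NA_integer_
  seg_rows <- list()
  seg_counter <- 0L
  with_seed(seed, {
    for (ch in unique(probes$chrom)) {
      idx <- which(probes$chrom == ch)
      ok <- idx[!probes$nc[idx] & is.finite(probes$logr[idx])]
      # recursive splitting over callable probes of this chromosome
      split_rec <- function(lo, hi) {
        pts <- ok[ok >= lo & ok <= hi]
        if (length(pts) >= min_probes) {
          res <- split_pvalue(probes$logr[pts], n_perm, alpha)
          if (res$p <= alpha) {
            # arc boundaries (i, j] in the callable-probe index space
            cuts <- integer(0)
            if (res$i > 0) cuts <- c(cuts, pts[res$i])
            if (res$j < length(pts)) cuts <- c(cuts, pts[res$j])
            bounds <- c(lo - 1, cuts, hi)
            return(invisible(lapply(seq_len(length(bounds) - 1), function(bb) {
              split_rec(bounds[bb] + 1, bounds[bb + 1])
            })))
          }
        }
        seg_counter <<- seg_counter + 1L
        probes$segment_id[idx[idx >= lo & idx <= hi]] <<- seg_counter
        vals <- probes$logr[pts]
        seg_rows[[seg_counter]] <<- data.frame(
          segment_id = seg_counter, chrom = ch,
          start = min(probes$start[idx[idx >= lo & idx <= hi]]),
          end = max(probes$end[idx[idx >= lo & idx <= hi]]),
          n_probes = sum(idx >= lo & idx <= hi),
          n_informative = length(pts),
          mean_logr = if (length(pts)) mean(vals) else NA_real_,
          sd_logr = if (length(pts) > 1) stats::sd(vals) else NA_real_,
          stringsAsFactors = FALSE
        )
        invisible(NULL)
      }
      split_rec(min(idx), max(idx))
    }
  })
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  # robust genome-wide per-probe logR noise scale, for the segment-call
  # significance guard
  resid <- probes$logr - segments$mean_logr[match(probes$segment_id,
                                                  segments$segment_id)]
  attr(segments, "sigma_probe") <- stats::mad(resid, na.rm = TRUE)
  list(segments = segments, probes = probes)
}

#' Call copy state and confidence of segments
#'
#' A segment is `neutral` when its mean logR lies within `neutral_band` of
#' zero, otherwise `amp` or `del` by sign; segments without callable probes
#' are `nc`. A significance guard keeps segments neutral when their mean,
#' although outside the band, is within `min_z` standard errors of zero.
#' Because the segmentation itself maximises contrast, the guard is
#' calibrated to the post-selection null scale (the maximal purely random
#' arc statistic reaches ~4.3 se), so a spurious split's offspring are not
#' mistaken for events -- the copy-number analogue of only calling what
#' the coverage can support. High-confidence (`hc`) grade is given to
#' amplifications above the 95th (deletions below the 5th) percentile of
#' the copy-neutral segments' logR values. When no neutral segment exists
#' the grading is skipped with a warning.
#'
#' @param segments Segment table from [segment_probes()].
#' @param neutral_band Half-width of the copy-neutral logR band.
#' @param min_z Minimum |mean| / standard error for a non-neutral call;
#'   inactive when the segment table carries no probe noise information
#'   (e.g. hand-built tables).
#' @return The segment table with `call` and `confidence` columns.
#' @export
call_segments <- function(segments, neutral_band = 0.2, min_z = 4.5) {
  call <- ifelse(segments$n_informative == 0 | !is.finite(segments$mean_logr),
                 "nc",
                 ifelse(abs(segments$mean_logr) <= neutral_band, "neutral",
                        ifelse(segments$mean_logr > 0, "amp", "del")))
  sigma <- attr(segments, "sigma_probe")
  if (is.null(sigma) && !is.null(segments$sd_logr)) {
    sigma <- stats::median(segments$sd_logr, na.rm = TRUE)
  }
  if (!is.null(sigma) && is.finite(sigma) && sigma > 0) {
    se <- sigma / sqrt(pmax(segments$n_informative, 1))
    weak <- call %in% c("amp", "del") &
      abs(segments$mean_logr) < min_z * se
    call[weak] <- "neutral"
  }
  segments$call <- call
  segments$confidence <- "standard"
  neutral_logr <- segments$mean_logr[call == "neutral"]
  if (length(neutral_logr) == 0) {
    if (any(call %in% c("amp", "del"))) {
      warning("no copy-neutral segments; high-confidence grading skipped")
    }
    return(segments)
  }
  q_hi <- stats::quantile(neutral_logr, 0.95, names = FALSE)
  q_lo <- stats::quantile(neutral_logr, 0.05, names = FALSE)
  hc <- (call == "amp" & segments$mean_logr > q_hi) |
    (call == "del" & segments$mean_logr < q_lo)
  segments$confidence[hc] <- "hc"
  segments
}

# Arm lookup from a cytoBand table: arm = leading p/q of the band name.
arm_table <- function(cytobands) {
  cb <- cytobands
  cb$arm <- substr(cb$band, 1, 1)
  lo <- stats::aggregate(start ~ chrom + arm, cb, min)
  hi <- stats::aggregate(end ~ chrom + arm, cb, max)
  out <- merge(lo, hi, by = c("chrom", "arm"))
  out[order(out$chrom, out$arm), , drop = FALSE]
}

#' Call chromosome-arm level copy-number aberrations
#'
#' An arm is called amplified (deleted) when more than `threshold` (default
#' 20%) of its targeted base pairs lie in segments consistently called in
#' that direction; when both directions exceed the threshold the larger
#' fraction wins, and mixed-direction patchwork never fakes an arm event.
#'
#' @param seg_result Result of [segment_probes()] whose segments carry calls
#'   (run [call_segments()] first and reassign, or pass `segments`).
#' @param segments Called segment table (with `call`).
#' @param probes Probe table with `segment_id` (targeted bp live on probes).
#' @param cytobands Cytoband table (chrom, start, end, band, stain).
#' @param threshold Fraction of targeted arm bp required for an arm call.
#' @return Data.frame with `chrom`, `arm`, `call`, `fraction_bp_amp`,
#'   `fraction_bp_del`, `fraction_bp_in_cna`.
#' @export
call_arms <- function(segments, probes, cytobands, threshold = 0.20) {
  arms <- arm_table(cytobands)
  probe_call <- segments$call[match(probes$segment_id, segments$segment_id)]
  probe_call[probes$nc] <- "nc"
  bp <- probes$end - probes$start
  mid <- (probes$start + probes$end) / 2
  out <- arms
  out$fraction_bp_amp <- NA_real_
  out$fraction_bp_del <- NA_real_
  for (i in seq_len(nrow(arms))) {
    sel <- probes$chrom == arms$chrom[i] & mid >= arms$start[i] &
      mid < arms$end[i]
    tot <- sum(bp[sel])
    out$fraction_bp_amp[i] <- if (tot > 0)
      sum(bp[sel & probe_call == "amp"]) / tot else 0
    out$fraction_bp_del[i] <- if (tot > 0)
      sum(bp[sel & probe_call == "del"]) / tot else 0
  }
  out$call <- ifelse(
    out$fraction_bp_amp > threshold & out$fraction_bp_amp >= out$fraction_bp_del,
    "amp",
    ifelse(out$fraction_bp_del > threshold, "del", "neutral"))
  out$fraction_bp_in_cna <- pmax(out$fraction_bp_amp, out$fraction_bp_del)
  out[, c("chrom", "arm", "call", "fraction_bp_amp", "fraction_bp_del",
          "fraction_bp_in_cna")]
}

#' Flag segments with loss of heterozygosity
#'
#' A segment is LOH when at least `min_sites` germline-heterozygous sites
#' fall inside it and the median tumor B-allele fraction departs from 0.5 by
#' at least `shift`.
#'
#' @param het_sites Germline-het sites with `chrom`, `pos` and tumor counts
#'   `tumor_ref`, `tumor_alt`.
#' @param segments Segment table.
#' @param min_sites Minimum het sites for a call.
#' @param shift Minimum departure of the median BAF from 0.5.
#' @return The segment table with a logical `loh` column.
#' @export
call_loh <- function(het_sites, segments, min_sites = 10, shift = 0.2) {
  segments$loh <- FALSE
  if (nrow(het_sites) == 0) return(segments)
  depth <- het_sites$tumor_ref + het_sites$tumor_alt
  baf <- ifelse(depth > 0, het_sites$tumor_alt / depth, NA_real_)
  for (i in seq_len(nrow(segments))) {
    sel <- het_sites$chrom == segments$chrom[i] &
      het_sites$pos > segments$start[i] & het_sites$pos <= segments$end[i] &
      is.finite(baf)
    if (sum(sel) >= min_sites &&
        abs(stats::median(baf[sel]) - 0.5) >= shift) {
      segments$loh[i] <- TRUE
    }
  }
  segments
}

probe_level_calls <- function(seg_result) {
  segs <- seg_result$segments
  probes <- seg_result$probes
  call <- segs$call[match(probes$segment_id, segs$segment_id)]
  conf <- segs$confidence[match(probes$segment_id, segs$segment_id)]
  call[probes$nc] <- "nc"
  data.frame(chrom = probes$chrom, start = probes$start, end = probes$end,
             call = call, hc = conf == "hc" & !probes$nc,
             stringsAsFactors = FALSE)
}

#' Base-pair concordance of two copy-number profiles
#'
#' Over the targeted base pairs lying inside high-confidence segments of
#' either sample, the per-probe copy state of the two samples is
#' cross-tabulated; the consistent fraction is the diagonal (amp/del/neutral
#' agreeing) over all base pairs classified in both samples (`nc` excluded).
#' Both samples must be called on the same probe layout.
#'
#' @param primary,model Results of [segment_probes()] with called segments
#'   (i.e. `segments` passed through [call_segments()]).
#' @return List with the bp `contingency` matrix over
#'   \{amp, del, neutral, nc\}^2 and `consistent_fraction`.
#' @export
cna_concordance <- function(primary, model) {
  pc <- probe_level_calls(primary)
  mc <- probe_level_calls(model)
  key_p <- paste(pc$chrom, pc$start)
  key_m <- paste(mc$chrom, mc$start)
  if (!identical(sort(key_p), sort(key_m))) {
    validation_error("primary and model must share the same probe layout")
  }
  mc <- mc[match(key_p, key_m), , drop = FALSE]
  include <- pc$hc | mc$hc
  bp <- (pc$end - pc$start)[include]
  lv <- c("amp", "del", "neutral", "nc")
  f_p <- factor(pc$call[include], levels = lv)
  f_m <- factor(mc$call[include], levels = lv)
  contingency <- tapply(bp, list(primary = f_p, model = f_m), sum,
                        default = 0)
  classified <- f_p != "nc" & f_m != "nc"
  consistent <- classified & (as.character(f_p) == as.character(f_m))
  denom <- sum(bp[classified])
  list(contingency = contingency,
       consistent_fraction = if (denom > 0) sum(bp[consistent]) / denom
                             else NA_real_)
}

#' Mean logR matrix over the union of high-confidence segments
#'
#' Collects the hc segments of every sample, reduces them to a union of
#' disjoint intervals, and fills a samples x intervals matrix with each
#' sample's mean probe logR inside every interval -- the copy-number
#' signature used for sample relatedness.
#'
#' @param sample_results Named list of per-sample [segment_probes()] results
#'   with called segments.
#' @return A numeric matrix (samples x union intervals).
#' @export
build_logr_matrix <- function(sample_results) {
  hc_list <- lapply(sample_results, function(res) {
    s <- res$segments
    s[s$confidence == "hc", c("chrom", "start", "end"), drop = FALSE]
  })
  hc_all <- do.call(rbind, hc_list)
  if (is.null(hc_all) || nrow(hc_all) == 0) {
    validation_error("no high-confidence segments in any sample")
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    hc_all$chrom, IRanges::IRanges(hc_all$start + 1, hc_all$end)))
  u_chrom <- as.character(GenomicRanges::seqnames(gr))
  u_start <- GenomicRanges::start(gr) - 1
  u_end <- GenomicRanges::end(gr)
  m <- matrix(NA_real_, nrow = length(sample_results), ncol = length(gr),
              dimnames = list(names(sample_results),
                              paste0(u_chrom, ":", u_start, "-", u_end)))
  for (s in seq_along(sample_results)) {
    probes <- sample_results[[s]]$probes
    mid <- (probes$start + probes$end) / 2
    for (j in seq_along(gr)) {
      sel <- probes$chrom == u_chrom[j] & mid > u_start[j] & mid <= u_end[j] &
        !probes$nc & is.finite(probes$logr)
      m[s, j] <- if (any(sel)) mean(probes$logr[sel]) else 0
    }
  }
  m
}

#' Cluster samples by their copy-number signature
#'
#' Pairwise Euclidean distance over the logR matrix and average-linkage
#' hierarchical clustering; deterministic given the input (rows are ordered
#' lexicographically by sample name before clustering).
#'
#' @param logr_matrix Samples x segments matrix from [build_logr_matrix()].
#' @return A list of class `tf_dendrogram`: `newick` string, the `hclust`
#'   object (NULL for a single sample) and the cophenetic distance matrix.
#' @export
cluster_samples <- function(logr_matrix) {
  logr_matrix <- logr_matrix[order(rownames(logr_matrix)), , drop = FALSE]
  if (nrow(logr_matrix) == 1) {
    return(structure(list(newick = paste0(rownames(logr_matrix), ";"),
                          hclust = NULL, cophenetic = NULL),
                     class = "tf_dendrogram"))
  }
  h <- stats::hclust(stats::dist(logr_matrix), method = "average")
  newick <- ape::write.tree(ape::as.phylo(h))
  structure(list(newick = newick, hclust = h,
                 cophenetic = as.matrix(stats::cophenetic(h))),
            class = "tf_dendrogram")
}

#' @export
print.tf_dendrogram <- function(x, ...) {
  cat("Sample dendrogram (average-linkage, Euclidean):\n ", x$newick, "\n")
  invisible(x)
}

#' Plot per-probe logR with segment means
#'
#' Simple per-chromosome diagnostic plot of probe logR values with the
#' fitted segment means overlaid.
#'
#' @param seg_result A [segment_probes()] result with called segments.
#' @param chrom Chromosome to plot.
#' @export
plot_logr <- function(seg_result, chrom) {
  probes <- seg_result$probes
  segs <- seg_result$segments
  p <- probes[probes$chrom == chrom & !probes$nc, ]
  s <- segs[segs$chrom == chrom, ]
  graphics::plot(p$start, p$logr, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.6),
                 xlab = paste(chrom, "position"), ylab = "logR")
  graphics::segments(s$start, s$mean_logr, s$end, s$mean_logr,
                     col = "red", lwd = 2)
  invisible(NULL)
}
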
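# Copy-number module: GC correction, logR, segmentation accuracy, segment
# and arm calls, LOH, concordance accounting and clustering.

flat_probes <- function(n, logr_sd = 0, chrom = "chr1", mean_logr = 0,
                        seed = 1) {
  set.seed(seed)
  start <- seq(0, by = 1000, length.out = n)
  data.frame(chrom = chrom, start = start, end = start + 120,
             gc = runif(n, 0.3, 0.6),
             normal_cov = 60, tumor_cov = 60,
             logr = rnorm(n, mean_logr, max(logr_sd, 1e-12)),
             nc = FALSE)
}

test_that("GC correction flattens a constructed coverage-GC dependence", {
  set.seed(51)
  n <- 2000
  gc <- runif(n, 0.2, 0.7)
  probes <- data.frame(chrom = "chr1",
                       start = seq(0, by = 1000, length.out = n))
  probes$end <- probes$start + 120
  probes$gc <- gc
  # deterministic monotone bias: coverage an exact function of GC
  probes$normal_cov <- 40 + 100 * gc
  probes$tumor_cov <- 40 + 100 * gc
  out <- gc_correct(probes)
  expect_lt(stats::sd(out$normal_cov) / mean(out$normal_cov), 0.05)
  # unbiased input passes through almost unchanged
  probes2 <- probes
  probes2$normal_cov <- rep(60, n)
  out2 <- gc_correct(probes2)
  expect_lt(max(abs(out2$normal_cov - probes2$normal_cov) /
                  probes2$normal_cov), 0.01)
  # all probes at the same GC: identity transform
  probes3 <- probes
  probes3$gc <- 0.5
  expect_equal(gc_correct(probes3)$normal_cov, probes3$normal_cov)
})

test_that("GC correction removes the logR-GC correlation on biased counts", {
  set.seed(52)
  n <- 3000
  gc <- runif(n, 0.2, 0.7)
  probes <- data.frame(chrom = "chr1",
                       start = seq(0, by = 1000, length.out = n))
  probes$end <- probes$start + 120
  probes$gc <- gc
  probes$normal_cov <- rnbinom(n, mu = 60, size = 20)
  probes$tumor_cov <- rnbinom(n, mu = 60 * (0.4 + 1.6 * gc), size = 20)
  raw <- compute_logr(probes)
  expect_gt(abs(cor(raw$logr, raw$gc, use = "complete.obs")), 0.3)
  corrected <- compute_logr(gc_correct(probes))
  expect_lt(abs(cor(corrected$logr, corrected$gc, use = "complete.obs")),
            0.05)
})

test_that("logR follows its definition and flags uncallable probes", {
  probes <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                       end = c(120, 1120, 2120), gc = 0.45,
                       normal_cov = c(60, 60, 0), tumor_cov = c(60, 90, 60))
  out <- compute_logr(probes, min_normal = 10)
  expect_true(out$nc[3])
  expect_true(is.na(out$logr[3]))
  # with equal library totals the 1.5x probe sits at log2(1.5) up to the
  # normalisation induced by the other probes
  probes2 <- data.frame(chrom = "chr1", start = 0:99 * 1000,
                        end = 0:99 * 1000 + 120, gc = 0.45,
                        normal_cov = 60,
                        tumor_cov = c(rep(60, 99), 90))
  out2 <- compute_logr(probes2)
  expect_lt(abs(out2$logr[100] - log2(1.5)), 0.02)
  expect_lt(abs(out2$logr[1]), 0.02)
})

test_that("a constant chromosome yields a single untested segment", {
  seg <- segment_probes(flat_probes(100, logr_sd = 0.1, seed = 53),
                        seed = 1)
  expect_equal(nrow(seg$segments), 1L)
  expect_equal(seg$segments$n_probes, 100L)
  tiny <- segment_probes(flat_probes(4, logr_sd = 0.1, seed = 54), seed = 1)
  expect_equal(nrow(tiny$segments), 1L)
})

test_that("a clean step is located within three probes in at least 95% of seeds", {
  hits <- vapply(1:20, function(s) {
    probes <- flat_probes(100, seed = 100 + s)
    set.seed(200 + s)
    probes$logr <- rnorm(100, 0, 0.1) + c(rep(0, 50), rep(0.58, 50))
    seg <- segment_probes(probes, seed = s)
    bks <- seg$segments$start / 1000 + 1
    any(abs(bks - 51) <= 3)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("segment probe counts cover each chromosome exactly once", {
  co <- simulate_cohort(cohort_config(n_patients = 1,
                                      model_type = "neurosphere",
                                      n_germline_sites = 50,
                                      n_somatic_sites = 50,
                                      n_probes_per_chrom = 60, seed = 55))
  pr <- compute_logr(gc_correct(co$probes[co$probes$sample == "primary", ]))
  seg <- segment_probes(pr, seed = 2)
  by_chrom <- tapply(seg$segments$n_probes, seg$segments$chrom, sum)
  expect_true(all(by_chrom == 60))
  expect_false(any(is.na(seg$probes$segment_id)))
})

test_that("segment calling grades clear outliers as high confidence", {
  segs <- data.frame(segment_id = 1:21, chrom = paste0("chr", 1:21),
                     start = 0, end = 1e6, n_probes = 50,
                     n_informative = 50,
                     mean_logr = c(rnorm(20, 0, 0.1), 2.2))
  out <- call_segments(segs)
  expect_equal(out$call[21], "amp")
  expect_equal(out$confidence[21], "hc")
  expect_true(all(out$confidence[abs(out$mean_logr) <= 0.2] == "standard"))
  # all neutral: no hc grades
  segs2 <- segs
  segs2$mean_logr <- rnorm(21, 0, 0.05)
  expect_true(all(call_segments(segs2)$confidence == "standard"))
  # no neutral segment at all: grading skipped with a warning
  segs3 <- segs[1:3, ]
  segs3$mean_logr <- c(1, -1, 2)
  expect_warning(out3 <- call_segments(segs3), "neutral")
  expect_true(all(out3$confidence == "standard"))
})

test_that("the arm rule fires above 20% affected base pairs and not below", {
  cyto <- data.frame(chrom = "chr1", start = c(0, 5e6), end = c(5e6, 1e7),
                     band = c("p11", "q11"), stain = "gneg")
  mk <- function(frac_del) {
    n <- 100
    start <- seq(0, by = 5e4, length.out = n)
    probes <- data.frame(chrom = "chr1", start = start, end = start + 120,
                         gc = 0.45, nc = FALSE,
                         segment_id = rep(1:2, c(round(frac_del * n),
                                                 n - round(frac_del * n))))
    segs <- data.frame(segment_id = 1:2, chrom = "chr1",
                       start = c(0, round(frac_del * n) * 5e4),
                       end = c(round(frac_del * n) * 5e4, 5e6),
                       n_probes = c(round(frac_del * n),
                                    n - round(frac_del * n)),
                       n_informative = c(round(frac_del * n),
                                         n - round(frac_del * n)),
                       mean_logr = c(-1, 0), call = c("del", "neutral"))
    call_arms(segs, probes, cyto)
  }
  out25 <- mk(0.25)
  expect_equal(out25$call[out25$arm == "p"], "del")
  out19 <- mk(0.19)
  expect_equal(out19$call[out19$arm == "p"], "neutral")
  # whole-arm amplification
  outall <- mk(0)
  probes <- data.frame(chrom = "chr1", start = seq(0, by = 5e4,
                                                   length.out = 100))
  probes$end <- probes$start + 120
  probes$gc <- 0.45; probes$nc <- FALSE; probes$segment_id <- 1L
  segs <- data.frame(segment_id = 1, chrom = "chr1", start = 0, end = 5e6,
                     n_probes = 100, n_informative = 100,
                     mean_logr = 0.58, call = "amp")
  outamp <- call_arms(segs, probes, cyto)
  expect_equal(outamp$call[outamp$arm == "p"], "amp")
  expect_equal(outamp$fraction_bp_in_cna[outamp$arm == "p"], 1)
})

test_that("LOH flags need enough het sites and a shifted allele balance", {
  segs <- data.frame(segment_id = 1:3, chrom = "chr1",
                     start = c(0, 1e6, 2e6), end = c(1e6, 2e6, 3e6),
                     n_probes = 10, n_informative = 10, mean_logr = 0)
  het <- function(n, pos0, baf) {
    data.frame(chrom = "chr1", pos = pos0 + seq_len(n) * 1000,
               tumor_ref = round(60 * (1 - baf)), tumor_alt = round(60 * baf))
  }
  sites <- rbind(het(20, 0, 0.5),      # balanced -> no loh
                 het(20, 1e6, 0.05),   # collapsed -> loh
                 het(5, 2e6, 0.05))    # too few sites -> no call
  out <- call_loh(sites, segs)
  expect_equal(out$loh, c(FALSE, TRUE, FALSE))
})

test_that("concordance accounting matches on identical and disjoint calls", {
  mk_res <- function(call, mean_logr, hc = TRUE) {
    n <- 50
    start <- seq(0, by = 1000, length.out = n)
    probes <- data.frame(chrom = "chr1", start = start, end = start + 120,
                         gc = 0.45, nc = FALSE, logr = mean_logr,
                         segment_id = 1L)
    segs <- data.frame(segment_id = 1L, chrom = "chr1", start = 0,
                       end = max(start) + 120, n_probes = n,
                       n_informative = n, mean_logr = mean_logr,
                       call = call,
                       confidence = if (hc) "hc" else "standard")
    list(segments = segs, probes = probes)
  }
  same <- cna_concordance(mk_res("amp", 0.6), mk_res("amp", 0.6))
  expect_equal(same$consistent_fraction, 1.0)
  expect_equal(sum(same$contingency), 50 * 120)
  opposite <- cna_concordance(mk_res("amp", 0.6), mk_res("del", -0.6))
  expect_equal(opposite$consistent_fraction, 0.0)
  # contingency totals equal the targeted bp in the union of hc segments
  none <- cna_concordance(mk_res("neutral", 0, hc = FALSE),
                          mk_res("neutral", 0, hc = FALSE))
  expect_equal(sum(none$contingency), 0)
})

test_that("a faithful primary/model pair at purity 0.9 is highly concordant", {
  cfg <- cohort_config(n_patients = 1, model_type = "neurosphere",
                       primary_purity = 0.9, n_germline_sites = 50,
                       n_somatic_sites = 50, seed = 56)
  co <- simulate_cohort(cfg)
  res <- lapply(c(primary = "primary", model = "model"), function(s) {
    pr <- compute_logr(gc_correct(co$probes[co$probes$sample == s, ]))
    seg <- segment_probes(pr, seed = 57)
    seg$segments <- call_segments(seg$segments)
    seg
  })
  conc <- cna_concordance(res$primary, res$model)
  expect_gte(conc$consistent_fraction, 0.9)
  # the known events are recovered as high-confidence calls in both samples
  for (r in res) {
    s <- r$segments
    expect_true(any(s$chrom == "chr7" & s$call == "amp" &
                      s$confidence == "hc"))
    expect_true(any(s$chrom == "chr10" & s$call == "del" &
                      s$confidence == "hc"))
  }
})

test_that("clustering is deterministic and joins duplicates at height zero", {
  m <- matrix(rnorm(40), nrow = 4,
              dimnames = list(c("s1", "s2", "s3", "s1_copy"), NULL))
  m["s1_copy", ] <- m["s1", ]
  dd <- cluster_samples(m)
  h <- dd$hclust
  pair <- which(h$merge[, 1] < 0 & h$merge[, 2] < 0 &
                  h$height < 1e-12)
  expect_length(pair, 1)
  joined <- sort(h$labels[-h$merge[pair, ]])
  expect_equal(joined, c("s1", "s1_copy"))
  single <- cluster_samples(m[1, , drop = FALSE])
  expect_equal(single$newick, "s1;")
  expect_true(grepl(";$", dd$newick))
})
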
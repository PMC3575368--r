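# Primary-vs-model comparison: the two-sided test, the permutation FDR
# contract, fidelity classification, MAF correlation and the contamination
# estimator.

test_that("compare_site matches the enumeration oracle on anchor tables", {
  expect_equal(compare_site(c(30, 30), c(30, 30)), 1.0)
  p <- compare_site(c(50, 0), c(0, 50))
  expect_lt(p, 1e-20)
  expect_lt(abs(p - oracle_fisher_two(50, 0, 0, 50)), 1e-25)
  p2 <- compare_site(c(43, 45), c(40, 44))
  expect_gt(p2, 0.85)
  expect_lt(abs(p2 - oracle_fisher_two(43, 45, 40, 44)), 1e-10)
})

test_that("permutation_fdr validates its inputs and is deterministic", {
  rec <- null_records(50, seed = 1)
  expect_error(permutation_fdr(rec, n_permutations = 10),
               class = "tf_validation_error")
  expect_error(permutation_fdr(rec[0, ], 500), class = "tf_validation_error")
  a <- suppressWarnings(permutation_fdr(rec, 200, seed = 5))
  b <- suppressWarnings(permutation_fdr(rec, 200, seed = 5))
  expect_identical(a$p_threshold, b$p_threshold)
  expect_identical(a$grid, b$grid)
})

test_that("the permutation FDR controls false discoveries under the null", {
  rec <- null_records(1000, seed = 2)
  fdr <- suppressWarnings(permutation_fdr(rec, 500, seed = 3))
  sig_frac <- mean(rec$p_two_sided <= fdr$p_threshold)
  mc_se <- sqrt(0.05 * 0.95 / nrow(rec))
  expect_lte(sig_frac, 0.05 + 2 * mc_se)
  expect_lte(fdr$estimated_fdr_at_threshold, fdr$target_fdr)
})

test_that("the FDR threshold finds real frequency changes at controlled cost", {
  set.seed(4)
  n <- 1000
  shifted <- sample(n, 200)
  f <- runif(n, 0.1, 0.5)
  f2 <- f
  f2[shifted] <- pmin(f[shifted] + 0.3, 0.95)
  pa <- rbinom(n, 60, f)
  ma <- rbinom(n, 60, f2)
  rec <- data.frame(primary_ref = 60 - pa, primary_alt = pa,
                    model_ref = 60 - ma, model_alt = ma,
                    primary_maf = pa / 60, model_maf = ma / 60)
  rec$p_two_sided <- fisher_two_sided(rec$primary_ref, rec$primary_alt,
                                      rec$model_ref, rec$model_alt)
  fdr <- permutation_fdr(rec, 500, seed = 5)
  sig <- rec$p_two_sided <= fdr$p_threshold
  expect_gt(mean(sig[shifted]), 0)
  n_disc <- sum(sig)
  realized <- sum(sig[-shifted]) / max(1, n_disc)
  expect_lte(realized, 0.05 + 2 * sqrt(0.05 * 0.95 / max(1, n_disc)))
})

test_that("classification is exhaustive, exclusive and matches the rules", {
  rec <- data.frame(
    primary_ref = c(30, 30, 40), primary_alt = c(30, 30, 20),
    model_ref = c(29, 60, 20), model_alt = c(31, 0, 40)
  )
  rec$primary_maf <- rec$primary_alt / 60
  rec$model_maf <- rec$model_alt / (rec$model_ref + rec$model_alt)
  rec$p_two_sided <- fisher_two_sided(rec$primary_ref, rec$primary_alt,
                                      rec$model_ref, rec$model_alt)
  out <- classify_records(rec, list(p_threshold = 0.01))
  expect_equal(out$q_class,
               c("shared_constant", "primary_only", "shared_changing"))
  # partition property on a larger random table
  rec2 <- null_records(300, seed = 6)
  out2 <- classify_records(rec2, list(p_threshold = 0.02))
  expect_equal(sum(table(factor(out2$q_class,
                                levels = c("shared_constant", "shared_changing",
                                           "primary_only", "model_only")))),
               nrow(rec2))
})

test_that("MAF correlation needs depth and reports faithful models above 0.7", {
  rec <- data.frame(primary_ref = c(40, 30, 20), primary_alt = c(20, 30, 40),
                    model_ref = c(40, 30, 20), model_alt = c(20, 30, 40))
  rec$primary_maf <- rec$primary_alt / 60
  rec$model_maf <- rec$model_alt / 60
  expect_equal(maf_correlation(rec)$r, 1.0)
  expect_error(maf_correlation(rec, min_depth = 100),
               class = "tf_insufficient_data_error")
  # simulated faithful pair: same CCFs, purities 0.8 vs 1.0, 60x, 300 sites
  set.seed(7)
  ccf <- sample(c(1, 0.4), 300, replace = TRUE, prob = c(0.7, 0.3))
  fp <- ccf * 0.8 / 2
  fm <- ccf / 2
  pa <- rbinom(300, 60, fp)
  ma <- rbinom(300, 60, fm)
  rec2 <- data.frame(primary_ref = 60 - pa, primary_alt = pa,
                     model_ref = 60 - ma, model_alt = ma,
                     primary_maf = pa / 60, model_maf = ma / 60)
  expect_gt(maf_correlation(rec2)$r, 0.7)
})

test_that("contamination is recovered from the MAF ratio", {
  mk <- function(pm, mm) {
    n <- length(pm)
    data.frame(primary_maf = pm, model_maf = mm, chrom = "chr1",
               pos = seq_len(n), q_class = "shared_constant")
  }
  expect_equal(suppressWarnings(
    estimate_contamination(mk(rep(0.5, 20), rep(0.5, 20)))), 0)
  expect_equal(suppressWarnings(
    estimate_contamination(mk(rep(0.25, 20), rep(0.5, 20)))), 0.5)
  expect_error(suppressWarnings(estimate_contamination(mk(0.2, 0.4))),
               class = "tf_insufficient_data_error")
  # parameter recovery at the cohort's contamination levels
  for (cc in c(0.09, 0.11, 0.25, 0.41)) {
    set.seed(round(1000 * cc))
    ma <- rbinom(150, 60, 0.5)
    pa <- rbinom(150, 60, 0.5 * (1 - cc))
    est <- suppressWarnings(estimate_contamination(mk(pa / 60, ma / 60)))
    expect_lte(abs(est - cc), 0.05)
  }
})

test_that("the contamination estimator is nearly unbiased at c = 0.25", {
  set.seed(8)
  est <- replicate(50, {
    ma <- rbinom(150, 60, 0.5)
    pa <- rbinom(150, 60, 0.5 * 0.75)
    rec <- data.frame(primary_maf = pa / 60, model_maf = ma / 60,
                      chrom = "chr1", pos = 1:150,
                      q_class = "shared_constant")
    suppressWarnings(estimate_contamination(rec))
  })
  expect_lte(abs(mean(est) - 0.25), 0.02)
})

test_that("contamination-driven changes are unidirectional", {
  # only the primary is contaminated, so significant frequency changes
  # should almost all point toward the (purer) model
  set.seed(9)
  f <- runif(600, 0.2, 0.5)
  pa <- rbinom(600, 60, f * 0.6)
  ma <- rbinom(600, 60, f)
  rec <- data.frame(primary_ref = 60 - pa, primary_alt = pa,
                    model_ref = 60 - ma, model_alt = ma,
                    primary_maf = pa / 60, model_maf = ma / 60)
  rec$p_two_sided <- fisher_two_sided(rec$primary_ref, rec$primary_alt,
                                      rec$model_ref, rec$model_alt)
  fdr <- permutation_fdr(rec, 300, seed = 10)
  out <- classify_records(rec, fdr)
  ch <- out[out$q_class == "shared_changing", ]
  expect_gt(nrow(ch), 10)
  expect_gte(mean(ch$model_maf > ch$primary_maf), 0.9)
})
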
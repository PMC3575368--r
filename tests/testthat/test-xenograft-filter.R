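# Xenograft read filter: the match score, the decision cascade, set-level
# accounting and the downstream effect on somatic calls.

rec <- function(hm, hp, hma, hmi, mm, mp, mma, mmi, id = "r1") {
  data.frame(read_id = id,
             human_mapped = hm, human_proper_pair = hp,
             human_matches = hma, human_mismatches = hmi,
             mouse_mapped = mm, mouse_proper_pair = mp,
             mouse_matches = mma, mouse_mismatches = mmi,
             stringsAsFactors = FALSE)
}

test_that("match score is matches minus mismatches", {
  expect_equal(match_score(48, 2), 46L)
  expect_equal(match_score(0, 0), 0L)
  expect_equal(match_score(3, 10), -7L)
  expect_error(match_score(-1, 0), class = "tf_validation_error")
})

test_that("the cascade decides by mapping, then pairing, then match score", {
  # human-specific alignment wins at stage 1
  r <- classify_reads(rec(TRUE, TRUE, 48, 2, FALSE, NA, NA, NA))
  expect_equal(r$call, "human")
  expect_equal(r$reason, "mapped_one_genome")
  # pairing tie, match score decides
  r <- classify_reads(rec(TRUE, TRUE, 48, 2, TRUE, TRUE, 35, 15))
  expect_equal(r$call, "human")
  expect_equal(r$reason, "match_score")
  # proper pairing beats a better match score
  r <- classify_reads(rec(TRUE, FALSE, 49, 1, TRUE, TRUE, 40, 10))
  expect_equal(r$call, "mouse")
  expect_equal(r$reason, "proper_pair")
  # exact tie on pairing and score is ambiguous and dropped
  r <- classify_reads(rec(TRUE, TRUE, 48, 2, TRUE, TRUE, 48, 2))
  expect_equal(r$call, "ambiguous")
  expect_equal(r$reason, "tie")
  expect_error(classify_reads(rec(FALSE, NA, NA, NA, FALSE, NA, NA, NA)),
               class = "tf_validation_error")
})

test_that("every read receives exactly one call and the stats reconcile", {
  cfg <- cohort_config(n_patients = 1, model_type = "xenograft",
                       mouse_read_fraction = 0.3, n_reads = 4000,
                       n_germline_sites = 100, n_somatic_sites = 50,
                       seed = 12)
  co <- simulate_cohort(cfg)
  fr <- filter_read_set(co$reads)
  expect_equal(nrow(fr$calls), nrow(co$reads))
  expect_equal(sum(fr$stats$by_call), fr$stats$n_input)
  expect_equal(sum(fr$stats$by_reason), fr$stats$n_input)
  expect_setequal(fr$kept_ids, fr$calls$read_id[fr$calls$call == "human"])
})

test_that("human-specific read sets pass through unchanged", {
  n <- 200
  reads <- rec(TRUE, TRUE, 48, 2, FALSE, NA, NA, NA)[rep(1, n), ]
  reads$read_id <- sprintf("r%03d", seq_len(n))
  fr <- filter_read_set(reads)
  expect_setequal(fr$kept_ids, reads$read_id)
  fr0 <- filter_read_set(reads[0, ])
  expect_length(fr0$kept_ids, 0)
  expect_equal(fr0$stats$n_input, 0L)
})

test_that("a 40% contaminated xenograft loses its mouse reads, not its human reads", {
  cfg <- cohort_config(n_patients = 1, model_type = "xenograft",
                       mouse_read_fraction = 0.4, n_reads = 12000,
                       n_germline_sites = 100, n_somatic_sites = 80,
                       seed = 13)
  co <- simulate_cohort(cfg)
  fr <- filter_read_set(co$reads)
  is_mouse <- co$truth$reads$species[match(fr$calls$read_id,
                                           co$truth$reads$read_id)] == "mouse"
  expect_gte(mean(fr$calls$call[is_mouse] != "human"), 0.95)
  expect_lte(mean(fr$calls$call[!is_mouse] != "human"), 0.05)
})

test_that("read filtering shrinks the xenograft somatic call set", {
  cfg <- cohort_config(n_patients = 1, model_type = "xenograft",
                       mouse_read_fraction = 0.4, n_reads = 12000,
                       n_germline_sites = 200, n_somatic_sites = 80,
                       seed = 14)
  co <- simulate_cohort(cfg)
  before <- call_variants(co$sites, "model")
  fr <- filter_read_set(co$reads)
  after <- call_variants(recount_model_alt(co$sites, co$reads, fr$kept_ids),
                         "model")
  expect_lt(sum(after$status == "somatic"), sum(before$status == "somatic"))
  # surviving somatic calls are overwhelmingly true somatic events
  st <- co$truth$sites$status[match(after$site_id[after$status == "somatic"],
                                    co$truth$sites$site_id)]
  expect_gt(mean(startsWith(st, "somatic")), 0.95)
})

test_that("the SAM adapter reconstructs mapping, pairing and match counts", {
  sam_h <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000000",
    "r1\t2\tchr1\t100\t60\t50M\t=\t300\t250\tACGT\t####\tNM:i:2",
    "r2\t0\tchr1\t500\t60\t40M10S\t*\t0\t0\tACGT\t####\tNM:i:1",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t####"
  )
  sam_m <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "r1\t0\tchr5\t100\t60\t50M\t*\t0\t0\tACGT\t####\tNM:i:10",
    "r3\t2\tchr5\t900\t60\t50M\t=\t1100\t250\tACGT\t####\tNM:i:0"
  )
  fh <- tempfile(fileext = ".sam"); writeLines(sam_h, fh)
  fm <- tempfile(fileext = ".sam"); writeLines(sam_m, fm)
  reads <- read_dual_alignment_sam(fh, fm)
  reads <- reads[order(reads$read_id), ]
  # r1: proper-paired in human, M = (50-2)-2 = 46 vs mouse 50-10-10
  expect_equal(reads$human_matches[1], 48L)
  expect_equal(reads$human_mismatches[1], 2L)
  expect_true(reads$human_proper_pair[1])
  # r2 absent from the mouse file -> unmapped there
  expect_false(reads$mouse_mapped[2])
  # r3 unmapped in human (flag 4), mapped+proper in mouse
  expect_false(reads$human_mapped[3])
  expect_true(reads$mouse_mapped[3])
  calls <- classify_reads(reads)
  expect_equal(calls$call[order(calls$read_id)], c("human", "human", "mouse"))
})
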
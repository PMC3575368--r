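# Independent brute-force oracles and small simulation helpers shared by
# the test files. The Fisher oracles enumerate every 2x2 table compatible
# with the observed margins using log-binomial coefficients only, so they
# share no code path with the package's phyper/dhyper implementations.

# P(tumor alt >= d) by direct enumeration over all tables with the margins
# of (a, b; c, d): rows normal (a ref, b alt) / tumor (c ref, d alt).
oracle_fisher_right <- function(a, b, c, d) {
  alt_total <- b + d
  ref_total <- a + c
  n_tumor <- c + d
  n_all <- alt_total + ref_total
  ks <- max(0, n_tumor - ref_total):min(alt_total, n_tumor)
  logp <- lchoose(alt_total, ks) + lchoose(ref_total, n_tumor - ks) -
    lchoose(n_all, n_tumor)
  sum(exp(logp[ks >= d]))
}

# Two-sided conditional p: sum of probabilities of tables no more likely
# than the observed one (relative tolerance as in fisher.test).
oracle_fisher_two <- function(a, b, c, d) {
  alt_total <- b + d
  n1 <- a + b
  n_all <- a + b + c + d
  ks <- max(0, alt_total - (n_all - n1)):min(alt_total, n1)
  logp <- lchoose(alt_total, ks) + lchoose(n_all - alt_total, n1 - ks) -
    lchoose(n_all, n1)
  p <- exp(logp)
  obs <- p[ks == b]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# Minimal single-patient configuration used by several tests: no CNA
# events, purely clonal somatic sites, no artifacts.
clean_config <- function(seed, n_somatic = 500, n_germline = 200,
                         purity = 1, model_type = "neurosphere", ...) {
  cohort_config(
    n_patients = 1, model_type = model_type,
    n_somatic_sites = n_somatic, n_germline_sites = n_germline,
    primary_purity = purity, artifact_fraction = 0,
    subclone_fractions = 1, subclone_weights = 1,
    cna_events = list(data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0), cn = numeric(0))),
    seed = seed, ...
  )
}

# Null comparison records: both samples binomial draws at the same site
# frequency, depth 60x.
null_records <- function(n, depth = 60, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    f <- stats::runif(n, 0.1, 0.5)
    pa <- stats::rbinom(n, depth, f)
    ma <- stats::rbinom(n, depth, f)
    rec <- data.frame(
      primary_ref = depth - pa, primary_alt = pa,
      model_ref = depth - ma, model_alt = ma,
      primary_maf = pa / depth, model_maf = ma / depth
    )
    rec$p_two_sided <- fisher_two_sided(rec$primary_ref, rec$primary_alt,
                                        rec$model_ref, rec$model_alt)
    rec
  })
}
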
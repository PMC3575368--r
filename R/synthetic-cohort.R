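# Synthetic matched-cohort generator: germline / primary / model allele
# counts, xenograft read records and exome probe coverages with known ground
# truth, on a toy genome of 22 two-armed chromosomes.

#' Toy genome used by the cohort simulator
#'
#' 22 synthetic autosomes of equal length with a centromere at the midpoint,
#' giving every chromosome a p and a q arm.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @return A data.frame with columns `chrom`, `length`, `centromere`.
#' @export
toy_genome <- function(n_chrom = 22, chrom_length = 10e6) {
  data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    length = chrom_length,
    centromere = chrom_length / 2,
    stringsAsFactors = FALSE
  )
}

#' Cytoband table for the toy genome
#'
#' One p and one q band per chromosome in UCSC cytoBand column order
#' (chrom, start, end, band, stain), 0-based half-open coordinates.
#'
#' @param genome A genome table from [toy_genome()].
#' @return A data.frame in cytoBand format.
#' @export
toy_cytobands <- function(genome = toy_genome()) {
  rbind(
    data.frame(chrom = genome$chrom, start = 0, end = genome$centromere,
               band = "p11", stain = "gneg", stringsAsFactors = FALSE),
    data.frame(chrom = genome$chrom, start = genome$centromere,
               end = genome$length, band = "q11", stain = "gneg",
               stringsAsFactors = FALSE)
  )[order(rep(seq_len(nrow(genome)), 2)), ]
}

#' Default copy-number events for a simulated cohort
#'
#' Every patient carries a whole-chromosome gain of chr7 (3 copies) and loss
#' of chr10 (1 copy), the two hallmark glioblastoma arm events; each patient
#' additionally gets a distinct focal high-level amplification (6 copies) and
#' a distinct q-arm (or p-arm) deletion so that copy-number profiles separate
#' patients while primary/model pairs remain close.
#'
#' @param n_patients Number of patients.
#' @param genome Genome table.
#' @return A list (one element per patient) of data.frames with columns
#'   `chrom`, `start`, `end`, `cn` (0-based half-open intervals).
#' @export
default_cna_events <- function(n_patients = 4, genome = toy_genome()) {
  len <- genome$length[1]
  cen <- genome$centromere[1]
  focal_chrom <- c("chr2", "chr4", "chr5", "chr8")
  arm_del <- list(
    c("chr13", "q"), c("chr15", "q"), c("chr6", "q"), c("chr12", "p")
  )
  lapply(seq_len(n_patients), function(i) {
    j <- ((i - 1) %% 4) + 1
    del <- arm_del[[j]]
    del_start <- if (del[2] == "p") 0 else cen
    del_end <- if (del[2] == "p") cen else len
    focal_mid <- cen + len / 4
    rbind(
      data.frame(chrom = "chr7", start = 0, end = len, cn = 3),
      data.frame(chrom = "chr10", start = 0, end = len, cn = 1),
      data.frame(chrom = del[1], start = del_start, end = del_end, cn = 1),
      data.frame(chrom = focal_chrom[j], start = focal_mid - 2.5e5,
                 end = focal_mid + 2.5e5, cn = 6)
    )
  })
}

#' Configuration for a simulated matched cohort
#'
#' Defaults describe the study conditions the generator emulates: four
#' patients (one neurosphere culture, one adherent culture, two flank
#' xenografts), ~60x mean on-target coverage, primary purities between 0.59
#' and 0.91 against pure models, 40% murine read contamination in xenograft
#' tissue, a mixture of clonal and subclonal somatic mutations, GC-biased
#' negative-binomial probe coverage carrying arm-level and focal copy-number
#' events, and a low-quality artifact mode among candidate variants.
#'
#' @param n_patients Number of patients.
#' @param model_type Character vector (recycled to `n_patients`), each one of
#'   "neurosphere", "adherent", "xenograft".
#' @param n_somatic_sites True somatic sites per patient.
#' @param n_germline_sites Germline variant sites per patient.
#' @param mean_depth Mean on-target read depth.
#' @param primary_purity Tumor purity of each primary sample (recycled).
#' @param model_purity Tumor purity of each model sample (recycled).
#' @param mouse_read_fraction Fraction of reads of murine origin in xenograft
#'   samples (recycled; ignored for in-vitro models).
#' @param n_reads Number of read records emitted per xenograft patient.
#' @param subclone_fractions Cancer-cell fractions of the simulated (sub)clones.
#' @param subclone_weights Probability that a somatic site belongs to each clone.
#' @param artifact_fraction Fraction of emitted candidate sites that are
#'   sequencing artifacts.
#' @param quality_means Named or positional pair `(mu_true, mu_artifact)` of
#'   mean alternate-allele base qualities; `mu_true` must exceed `mu_artifact`.
#' @param quality_sd Base-quality standard deviation within each mode.
#' @param cna_events List (per patient) of copy-number event tables
#'   (`chrom`, `start`, `end`, `cn`); `NULL` for [default_cna_events()].
#' @param gc_bias_strength Strength of the quadratic GC-coverage bow
#'   (0 = flat coverage).
#' @param gc_bias_tumor_factor Multiplier on `gc_bias_strength` for the
#'   tumor-sample libraries; capture bias is library-specific and the
#'   model libraries show the stronger GC bow, which is what makes GC
#'   correction matter for the coverage log-ratio.
#' @param n_probes_per_chrom Exome capture probes simulated per chromosome.
#' @param probe_width Probe width in bp.
#' @param sequencing_error Per-base error rate feeding stray alternate reads.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return An object of class `tf_cohort_config`.
#' @export
cohort_config <- function(n_patients = 4,
                          model_type = c("neurosphere", "adherent",
                                         "xenograft", "xenograft"),
                          n_somatic_sites = 160,
                          n_germline_sites = 1000,
                          mean_depth = 60,
                          primary_purity = c(0.91, 0.89, 0.75, 0.59),
                          model_purity = 1.0,
                          mouse_read_fraction = 0.4,
                          n_reads = 20000,
                          subclone_fractions = c(1.0, 0.4),
                          subclone_weights = c(0.7, 0.3),
                          artifact_fraction = 0.1,
                          quality_means = c(mu_true = 30, mu_artifact = 12),
                          quality_sd = 2,
                          cna_events = NULL,
                          gc_bias_strength = 1,
                          gc_bias_tumor_factor = 1.6,
                          n_probes_per_chrom = 200,
                          probe_width = 120,
                          sequencing_error = 0.001,
                          seed = 1L) {
  genome <- toy_genome()
  if (length(n_patients) != 1 || n_patients < 1) {
    config_error("n_patients", "must be a single positive count")
  }
  n_patients <- as.integer(n_patients)
  model_type <- rep_len(model_type, n_patients)
  bad <- setdiff(model_type, c("neurosphere", "adherent", "xenograft"))
  if (length(bad)) {
    config_error("model_type", paste("unknown model type:", bad[1]))
  }
  if (mean_depth <= 0) config_error("mean_depth", "must be > 0")
  check_frac <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      config_error(nm, "must be a fraction in [0, 1]")
    }
  }
  primary_purity <- rep_len(primary_purity, n_patients)
  model_purity <- rep_len(model_purity, n_patients)
  mouse_read_fraction <- rep_len(mouse_read_fraction, n_patients)
  check_frac(primary_purity, "primary_purity")
  check_frac(model_purity, "model_purity")
  check_frac(mouse_read_fraction, "mouse_read_fraction")
  check_frac(artifact_fraction, "artifact_fraction")
  if (artifact_fraction >= 1) config_error("artifact_fraction", "must be < 1")
  if (any(subclone_fractions <= 0) || any(subclone_fractions > 1)) {
    config_error("subclone_fractions", "cancer-cell fractions must lie in (0, 1]")
  }
  if (length(subclone_weights) != length(subclone_fractions) ||
      any(subclone_weights < 0) || sum(subclone_weights) <= 0) {
    config_error("subclone_weights",
                 "must be non-negative weights matching subclone_fractions")
  }
  if (length(quality_means) != 2 || any(!is.finite(quality_means))) {
    config_error("quality_means", "must be a finite pair (mu_true, mu_artifact)")
  }
  if (quality_means[1] <= quality_means[2]) {
    config_error("quality_means", "mu_true must exceed mu_artifact")
  }
  if (quality_sd <= 0) config_error("quality_sd", "must be > 0")
  if (is.null(cna_events)) {
    cna_events <- default_cna_events(n_patients, genome)
  }
  if (length(cna_events) != n_patients) {
    config_error("cna_events", "must supply one event table per patient")
  }
  for (ev in cna_events) {
    if (nrow(ev) == 0) next
    idx <- match(ev$chrom, genome$chrom)
    if (any(is.na(idx)) || any(ev$start < 0) ||
        any(ev$end > genome$length[idx]) || any(ev$end <= ev$start)) {
      config_error("cna_events",
                   "every event interval must lie within the simulated genome")
    }
    if (any(ev$cn < 0 | ev$cn != round(ev$cn))) {
      config_error("cna_events", "copy numbers must be non-negative integers")
    }
  }
  if (gc_bias_strength < 0) config_error("gc_bias_strength", "must be >= 0")
  if (gc_bias_tumor_factor < 0) {
    config_error("gc_bias_tumor_factor", "must be >= 0")
  }
  if (length(seed) != 1 || !is.finite(seed)) {
    config_error("seed", "must be a single integer")
  }
  structure(list(
    n_patients = n_patients,
    patients = sprintf("P%02d", seq_len(n_patients)),
    model_type = model_type,
    n_somatic_sites = as.integer(n_somatic_sites),
    n_germline_sites = as.integer(n_germline_sites),
    mean_depth = mean_depth,
    primary_purity = primary_purity,
    model_purity = model_purity,
    mouse_read_fraction = mouse_read_fraction,
    n_reads = as.integer(n_reads),
    subclone_fractions = subclone_fractions,
    subclone_weights = subclone_weights / sum(subclone_weights),
    artifact_fraction = artifact_fraction,
    quality_means = unname(quality_means),
    quality_sd = quality_sd,
    cna_events = cna_events,
    gc_bias_strength = gc_bias_strength,
    gc_bias_tumor_factor = gc_bias_tumor_factor,
    n_probes_per_chrom = as.integer(n_probes_per_chrom),
    probe_width = probe_width,
    sequencing_error = sequencing_error,
    genome = genome,
    seed = as.integer(seed)
  ), class = "tf_cohort_config")
}

# GC response of capture efficiency: quadratic bow peaking at GC = 0.45.
gc_response <- function(gc, strength) {
  pmax(0.1, 1 - strength * ((gc - 0.45) / 0.35)^2)
}

# Tumor copy number at positions, given one patient's event table.
cn_at <- function(chrom, pos, events) {
  cn <- rep(2L, length(chrom))
  if (is.null(events) || nrow(events) == 0) return(cn)
  for (i in seq_len(nrow(events))) {
    hit <- chrom == events$chrom[i] & pos > events$start[i] &
      pos <= events$end[i]
    cn[hit] <- as.integer(events$cn[i])
  }
  cn
}

# Expected mutant allele fraction: m mutant copies at cancer-cell fraction
# ccf in a sample of purity p whose tumor copy number is cn.
expected_maf <- function(m, ccf, p, cn) {
  (m * ccf * p) / (cn * p + 2 * (1 - p))
}

rnbinom_depth <- function(n, mu, size = 5) {
  pmax(1L, stats::rnbinom(n, mu = mu, size = size))
}

sample_bases <- function(n, transition_prob) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  is_ts <- stats::runif(n) < transition_prob
  alt <- ifelse(is_ts, ts_map[ref], NA)
  tv <- which(!is_ts)
  for (i in tv) {
    alt[i] <- sample(setdiff(c("A", "C", "G", "T"), c(ref[i], ts_map[ref[i]])), 1)
  }
  data.frame(ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

consequence_classes <- c("missense", "nonsense", "frameshift",
                         "inframe_deletion", "splice", "synonymous",
                         "noncoding")

# Coding-class proportions follow the landscape typical of glioblastoma
# exomes (~61% missense, ~34% synonymous among coding mutations); 40% of
# somatic sites fall outside coding exons.
somatic_consequence_probs <- c(
  missense = 0.6 * 234 / 384, nonsense = 0.6 * 12 / 384,
  frameshift = 0.6 * 3 / 384, inframe_deletion = 0.6 * 1 / 384,
  splice = 0.6 * 5 / 384, synonymous = 0.6 * 129 / 384, noncoding = 0.4
)

germline_consequence_probs <- c(
  missense = 0.25, nonsense = 0.005, frameshift = 0.005,
  inframe_deletion = 0.005, splice = 0.01, synonymous = 0.225,
  noncoding = 0.5
)

cancer_genes <- c("PTEN", "TP53", "EGFR", "NRAS", "PIK3R1", "CREBBP",
                  "PIK3CA", "IDH1", "RB1", "NF1")

assign_genes <- function(chrom, pos, cancer_prob = 0.05) {
  gene <- sprintf("G%s_%03d", sub("^chr", "", chrom), pos %/% 1e5)
  hit <- stats::runif(length(gene)) < cancer_prob
  gene[hit] <- sample(cancer_genes, sum(hit), replace = TRUE)
  gene
}

#' Simulate a matched germline / primary / model cohort
#'
#' Generates, deterministically under the configuration seed, per-site allele
#' counts for the three samples of every patient, exome capture probe
#' coverages carrying the configured copy-number events under a GC-biased
#' negative-binomial depth model, dual-genome read alignment summaries for
#' xenograft patients, and a ground-truth object covering every emitted site,
#' read and probe exactly once.
#'
#' At a somatic site the expected mutant allele fraction is
#' `f = m * CCF * p / (CN_t * p + 2 * (1 - p))` (m mutant copies, CCF
#' cancer-cell fraction, p sample purity, CN_t tumor copy number); observed
#' alternate counts are Binomial(depth, f) with depth drawn from a negative
#' binomial whose mean follows a smooth quadratic function of probe GC.
#' Artifact sites draw alternate counts at a fixed 8% rate in every sample
#' and base qualities from the low-quality mode. Xenograft model samples
#' additionally contain candidate sites whose alternate support comes from
#' individually tracked mouse reads, so that read filtering genuinely
#' changes their counts.
#'
#' @param config A [cohort_config()].
#' @return An object of class `tf_cohort`: a list with data.frames `sites`,
#'   `reads`, `probes`, the `truth` ground-truth list, `cytobands`, `genome`
#'   and the `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "tf_cohort_config")) {
    config_error("config", "must be created by cohort_config()")
  }
  with_seed(config$seed, {
    genome <- config$genome
    layout <- probe_layout(config)
    sites_list <- list()
    reads_list <- list()
    probes_list <- list()
    truth_sites <- list()
    truth_reads <- list()
    truth_probes <- list()
    for (i in seq_len(config$n_patients)) {
      pat <- simulate_patient(config, i, layout)
      sites_list[[i]] <- pat$sites
      probes_list[[i]] <- pat$probes
      truth_sites[[i]] <- pat$truth_sites
      truth_probes[[i]] <- pat$truth_probes
      if (!is.null(pat$reads)) {
        reads_list[[length(reads_list) + 1]] <- pat$reads
        truth_reads[[length(truth_reads) + 1]] <- pat$truth_reads
      }
    }
    sites <- do.call(rbind, sites_list)
    rownames(sites) <- NULL
    probes <- do.call(rbind, probes_list)
    rownames(probes) <- NULL
    reads <- if (length(reads_list)) do.call(rbind, reads_list) else NULL
    if (!is.null(reads)) rownames(reads) <- NULL
    truth <- list(
      sites = do.call(rbind, truth_sites),
      reads = if (length(truth_reads)) do.call(rbind, truth_reads) else NULL,
      probes = do.call(rbind, truth_probes),
      purity = data.frame(
        patient = config$patients,
        model_type = config$model_type,
        primary_purity = config$primary_purity,
        model_purity = config$model_purity,
        mouse_read_fraction = ifelse(config$model_type == "xenograft",
                                     config$mouse_read_fraction, 0),
        stringsAsFactors = FALSE
      )
    )
    rownames(truth$sites) <- NULL
    rownames(truth$probes) <- NULL
    if (!is.null(truth$reads)) rownames(truth$reads) <- NULL
    structure(list(
      sites = sites, reads = reads, probes = probes, truth = truth,
      cytobands = toy_cytobands(genome), genome = genome, config = config
    ), class = "tf_cohort")
  })
}

# Shared probe layout: positions and GC content are properties of the capture
# design, identical for every sample.
probe_layout <- function(config) {
  genome <- config$genome
  n <- config$n_probes_per_chrom
  spacing <- floor(genome$length[1] / n)
  per_chrom <- lapply(genome$chrom, function(ch) {
    start <- spacing * (seq_len(n) - 1)
    data.frame(chrom = ch, start = start, end = start + config$probe_width,
               stringsAsFactors = FALSE)
  })
  layout <- do.call(rbind, per_chrom)
  layout$gc <- 0.15 + 0.6 * stats::rbeta(nrow(layout), 5, 5)
  layout
}

simulate_patient <- function(config, i, layout) {
  patient <- config$patients[i]
  events <- config$cna_events[[i]]
  p_prim <- config$primary_purity[i]
  p_model <- config$model_purity[i]
  is_xeno <- config$model_type[i] == "xenograft"
  mouse_frac <- if (is_xeno) config$mouse_read_fraction[i] else 0
  mu_true <- config$quality_means[1]
  mu_art <- config$quality_means[2]
  qsd <- config$quality_sd

  # ---- probes (primary and model each against the matched germline) ----
  # capture GC bias is library-specific: tumor libraries carry the
  # stronger bow, so the coverage log-ratio retains a GC trend until
  # corrected
  gcr_normal <- gc_response(layout$gc, config$gc_bias_strength)
  gcr_tumor <- gc_response(layout$gc, config$gc_bias_strength *
                             config$gc_bias_tumor_factor)
  probe_mid <- (layout$start + layout$end) / 2
  cn_true <- cn_at(layout$chrom, probe_mid, events)
  # one blood library per patient: both the primary and the model logR use
  # the same germline coverage, so normal-library noise is shared between
  # the two comparisons exactly as in a matched design
  normal_cov <- rnbinom_depth(nrow(layout), config$mean_depth * gcr_normal)
  probes <- do.call(rbind, lapply(c("primary", "model"), function(s) {
    purity <- if (s == "primary") p_prim else p_model
    cn_eff <- cn_true * purity + 2 * (1 - purity)
    data.frame(
      patient = patient, sample = s,
      chrom = layout$chrom, start = layout$start, end = layout$end,
      gc = layout$gc,
      normal_cov = normal_cov,
      tumor_cov = rnbinom_depth(nrow(layout),
                                config$mean_depth * gcr_tumor * cn_eff / 2),
      stringsAsFactors = FALSE
    )
  }))
  truth_probes <- data.frame(
    patient = patient, chrom = layout$chrom, start = layout$start,
    end = layout$end, true_cn = cn_true, stringsAsFactors = FALSE
  )

  # ---- candidate sites ----
  n_g <- config$n_germline_sites
  n_s <- config$n_somatic_sites
  n_a <- round(config$artifact_fraction * (n_g + n_s) /
                 (1 - config$artifact_fraction))
  n_m <- if (is_xeno && mouse_frac > 0) round(2.5 * mouse_frac * n_s) else 0
  n_tot <- n_g + n_s + n_a + n_m
  idx <- sample.int(nrow(layout), n_tot)
  chrom <- layout$chrom[idx]
  pos <- layout$start[idx] + sample.int(config$probe_width, n_tot, replace = TRUE)
  gc <- layout$gc[idx]
  status <- rep(c("germline", "somatic", "artifact", "mouse_artifact"),
                c(n_g, n_s, n_a, n_m))
  cn <- cn_at(chrom, pos, events)

  is_germ <- status == "germline"
  is_som <- status == "somatic"
  is_art <- status == "artifact"
  is_mouse <- status == "mouse_artifact"

  zygosity <- ifelse(is_germ & stats::runif(n_tot) < 2 / 3, "het", "hom")
  zygosity[!is_germ] <- NA

  ccf <- rep(NA_real_, n_tot)
  clone_idx <- sample.int(length(config$subclone_fractions), sum(is_som),
                          replace = TRUE, prob = config$subclone_weights)
  ccf[is_som] <- config$subclone_fractions[clone_idx]

  # transition probability 0.756 reproduces the exome-typical Ts/Tv of ~3.1
  # at genuine variants; artifacts show no transition preference
  ba <- sample_bases(n_tot, 0)   # placeholder, replaced per-class below
  ba_true <- sample_bases(n_tot, 0.756)
  ba_art <- sample_bases(n_tot, 0.5)
  ba[!is_art, ] <- ba_true[!is_art, ]
  ba[is_art, ] <- ba_art[is_art, ]

  consequence <- character(n_tot)
  consequence[is_germ] <- sample(consequence_classes, sum(is_germ), TRUE,
                                 prob = germline_consequence_probs)
  consequence[!is_germ] <- sample(consequence_classes, sum(!is_germ), TRUE,
                                  prob = somatic_consequence_probs)
  variant_type <- ifelse(consequence %in% c("frameshift", "inframe_deletion"),
                         "indel", "snv")
  ba$ref[variant_type == "indel"] <- paste0(ba$ref[variant_type == "indel"], "T")

  known <- rep(FALSE, n_tot)
  known[is_germ] <- stats::runif(sum(is_germ)) < 0.9
  known[is_art] <- stats::runif(sum(is_art)) < 0.02
  gene <- assign_genes(chrom, pos)

  quality <- stats::rnorm(n_tot, mu_true, qsd)
  quality[is_art] <- stats::rnorm(sum(is_art), mu_art, qsd)

  # per-sample expected alt fractions
  err <- config$sequencing_error
  site_mu <- config$mean_depth * gc_response(gc, config$gc_bias_strength)

  # which germline allele is affected by a tumor copy-number change
  alt_affected <- stats::runif(n_tot) < 0.5
  m_het <- function(cn) ifelse(cn >= 2, ifelse(alt_affected, cn - 1L, 1L),
                               ifelse(alt_affected, 0L, 1L))

  f_for_sample <- function(purity) {
    f <- rep(err, n_tot)
    cn_eff <- cn * purity + 2 * (1 - purity)
    het <- is_germ & zygosity == "het"
    hom <- is_germ & zygosity == "hom"
    f[het] <- ((m_het(cn) * purity + 1 * (1 - purity)) / cn_eff)[het]
    f[hom] <- 1 - err
    f[is_som] <- expected_maf(1, ccf[is_som], purity, cn[is_som])
    f[is_art] <- 0.08
    f
  }
  f_germ <- rep(err, n_tot)
  f_germ[is_germ & zygosity == "het"] <- 0.5
  f_germ[is_germ & zygosity == "hom"] <- 1 - err
  f_germ[is_art] <- 0.08
  f_prim <- f_for_sample(p_prim)
  f_model <- f_for_sample(p_model)

  depth_g <- rnbinom_depth(n_tot, site_mu)
  depth_p <- rnbinom_depth(n_tot, site_mu * (cn * p_prim + 2 * (1 - p_prim)) / 2)
  depth_m <- rnbinom_depth(n_tot, site_mu * (cn * p_model + 2 * (1 - p_model)) / 2)

  alt_g <- stats::rbinom(n_tot, depth_g, f_germ)
  alt_p <- stats::rbinom(n_tot, depth_p, f_prim)
  alt_m <- stats::rbinom(n_tot, depth_m, f_model)

  site_id <- sprintf("%s_s%05d", patient, seq_len(n_tot))

  # ---- reads (xenograft patients only) ----
  reads <- NULL
  truth_reads <- NULL
  if (is_xeno) {
    rr <- simulate_reads(config, patient, mouse_frac,
                         mouse_site_ids = site_id[is_mouse],
                         mouse_site_depth = depth_m[is_mouse])
    reads <- rr$reads
    truth_reads <- rr$truth
    # mouse-contamination sites: model alt support is exactly the set of
    # mouse reads assigned to the site (human reads contribute reference)
    support <- rr$support
    alt_m[is_mouse] <- support[site_id[is_mouse]]
    alt_g[is_mouse] <- stats::rbinom(sum(is_mouse), depth_g[is_mouse], err)
    alt_p[is_mouse] <- stats::rbinom(sum(is_mouse), depth_p[is_mouse], err)
  }

  sites <- data.frame(
    site_id = site_id, patient = patient, chrom = chrom, pos = pos,
    ref = ba$ref, alt = ba$alt, variant_type = variant_type,
    germline_ref = depth_g - pmin(alt_g, depth_g),
    germline_alt = pmin(alt_g, depth_g),
    primary_ref = depth_p - pmin(alt_p, depth_p),
    primary_alt = pmin(alt_p, depth_p),
    model_ref = depth_m,
    model_alt = alt_m,
    mean_alt_quality = quality, consequence = consequence,
    known = known, gene = gene, stringsAsFactors = FALSE
  )
  # for ordinary sites model_ref is depth minus alt; mouse sites keep their
  # human-derived reference depth with mouse alt support on top
  ordinary <- !is_mouse
  sites$model_ref[ordinary] <- depth_m[ordinary] - pmin(alt_m[ordinary],
                                                        depth_m[ordinary])
  sites$model_alt[ordinary] <- pmin(alt_m[ordinary], depth_m[ordinary])

  truth_sites <- data.frame(
    site_id = site_id, patient = patient,
    status = ifelse(is_germ, paste0("germline_", zygosity),
             ifelse(is_som, ifelse(ccf >= max(config$subclone_fractions),
                                   "somatic_clonal", "somatic_subclonal"),
                    status)),
    ccf = ifelse(is_som, ccf, NA_real_),
    tumor_cn = cn, stringsAsFactors = FALSE
  )

  list(sites = sites, probes = probes, reads = reads,
       truth_sites = truth_sites, truth_probes = truth_probes,
       truth_reads = truth_reads)
}

# Dual-genome alignment summaries for one xenograft patient's read set.
# Mouse reads align tightly to the mouse genome (Poisson(0.5) mismatches) and
# loosely to human (Poisson(4)); human reads are the mirror image. A subset
# of mouse reads is assigned to mouse-contamination candidate sites as their
# alternate-allele support.
simulate_reads <- function(config, patient, mouse_frac, mouse_site_ids,
                           mouse_site_depth) {
  n <- config$n_reads
  read_len <- 50
  is_mouse <- stats::runif(n) < mouse_frac
  n_mouse <- sum(is_mouse)

  mis_self <- stats::rpois(n, 0.5)
  mis_other <- stats::rpois(n, 4)
  human_mis <- ifelse(is_mouse, mis_other, mis_self)
  mouse_mis <- ifelse(is_mouse, mis_self, mis_other)
  human_mapped <- ifelse(is_mouse, stats::runif(n) < 0.85, TRUE)
  mouse_mapped <- ifelse(is_mouse, TRUE, stats::runif(n) < 0.2)
  human_proper <- human_mapped &
    (stats::runif(n) < ifelse(is_mouse, 0.3, 0.95))
  mouse_proper <- mouse_mapped &
    (stats::runif(n) < ifelse(is_mouse, 0.95, 0.3))

  reads <- data.frame(
    read_id = sprintf("%s_r%06d", patient, seq_len(n)),
    patient = patient,
    site_id = NA_character_,
    human_mapped = human_mapped,
    human_proper_pair = ifelse(human_mapped, human_proper, NA),
    human_matches = ifelse(human_mapped, pmax(0L, read_len - human_mis),
                           NA_integer_),
    human_mismatches = ifelse(human_mapped, human_mis, NA_integer_),
    mouse_mapped = mouse_mapped,
    mouse_proper_pair = ifelse(mouse_mapped, mouse_proper, NA),
    mouse_matches = ifelse(mouse_mapped, pmax(0L, read_len - mouse_mis),
                           NA_integer_),
    mouse_mismatches = ifelse(mouse_mapped, mouse_mis, NA_integer_),
    stringsAsFactors = FALSE
  )

  support <- stats::setNames(integer(length(mouse_site_ids)), mouse_site_ids)
  if (length(mouse_site_ids) && n_mouse > 0) {
    want <- stats::rbinom(length(mouse_site_ids), mouse_site_depth,
                          stats::runif(length(mouse_site_ids), 0.10, 0.40))
    want <- pmax(want, 2L)   # contamination sites carry detectable support
    total <- sum(want)
    pool <- which(is_mouse)
    if (total > length(pool)) {
      want <- pmin(want, pmax(2L, floor(want * length(pool) / total)))
      total <- sum(want)
    }
    assigned <- sample(pool, min(total, length(pool)))
    reads$site_id[assigned] <- rep(mouse_site_ids, want)[seq_along(assigned)]
    tab <- table(reads$site_id[assigned])
    support[names(tab)] <- as.integer(tab)
  }

  truth <- data.frame(
    read_id = reads$read_id, patient = patient,
    species = ifelse(is_mouse, "mouse", "human"),
    site_id = reads$site_id, stringsAsFactors = FALSE
  )
  list(reads = reads, truth = truth, support = support)
}

#' @export
print.tf_cohort <- function(x, ...) {
  cat("Synthetic matched tumor cohort\n")
  cat(sprintf("  patients: %d (%s)\n", x$config$n_patients,
              paste(x$config$model_type, collapse = ", ")))
  cat(sprintf("  sites: %d   probes: %d   reads: %d\n",
              nrow(x$sites), nrow(x$probes),
              if (is.null(x$reads)) 0L else nrow(x$reads)))
  invisible(x)
}
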
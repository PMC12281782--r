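# Synthetic EPIC-like cohort generator.
#
# The generator emulates the structure the analysis assumes: 16 patients
# (11 recurrence, of whom 5 metastasis), 3-5 samples per patient spread over
# cancer / normal-adjacent / normal-distant tissue, and beta values drawn as
# the logistic transform of a hierarchical normal model
#   m_js = mu_j + b_{j,patient(s)} + e_js
# with per-CpG baseline mu_j, a patient random effect (SD sigma_inter) and
# sample noise (SD sigma_intra) on the logit scale. Differentially
# methylated CpGs add their group shift at the PATIENT level, so spiked
# probes have high between-patient and low within-patient variation --
# the methylation "field effect" signature.

CHROMHMM_STATES <- c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD", "TssBiv",
                     "EnhA1", "EnhA2", "EnhG1", "EnhG2", "EnhWk", "EnhBiv",
                     "Tx", "TxWk", "ReprPC", "ReprPCWk", "Het", "Quies")

#' Simulation configuration
#'
#' Defaults encode the study conditions the cohort emulates: cohort shape
#' 16 patients (11 recurrence / 5 metastasis), ~64 samples, 10,000 probes
#' with 37 recurrence- and 20 metastasis-associated spiked CpGs, a group
#' effect of 0.2 on the beta scale, and logit-scale patient / sample SDs of
#' 0.22 / 0.18 chosen so the null CpGs show whole-array-like inter- and
#' intrapatient coefficients of variation (~0.17 / ~0.11).
#'
#' @param n_patients,n_recurrence,n_metastasis Cohort composition;
#'   metastasis patients are a subset of recurrence patients.
#' @param samples_per_patient Integer range (min, max) of samples per patient.
#' @param n_probes Number of CpG probes.
#' @param n_recurrence_dmcs,n_metastasis_dmcs Number of spiked CpGs per
#'   outcome; `dmc_overlap` is the fraction of metastasis DMCs shared with
#'   the recurrence set.
#' @param delta_beta Group effect size on the beta scale.
#' @param sigma_inter,sigma_intra Between-patient and within-patient SD on
#'   the logit scale; within must be smaller than between.
#' @param frac_fail_beads,frac_fail_detp,frac_fail_snp Fractions of probes
#'   designated to fail each QC filter (disjoint sets, never spiked probes).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Validated configuration list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 16L, n_recurrence = 11L,
                              n_metastasis = 5L,
                              samples_per_patient = c(3L, 5L),
                              n_probes = 10000L,
                              n_recurrence_dmcs = 37L,
                              n_metastasis_dmcs = 20L,
                              dmc_overlap = 0.1,
                              delta_beta = 0.2,
                              sigma_inter = 0.22, sigma_intra = 0.18,
                              frac_fail_beads = 0.01,
                              frac_fail_detp = 0.01,
                              frac_fail_snp = 0.01,
                              seed = 1L) {
  cfg <- list(n_patients = n_patients, n_recurrence = n_recurrence,
              n_metastasis = n_metastasis,
              samples_per_patient = samples_per_patient,
              n_probes = n_probes, n_recurrence_dmcs = n_recurrence_dmcs,
              n_metastasis_dmcs = n_metastasis_dmcs,
              dmc_overlap = dmc_overlap, delta_beta = delta_beta,
              sigma_inter = sigma_inter, sigma_intra = sigma_intra,
              frac_fail_beads = frac_fail_beads,
              frac_fail_detp = frac_fail_detp, frac_fail_snp = frac_fail_snp,
              seed = as.integer(seed))
  if (!(n_metastasis <= n_recurrence && n_recurrence <= n_patients)) {
    stop("need n_metastasis <= n_recurrence <= n_patients")
  }
  if (sigma_intra >= sigma_inter) {
    stop("sigma_intra must be smaller than sigma_inter")
  }
  if (delta_beta < 0 || delta_beta >= 1) stop("delta_beta must lie in [0, 1)")
  if (dmc_overlap < 0 || dmc_overlap > 1) stop("dmc_overlap must lie in [0, 1]")
  n_qc <- round((frac_fail_beads + frac_fail_detp + frac_fail_snp) * n_probes)
  if (n_recurrence_dmcs + n_metastasis_dmcs + n_qc > n_probes) {
    stop("n_probes too small for the requested spiked and QC-failing sets")
  }
  structure(cfg, class = "simulation_config")
}

# logit shift producing a beta-scale difference of delta at baseline mu,
# clamped away from the boundaries (the logistic keeps betas inside (0,1))
logit_shift <- function(mu, delta, direction) {
  target <- pmin(0.99, pmax(0.01, stats::plogis(mu) + direction * delta))
  stats::qlogis(target) - mu
}

#' Generate a synthetic methylation cohort with known ground truth
#'
#' @param config A [simulation_config()].
#' @return List with `beta` (probe x sample matrix), `samples`, `patients`,
#'   `annotation` (manifest-style data frame with QC fields), and `truth`
#'   (spiked probe ids per outcome with their logit shifts, and the
#'   designated QC-failing probes per rule).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  np <- config$n_patients
  patient_ids <- sprintf("P%02d", seq_len(np))
  recurrence <- seq_len(np) <= config$n_recurrence
  metastasis <- seq_len(np) <= config$n_metastasis

  # samples: k per patient -> (k - 2) cancer, 1 normal-adjacent, 1 distant
  k_range <- seq(config$samples_per_patient[1], config$samples_per_patient[2])
  # the sampling design aims for 2 cancer + 1 adjacent + 1 distant samples,
  # so 4 per patient is the mode
  k_prob <- ifelse(k_range == 4L, 2, 1)
  k <- sample(k_range, np, replace = TRUE, prob = k_prob)
  samples <- do.call(rbind, lapply(seq_len(np), function(i) {
    classes <- c(rep("cancer", k[i] - 2L), "normal_adjacent", "normal_distant")
    data.frame(sample_id = sprintf("%s_S%d", patient_ids[i], seq_len(k[i])),
               patient_id = patient_ids[i], tissue_class = classes,
               stringsAsFactors = FALSE)
  }))
  samples$cancer_area_pct <- ifelse(
    samples$tissue_class == "cancer",
    round(pmin(100, pmax(10, stats::rnorm(nrow(samples), 85, 15)))), 0)
  samples <- sample_table(samples)

  patients <- data.frame(
    patient_id = patient_ids, recurrence = recurrence, metastasis = metastasis,
    followup_years = round(stats::runif(np, 8, 16), 1),
    age_years = round(stats::rnorm(np, 63, 5)),
    psa_ng_ml = round(stats::rlnorm(np, log(10), 0.25), 1),
    isup_grade = sample(c(2L, 3L, 5L), np, replace = TRUE,
                        prob = c(0.5, 0.37, 0.13)),
    eau_risk = sample(c("intermediate", "high"), np, replace = TRUE,
                      prob = c(0.69, 0.31)),
    pt_stage = sample(c("T2c", "T3a", "T3b"), np, replace = TRUE,
                      prob = c(0.53, 0.2, 0.27)),
    stringsAsFactors = FALSE)
  patients$recurrence_free_interval_months <-
    ifelse(recurrence, round(stats::runif(np, 3, 48)), NA_real_)
  patients <- patient_table(patients)

  # probes on 4 synthetic chromosomes, 1-based positions, >= 500 bp apart
  nj <- config$n_probes
  probe_ids <- sprintf("cg%06d", seq_len(nj))
  chrom <- sort(rep_len(paste0("chr", 1:4), nj))
  pos <- unlist(lapply(split(seq_len(nj), chrom), function(ix) {
    cumsum(sample(500:2000, length(ix), replace = TRUE))
  }), use.names = FALSE)

  # spiked probe sets: metastasis set shares dmc_overlap of its probes with
  # the recurrence set; QC failures drawn from the remaining probes
  rec_idx <- sample(nj, config$n_recurrence_dmcs)
  n_shared <- round(config$dmc_overlap * config$n_metastasis_dmcs)
  met_idx <- c(sample(rec_idx, n_shared),
               sample(setdiff(seq_len(nj), rec_idx),
                      config$n_metastasis_dmcs - n_shared))
  spiked <- union(rec_idx, met_idx)
  pool <- setdiff(seq_len(nj), spiked)
  n_fail <- round(c(config$frac_fail_beads, config$frac_fail_detp,
                    config$frac_fail_snp) * nj)
  fail_idx <- split(sample(pool, sum(n_fail)),
                    rep(c("beads", "detp", "snp"), n_fail))

  island <- sample(c("island", "shore", "shelf", "open_sea"), nj,
                   replace = TRUE, prob = c(0.3, 0.2, 0.1, 0.4))
  island[rec_idx] <- sample(c("island", "shore", "shelf", "open_sea"),
                            length(rec_idx), replace = TRUE,
                            prob = c(0.6, 0.15, 0.05, 0.2))
  gene <- ifelse(stats::runif(nj) < 0.5,
                 sprintf("GENE%04d", sample(2000L, nj, replace = TRUE)), "")
  gene[rec_idx] <- sprintf("RGENE%02d", rep_len(1:19, length(rec_idx)))
  gene[setdiff(met_idx, rec_idx)] <-
    sprintf("MGENE%02d", rep_len(1:15, length(setdiff(met_idx, rec_idx))))

  bead_count <- sample(8:20, nj, replace = TRUE)
  bead_count[fail_idx$beads] <- sample(1:2, length(fail_idx$beads), TRUE)
  detection_p <- stats::runif(nj, 0, 0.01)
  detection_p[fail_idx$detp] <- stats::runif(length(fail_idx$detp), 0.051, 0.5)
  snp_distance_bp <- sample(10:10000, nj, replace = TRUE)
  snp_distance_bp[fail_idx$snp] <- sample(0:4, length(fail_idx$snp), TRUE)

  annotation <- data.frame(probe_id = probe_ids, chrom = chrom, pos = pos,
                           gene_symbols = gene, island_relation = island,
                           bead_count = bead_count, detection_p = detection_p,
                           snp_distance_bp = snp_distance_bp,
                           stringsAsFactors = FALSE)

  # logit-scale hierarchical model
  mu <- stats::rnorm(nj, stats::qlogis(0.35), 0.5)
  ns <- nrow(samples)
  pat_of_sample <- match(samples$patient_id, patient_ids)
  B <- matrix(stats::rnorm(nj * np, 0, config$sigma_inter), nj, np)
  # group shifts at the patient level; recurrence DMCs split gain/loss,
  # metastasis DMCs are predominantly loss of methylation
  rec_dir <- sample(c(-1, 1), length(rec_idx), replace = TRUE)
  met_dir <- sample(c(-1, 1), length(met_idx), replace = TRUE,
                    prob = c(0.9, 0.1))
  rec_shift <- logit_shift(mu[rec_idx], config$delta_beta, rec_dir)
  met_shift <- logit_shift(mu[met_idx], config$delta_beta, met_dir)
  B[rec_idx, recurrence] <- B[rec_idx, recurrence] + rec_shift
  B[met_idx, metastasis] <- B[met_idx, metastasis] + met_shift
  E <- matrix(stats::rnorm(nj * ns, 0, config$sigma_intra), nj, ns)
  m <- mu + B[, pat_of_sample, drop = FALSE] + E
  beta <- beta_matrix(stats::plogis(m), probe_ids, samples$sample_id)

  truth <- list(recurrence_dmcs = probe_ids[rec_idx],
                metastasis_dmcs = probe_ids[met_idx],
                recurrence_shift = stats::setNames(rec_shift, probe_ids[rec_idx]),
                metastasis_shift = stats::setNames(met_shift, probe_ids[met_idx]),
                qc_fail = lapply(fail_idx, function(ix) probe_ids[ix]))
  list(beta = beta, samples = samples, patients = patients,
       annotation = annotation, truth = truth, config = config)
}

#' Generate synthetic chromatin-state and TFBS tracks
#'
#' Builds, per synthetic cell line, a 17-state segmentation tiling each
#' chromosome (one segment per probe, with boundaries midway between
#' adjacent probes), and one TFBS track of point-like binding sites. The
#' chromatin state at recurrence-DMC positions is drawn with the
#' promoter-group probability inflated by `promoter_enrichment_factor`;
#' `n_planted_tfs` factors get binding sites within 150 bp of spiked DMCs so
#' downstream TFBR enrichment can recover them.
#'
#' @param annotation Manifest-style data frame from [generate_cohort()].
#' @param truth Truth labels from [generate_cohort()].
#' @param promoter_enrichment_factor Multiplier (>= 1) on the promoter-state
#'   probability at recurrence-DMC positions.
#' @param n_tfs Number of transcription factors in the TFBS track.
#' @param n_planted_tfs Number of factors planted near spiked DMCs.
#' @param bg_hit_rate Fraction of background probes near a site per TF.
#' @param seed Integer seed.
#' @return List with `chromatin` (named list of two cell-line tracks) and
#'   `tfbs` (one track, labels = TF names), plus `planted_tfs`.
#' @export
generate_tracks <- function(annotation, truth, promoter_enrichment_factor = 3,
                            n_tfs = 50L, n_planted_tfs = 5L,
                            bg_hit_rate = 0.08, seed = 1L) {
  if (promoter_enrichment_factor < 1) {
    stop("promoter_enrichment_factor must be >= 1")
  }
  set.seed(seed)
  promoter_states <- c("TssA", "TssBiv", "TssFlnk", "TssFlnkD", "TssFlnkU")
  # the EPIC array is promoter-biased by design, so the background state
  # distribution AT PROBE POSITIONS weights promoters well above their
  # genomic share
  group_p <- c(promoter = 0.2, enhancer = 0.12, transcribed = 0.22,
               PRC = 0.05, heterochromatin = 0.05, quiescent = 0.36)
  state_group <- vapply(CHROMHMM_STATES, collapse_state, character(1))
  base_p <- group_p[state_group] / table(state_group)[state_group]
  is_dmc <- annotation$probe_id %in% truth$recurrence_dmcs
  dmc_p <- base_p
  dmc_p[state_group == "promoter"] <-
    dmc_p[state_group == "promoter"] * promoter_enrichment_factor
  dmc_p <- dmc_p / sum(dmc_p)
  base_p <- base_p / sum(base_p)

  one_track <- function() {
    do.call(rbind, lapply(split(annotation, annotation$chrom), function(a) {
      a <- a[order(a$pos), ]
      p0 <- a$pos - 1L                       # 0-based probe coordinates
      cuts <- if (nrow(a) > 1) floor((p0[-1] + p0[-nrow(a)]) / 2) + 1L else integer(0)
      starts <- c(0L, cuts)
      ends <- c(cuts, p0[nrow(a)] + 500L)
      lab <- ifelse(a$probe_id %in% truth$recurrence_dmcs,
                    sample(CHROMHMM_STATES, nrow(a), TRUE, prob = dmc_p),
                    sample(CHROMHMM_STATES, nrow(a), TRUE, prob = base_p))
      data.frame(chrom = a$chrom, start = starts, end = ends, label = lab,
                 stringsAsFactors = FALSE)
    }))
  }
  chromatin <- list(PC3 = one_track(), LNCaP = one_track())
  rownames(chromatin$PC3) <- rownames(chromatin$LNCaP) <- NULL

  tf_names <- c("FOXK1", "NFIB", "STAT5A", "TCF7L1", "ESR1",
                sprintf("TF%03d", seq_len(max(0, n_tfs - 5L))))[seq_len(n_tfs)]
  planted <- tf_names[seq_len(n_planted_tfs)]
  spiked <- union(truth$recurrence_dmcs, truth$metastasis_dmcs)
  site_rows <- lapply(tf_names, function(tf) {
    anchors <- annotation[stats::runif(nrow(annotation)) < bg_hit_rate, ]
    if (tf %in% planted) {
      extra <- annotation[annotation$probe_id %in% spiked, ]
      extra <- extra[stats::runif(nrow(extra)) < 0.7, ]
      anchors <- rbind(anchors, extra)
    }
    if (nrow(anchors) == 0L) return(NULL)
    off <- sample(-100:100, nrow(anchors), replace = TRUE)
    start <- pmax(0, anchors$pos - 1L + off - 5L)
    data.frame(chrom = anchors$chrom, start = start, end = start + 10L,
               label = tf, stringsAsFactors = FALSE)
  })
  tfbs <- do.call(rbind, site_rows)
  rownames(tfbs) <- NULL
  list(chromatin = chromatin, tfbs = tfbs, planted_tfs = planted)
}

#' Generate recurrence-free survival records
#'
#' Event times are exponential with patient-specific log-hazard `risk_link`;
#' every patient also draws an administrative censoring time uniform on
#' 96-192 months (the 8-16 year follow-up window). The recorded time is the
#' smaller of the two; `event` is TRUE when the event time came first, and
#' censored records carry the follow-up time.
#'
#' @param patients Patient table (only `patient_id` is used).
#' @param risk_link Named numeric vector, log-hazard per patient (0 = the
#'   baseline hazard, median event time `base_median_months`).
#' @param base_median_months Median event time at log-hazard 0 (default 120,
#'   giving a baseline event fraction near the cohort's 11/16 recurrence
#'   over the 8-16 year window).
#' @param seed Integer seed.
#' @return A [survival_table()] with one row per patient.
#' @export
generate_survival <- function(patients, risk_link, base_median_months = 120,
                              seed = 1L) {
  set.seed(seed)
  ids <- patients$patient_id
  link <- risk_link[ids]
  if (anyNA(link)) stop("risk_link must cover every patient")
  rate <- log(2) / base_median_months * exp(link)
  t_event <- stats::rexp(length(ids), rate)
  t_cens <- stats::runif(length(ids), 96, 192)
  survival_table(ids, pmin(t_event, t_cens), t_event <= t_cens)
}

#' Generate a synthetic gene-count matrix
#'
#' Negative-binomial counts with lognormal library sizes and a patient
#' random effect, where designated genes differ between cancer and normal
#' tissue but no gene differs by outcome -- expression mirrors tissue, not
#' recurrence.
#'
#' @param samples Sample table.
#' @param genes Character vector of gene names (e.g. unique non-empty
#'   `gene_symbols` from the cohort annotation).
#' @param tissue_de_genes Genes given a cancer-vs-normal log2 fold change.
#' @param lfc Absolute log2 fold change for tissue-DE genes (default 1).
#' @param seed Integer seed.
#' @return List with `counts` (gene x sample integer matrix) and
#'   `tissue_de_genes`.
#' @export
generate_counts <- function(samples, genes, tissue_de_genes = NULL, lfc = 1,
                            seed = 1L) {
  set.seed(seed)
  genes <- unique(genes[genes != ""])
  ng <- length(genes); ns <- nrow(samples)
  base <- stats::rnorm(ng, 5, 1.5)                    # log2 baseline
  lib <- stats::rlnorm(ns, log(1), 0.15)
  pat <- factor(samples$patient_id)
  pat_eff <- matrix(stats::rnorm(ng * nlevels(pat), 0, 0.15), ng)
  de <- genes %in% tissue_de_genes
  dir <- ifelse(stats::runif(ng) < 0.5, 1, -1)
  cancer <- samples$tissue_class == "cancer"
  log2mu <- base + pat_eff[, as.integer(pat), drop = FALSE] +
    outer(de * dir * lfc, as.numeric(cancer))
  mu <- sweep(2^log2mu, 2, lib, "*")
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu, size = 10), ng, ns,
                   dimnames = list(genes, samples$sample_id))
  list(counts = counts, tissue_de_genes = genes[de])
}

#' Write a synthetic cohort to a directory in the pipeline's file dialects
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param tracks Optional output of [generate_tracks()].
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, tracks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_tsv_table(cohort$samples, file.path(dir, "samples.tsv"))
  write_tsv_table(cohort$patients, file.path(dir, "patients.tsv"))
  write_tsv_table(cohort$annotation, file.path(dir, "manifest.tsv"))
  writeLines(cohort$truth$recurrence_dmcs,
             file.path(dir, "truth_recurrence_dmcs.txt"))
  writeLines(cohort$truth$metastasis_dmcs,
             file.path(dir, "truth_metastasis_dmcs.txt"))
  if (!is.null(tracks)) {
    for (cl in names(tracks$chromatin)) {
      write_bed(tracks$chromatin[[cl]],
                file.path(dir, paste0("chromhmm_", cl, ".bed")))
    }
    write_bed(tracks$tfbs, file.path(dir, "tfbs.bed"))
  }
  invisible(dir)
}
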
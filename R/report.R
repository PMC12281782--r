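# Cohort summary (Table-1 style), heatmap-ready matrices, and the
# end-to-end pipeline runner.

#' Cohort characteristics summary
#'
#' Table-1 style summary of the patient table, split by recurrence group and
#' total: median and IQR (25th/75th percentile, linear interpolation) for
#' numeric variables; count and percentage per level for categorical ones.
#' Percentages are computed within group on non-missing denominators and
#' rounded to one decimal; missing counts are reported separately.
#'
#' @param patients Patient table.
#' @return Long-format data frame with columns `variable`, `level`
#'   (`NA` for numeric statistics), `stat` (median / q25 / q75 / count /
#'   pct / missing), `group` (non_recurrence / recurrence / total) and
#'   `value`.
#' @export
cohort_summary <- function(patients) {
  if (nrow(patients) == 0L) stop("empty patient table")
  groups <- list(non_recurrence = !patients$recurrence,
                 recurrence = patients$recurrence,
                 total = rep(TRUE, nrow(patients)))
  numeric_vars <- intersect(
    c("age_years", "psa_ng_ml", "recurrence_free_interval_months"),
    names(patients))
  cat_vars <- intersect(c("eau_risk", "isup_grade", "pt_stage", "metastasis"),
                        names(patients))
  rows <- list()
  add <- function(variable, level, stat, group, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, stat = stat, group = group,
      value = value, stringsAsFactors = FALSE)
  }
  for (v in numeric_vars) {
    for (g in names(groups)) {
      x <- patients[[v]][groups[[g]]]
      x <- x[!is.na(x)]
      if (length(x)) {
        qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        add(v, NA, "median", g, qs[2])
        add(v, NA, "q25", g, qs[1])
        add(v, NA, "q75", g, qs[3])
      }
      add(v, NA, "missing", g, sum(is.na(patients[[v]][groups[[g]]])))
    }
  }
  for (v in cat_vars) {
    col <- patients[[v]]
    if (is.logical(col)) col <- ifelse(col, "yes", "no")
    levels_v <- sort(unique(col[!is.na(col)]))
    for (g in names(groups)) {
      x <- col[groups[[g]]]
      denom <- sum(!is.na(x))
      for (lev in levels_v) {
        cnt <- sum(x == lev, na.rm = TRUE)
        add(v, as.character(lev), "count", g, cnt)
        add(v, as.character(lev), "pct", g,
            if (denom > 0) round(100 * cnt / denom, 1) else NA_real_)
      }
      add(v, NA, "missing", g, sum(is.na(x)))
    }
  }
  do.call(rbind, rows)
}

#' Query one value from a cohort summary
#'
#' @param summary Output of [cohort_summary()].
#' @param variable,stat,group Row selectors; `level` additionally for
#'   categorical variables.
#' @param level Optional level selector.
#' @return The single matching value.
#' @export
summary_value <- function(summary, variable, stat, group, level = NULL) {
  sel <- summary$variable == variable & summary$stat == stat &
    summary$group == group
  if (!is.null(level)) sel <- sel & !is.na(summary$level) & summary$level == level
  v <- summary$value[sel]
  if (length(v) != 1L) stop("selector matched ", length(v), " rows")
  v
}

#' Heatmap-ready ordered beta matrix
#'
#' Subsets the beta matrix to a CpG set and optionally orders rows and
#' columns by average-linkage hierarchical clustering of Euclidean
#' distances, with tissue-class and outcome annotations per sample.
#'
#' @param beta Beta matrix.
#' @param samples Sample table.
#' @param cpg_set Non-empty character vector of probe ids.
#' @param row_order `"cluster"` or `"given"` (also governs columns).
#' @param patients Optional patient table for outcome annotations.
#' @return List with `matrix` (ordered), `annotations` (per ordered
#'   column), and `row_hclust` / `col_hclust` (NULL when `row_order =
#'   "given"`).
#' @export
heatmap_matrix <- function(beta, samples, cpg_set,
                           row_order = c("cluster", "given"),
                           patients = NULL) {
  row_order <- match.arg(row_order)
  if (length(cpg_set) == 0L) stop("cpg_set must be non-empty")
  M <- beta[cpg_set, samples$sample_id, drop = FALSE]
  rh <- ch <- NULL
  if (row_order == "cluster") {
    rh <- stats::hclust(stats::dist(M), method = "average")
    ch <- stats::hclust(stats::dist(t(M)), method = "average")
    M <- M[rh$order, ch$order, drop = FALSE]
  }
  ann <- data.frame(sample_id = colnames(M),
                    tissue_class = samples$tissue_class[
                      match(colnames(M), samples$sample_id)],
                    stringsAsFactors = FALSE)
  if (!is.null(patients)) {
    pid <- samples$patient_id[match(ann$sample_id, samples$sample_id)]
    ix <- match(pid, patients$patient_id)
    ann$recurrence <- patients$recurrence[ix]
    ann$metastasis <- patients$metastasis[ix]
  }
  list(matrix = M, annotations = ann, row_hclust = rh, col_hclust = ch)
}

# short deterministic content hash (polynomial, mod 2^31-1) used to stamp
# run outputs
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

default_pipeline_config <- function() {
  list(seed = 1L,
       simulate = list(),
       dmc_q_threshold = 0.05,
       heterogeneity = list(n_iter = 10L),
       enrichment = list(promoter_enrichment_factor = 3, n_tfs = 50L),
       risk = list(l1_ratio = 0.1, inner_cv_folds = 5L))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> probe filtering -> differential
#' methylation (recurrence and metastasis) -> heterogeneity -> chromatin /
#' TFBR enrichment -> risk model -> cohort report, writing every artifact
#' into `out_dir`, stamped with a config hash and the seed. A log records
#' each stage's input/output row counts. All randomness derives from
#' `config$seed`, so a rerun with the same config is reproducible.
#'
#' @param config Configuration list or path to a YAML file. Must contain
#'   either a `simulate` block (passed to [simulation_config()]) or a
#'   `paths` block naming `beta`, `samples`, `patients`, `manifest` TSVs
#'   (and optionally `chromatin` BED paths and `tfbs`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
    invisible(NULL)
  }
  cat(sprintf("run config_hash=%s seed=%d\n", config_hash(cfg),
              as.integer(cfg$seed)), file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- input -----------------------------------------------------------
  if (!is.null(cfg$paths)) {
    req <- c("beta", "samples", "patients", "manifest")
    miss <- setdiff(req, names(cfg$paths))
    if (length(miss)) stop("config paths block missing field(s): ",
                           paste(miss, collapse = ", "))
    ds <- stage("read", read_dataset(cfg$paths$beta, cfg$paths$samples,
                                     cfg$paths$patients))
    annotation <- stage("read", read_manifest(cfg$paths$manifest))
    tracks <- NULL
    if (!is.null(cfg$paths$chromatin)) {
      tracks <- list(chromatin = lapply(cfg$paths$chromatin, read_bed),
                     tfbs = if (!is.null(cfg$paths$tfbs))
                       read_bed(cfg$paths$tfbs))
    }
    cohort <- list(beta = ds$beta, samples = ds$samples,
                   patients = ds$patients, annotation = annotation,
                   truth = NULL)
  } else {
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(cfg$simulate,
                                         list(seed = as.integer(cfg$seed))))
    cohort <- stage("simulate", generate_cohort(sim_cfg))
    tracks <- stage("simulate", generate_tracks(
      cohort$annotation, cohort$truth,
      promoter_enrichment_factor = cfg$enrichment$promoter_enrichment_factor,
      n_tfs = cfg$enrichment$n_tfs, seed = cfg$seed + 1L))
    write_cohort(cohort, file.path(out_dir, "simulated"), tracks)
  }
  logf("input: %d probes, %d samples, %d patients", nrow(cohort$beta),
       ncol(cohort$beta), nrow(cohort$patients))

  # --- filter ----------------------------------------------------------
  filt <- stage("filter", filter_probes(cohort$beta, cohort$annotation))
  write_tsv_table(filt$report, file.path(out_dir, "filter_report.tsv"))
  logf("filter: %d in, %d removed, %d out", nrow(cohort$beta),
       length(unique(filt$report$probe_id)), nrow(filt$beta))
  beta <- filt$beta
  ann <- cohort$annotation[match(rownames(beta), cohort$annotation$probe_id), ]

  # --- differential methylation ---------------------------------------
  dmc <- list()
  for (outc in c("recurrence", "metastasis")) {
    res <- stage("dmc", mixed_group_test(beta, cohort$samples,
                                         cohort$patients, outcome = outc))
    write_tsv_table(res, file.path(out_dir, paste0("dmc_", outc, ".tsv")))
    dmc[[outc]] <- res
    logf("dmc %s: %d tested, %d at q<%g (consensus rho %.3f)", outc,
         sum(!is.na(res$p)), sum(res$q < cfg$dmc_q_threshold, na.rm = TRUE),
         cfg$dmc_q_threshold, attr(res, "consensus_rho"))
  }
  ov <- rank_overlap(dmc$recurrence, dmc$metastasis, 0.1)
  logf("rank overlap top 10%%: %d (%.3f)", ov$count, ov$fraction)

  dmc_sets <- lapply(dmc, function(res) {
    hits <- res$feature_id[!is.na(res$q) & res$q < cfg$dmc_q_threshold]
    if (length(hits) >= 3L) hits else
      res$feature_id[order(res$rank)][seq_len(min(37L, nrow(res)))]
  })

  # --- heterogeneity ---------------------------------------------------
  het <- list()
  for (outc in names(dmc_sets)) {
    rep_cv <- stage("heterogeneity", cv_report(
      beta, cohort$samples, dmc_sets[[outc]],
      n_iter = cfg$heterogeneity$n_iter, seed = cfg$seed + 10L))
    het[[outc]] <- rep_cv
    write_tsv_table(
      data.frame(statistic = names(rep_cv$medians), value = rep_cv$medians),
      file.path(out_dir, paste0("heterogeneity_medians_", outc, ".tsv")))
    logf("heterogeneity %s: medians inter %.3f intra %.3f (null %.3f/%.3f)",
         outc, rep_cv$medians["dmc_inter"], rep_cv$medians["dmc_intra"],
         rep_cv$medians["null_inter"], rep_cv$medians["null_intra"])
  }
  corr <- stage("heterogeneity", intrapatient_correlation(
    beta, cohort$samples, dmc_sets$recurrence, seed = cfg$seed + 11L))
  write_tsv_table(corr, file.path(out_dir, "intrapatient_correlation.tsv"))

  # --- enrichment ------------------------------------------------------
  enr <- NULL
  if (!is.null(tracks)) {
    query <- ann[ann$probe_id %in% dmc_sets$recurrence, ]
    enr <- list()
    for (cl in names(tracks$chromatin)) {
      e <- stage("enrich", state_enrichment(query, ann, tracks$chromatin[[cl]]))
      enr[[cl]] <- e
      write_tsv_table(e, file.path(out_dir, paste0("state_enrichment_",
                                                   cl, ".tsv")))
    }
    if (!is.null(tracks$tfbs)) {
      tfbr <- stage("enrich", build_tfbr(tracks$tfbs))
      tfe <- stage("enrich", tf_enrichment(query, ann, tfbr))
      enr$tf <- tfe
      write_tsv_table(tfe, file.path(out_dir, "tf_enrichment.tsv"))
      logf("enrich: %d TFs tested, %d at q<0.05", nrow(tfe),
           sum(tfe$q < 0.05))
    }
  }

  # --- risk model ------------------------------------------------------
  risk <- NULL
  surv_p <- with(cohort$patients, survival_table(
    patient_id,
    ifelse(recurrence, recurrence_free_interval_months, followup_years * 12),
    recurrence))
  ix <- match(cohort$samples$patient_id, surv_p$unit_id)
  surv_s <- survival_table(cohort$samples$sample_id,
                           surv_p$time_months[ix], surv_p$event[ix])
  Xr <- t(beta[dmc_sets$recurrence, cohort$samples$sample_id, drop = FALSE])
  risk <- stage("riskmodel", {
    sel <- loocv_selection(Xr, surv_s, l1_ratio = cfg$risk$l1_ratio,
                           inner_cv_folds = cfg$risk$inner_cv_folds,
                           seed = cfg$seed + 20L)
    model <- build_final_model(sel$coefficients, Xr, surv_s)
    strat <- stratify_and_test(model, Xr, surv_s)
    list(selection = sel, model = model, stratification = strat)
  })
  jsonlite::write_json(
    list(probes = risk$model$probes,
         coefficients = as.list(risk$model$coefficients),
         cutoff = risk$model$cutoff,
         selection_frequency = as.list(risk$model$selection_frequency),
         logrank_p = risk$stratification$p),
    file.path(out_dir, "risk_model.json"), auto_unbox = TRUE, digits = NA)
  write_tsv_table(risk$stratification$groups,
                  file.path(out_dir, "risk_groups.tsv"))
  logf("riskmodel: %d probes selected, logrank p %.4g",
       length(risk$model$probes), risk$stratification$p)

  # --- report ----------------------------------------------------------
  summ <- stage("report", cohort_summary(cohort$patients))
  write_tsv_table(summ, file.path(out_dir, "cohort_summary.tsv"))
  hm <- stage("report", heatmap_matrix(beta, cohort$samples,
                                       dmc_sets$recurrence,
                                       patients = cohort$patients))
  write_tsv_table(
    data.frame(probe_id = rownames(hm$matrix), hm$matrix,
               check.names = FALSE),
    file.path(out_dir, "heatmap_recurrence.tsv"))
  grDevices::png(file.path(out_dir, "heatmap_recurrence.png"),
                 width = 900, height = 700)
  pheatmap::pheatmap(hm$matrix, cluster_rows = FALSE, cluster_cols = FALSE,
                     show_colnames = FALSE,
                     annotation_col = data.frame(
                       tissue = hm$annotations$tissue_class,
                       recurrence = as.character(hm$annotations$recurrence),
                       row.names = hm$annotations$sample_id))
  grDevices::dev.off()
  logf("done")
  invisible(list(cohort = cohort, filtered = filt, dmc = dmc,
                 heterogeneity = het, correlation = corr, enrichment = enr,
                 risk = risk, summary = summ, overlap = ov))
}
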
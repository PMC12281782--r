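# Core containers and TSV/BED readers-writers.
#
# Conventions used throughout the package:
#  * beta matrix: numeric matrix, probes in rows, samples in columns,
#    values in [0,1] with NAs allowed (masked probes).
#  * manifest / CpG positions are 1-based (Illumina convention); BED
#    segments are 0-based half-open. The only place the two conventions
#    meet is assign_cpgs_to_segments().
#  * strand is ignored: CpG positions are point queries.

TISSUE_CLASSES <- c("cancer", "normal_adjacent", "normal_distant")
ISLAND_LEVELS <- c("island", "shore", "shelf", "open_sea")

#' Construct and validate a beta-value matrix
#'
#' @param values Numeric matrix of methylation beta values in `[0, 1]`
#'   (NA allowed), probes in rows, samples in columns.
#' @param probe_ids,sample_ids Optional dimnames; taken from `values` when
#'   absent.
#' @return The validated matrix with dimnames set.
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("probe and sample identifiers are required")
  }
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("dimnames lengths must match the matrix dimensions")
  }
  if (anyDuplicated(probe_ids)) stop("duplicate probe_ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  rng <- range(values, na.rm = TRUE)
  if (nrow(values) > 0 && (rng[1] < 0 || rng[2] > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  values
}

#' Construct and validate a sample table
#'
#' @param df Data frame with columns `sample_id`, `patient_id`,
#'   `tissue_class` (one of cancer / normal_adjacent / normal_distant) and
#'   optionally `cancer_area_pct`.
#' @return Validated data frame.
#' @export
sample_table <- function(df) {
  req <- c("sample_id", "patient_id", "tissue_class")
  if (!all(req %in% names(df))) {
    stop("sample table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_ids in sample table")
  bad <- setdiff(unique(df$tissue_class), TISSUE_CLASSES)
  if (length(bad)) {
    stop("unknown tissue_class ", paste(sQuote(bad), collapse = ", "),
         "; allowed classes: ", paste(TISSUE_CLASSES, collapse = ", "))
  }
  if (is.null(df$cancer_area_pct)) df$cancer_area_pct <- 0
  if (any(df$cancer_area_pct < 0 | df$cancer_area_pct > 100, na.rm = TRUE)) {
    stop("cancer_area_pct must lie in [0, 100]")
  }
  if (any(df$tissue_class != "cancer" & df$cancer_area_pct > 0, na.rm = TRUE)) {
    stop("normal tissue classes must have cancer_area_pct 0")
  }
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Construct and validate a patient table
#'
#' @param df Data frame with at least `patient_id`, `recurrence`,
#'   `metastasis`; clinical covariates (age_years, psa_ng_ml, isup_grade,
#'   eau_risk, pt_stage, followup_years, recurrence_free_interval_months)
#'   are optional but validated when present.
#' @return Validated data frame.
#' @export
patient_table <- function(df) {
  req <- c("patient_id", "recurrence", "metastasis")
  if (!all(req %in% names(df))) {
    stop("patient table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_ids")
  df$recurrence <- as.logical(df$recurrence)
  df$metastasis <- as.logical(df$metastasis)
  if (any(df$metastasis & !df$recurrence)) {
    stop("metastasis implies recurrence in this cohort")
  }
  if (!is.null(df$recurrence_free_interval_months)) {
    mism <- xor(df$recurrence, !is.na(df$recurrence_free_interval_months))
    if (any(mism)) {
      stop("recurrence_free_interval_months must be present iff recurrence")
    }
  }
  if (!is.null(df$eau_risk)) {
    bad <- setdiff(stats::na.omit(unique(df$eau_risk)),
                   c("intermediate", "high"))
    if (length(bad)) stop("unknown eau_risk level: ", paste(bad, collapse = ", "))
  }
  as.data.frame(df, stringsAsFactors = FALSE)
}

normalize_island_relation <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  map <- c(island = "island",
           nshore = "shore", sshore = "shore", shore = "shore",
           nshelf = "shelf", sshelf = "shelf", shelf = "shelf",
           opensea = "open_sea", sea = "open_sea")
  out <- unname(map[key])
  if (anyNA(out)) {
    stop("unknown island relation: ",
         paste(sQuote(unique(x[is.na(out)])), collapse = ", "))
  }
  out
}

#' Read the per-probe manifest
#'
#' TSV with header; requires columns `probe_id`, `chrom`, `pos` (1-based),
#' `island_relation`, `bead_count`, `detection_p`, `snp_distance_bp`;
#' `gene_symbols` (comma-separated, possibly empty) is optional. Island
#' relations are normalized to island / shore / shelf / open_sea.
#'
#' @param path Path to the manifest TSV.
#' @return Data frame of CpG records in file order.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  req <- c("probe_id", "chrom", "pos", "island_relation", "bead_count",
           "detection_p", "snp_distance_bp")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(df$pos)) stop("non-numeric probe position")
  if (any(df$pos < 1)) stop("probe positions are 1-based; found pos < 1")
  if (any(df$detection_p < 0 | df$detection_p > 1, na.rm = TRUE)) {
    stop("detection_p must lie in [0, 1]")
  }
  df$island_relation <- normalize_island_relation(df$island_relation)
  if (is.null(df$gene_symbols)) df$gene_symbols <- ""
  df$gene_symbols[is.na(df$gene_symbols)] <- ""
  df
}

#' Read a BED3+ interval track
#'
#' Coordinates are 0-based half-open and are parsed verbatim, never shifted.
#'
#' @param path Path to a headerless BED file.
#' @param label_column 1-based column index carrying the segment label
#'   (chromatin state or TF name); default 4.
#' @return Data frame with columns chrom, start, end, label.
#' @export
read_bed <- function(path, label_column = 4L) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < label_column) stop("BED file has no column ", label_column)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]),
                    label = as.character(df[[label_column]]),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0)) stop("negative segment start")
  if (any(out$start >= out$end)) stop("empty segment (start >= end)")
  out
}

#' Read the cohort dataset
#'
#' @param beta_path TSV of the beta matrix: first column `probe_id`, one
#'   column per sample.
#' @param sample_sheet_path TSV sample sheet (sample_id, patient_id,
#'   tissue_class, cancer_area_pct).
#' @param patient_table_path TSV patient table.
#' @return List with elements `beta`, `samples`, `patients`,
#'   cross-referenced: sheet samples all present in the matrix (the matrix
#'   is subset to the sheet, in sheet order) and every sample maps to
#'   exactly one known patient.
#' @export
read_dataset <- function(beta_path, sample_sheet_path, patient_table_path) {
  bm <- utils::read.delim(beta_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(bm) == 0L) stop("no probes in beta matrix file")
  beta <- beta_matrix(as.matrix(bm[, -1, drop = FALSE]),
                      probe_ids = as.character(bm[[1]]),
                      sample_ids = colnames(bm)[-1])
  samples <- sample_table(utils::read.delim(sample_sheet_path,
                                            stringsAsFactors = FALSE))
  patients <- patient_table(utils::read.delim(patient_table_path,
                                              stringsAsFactors = FALSE))
  missing_s <- setdiff(samples$sample_id, colnames(beta))
  if (length(missing_s)) {
    stop("samples in sheet absent from beta matrix: ",
         paste(missing_s, collapse = ", "))
  }
  missing_p <- setdiff(samples$patient_id, patients$patient_id)
  if (length(missing_p)) {
    stop("patients in sample sheet absent from patient table: ",
         paste(missing_p, collapse = ", "))
  }
  list(beta = beta[, samples$sample_id, drop = FALSE],
       samples = samples, patients = patients)
}

#' Write tabular pipeline objects as TSV
#'
#' `write_beta_matrix()` writes probes as the first column; the writers and
#' readers round-trip values at full `write.table` precision (15 significant
#' digits).
#'
#' @param beta,df Object to write.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a BED3+ track
#'
#' @param track Data frame with chrom, start, end, label.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Construct a survival table
#'
#' @param unit_id Sample or patient identifiers.
#' @param time_months Positive follow-up/event times in months.
#' @param event Logical; TRUE when recurrence was observed. Censored units
#'   carry their follow-up time.
#' @return Data frame with columns unit_id, time_months, event.
#' @export
survival_table <- function(unit_id, time_months, event) {
  if (any(time_months <= 0)) stop("time_months must be positive")
  data.frame(unit_id = as.character(unit_id),
             time_months = as.numeric(time_months),
             event = as.logical(event), stringsAsFactors = FALSE)
}
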
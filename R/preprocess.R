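#' Probe-level quality and SNP filtering
#'
#' Removes probes with fewer than 3 beads, detection p-value above 0.05, or
#' a SNP closer than 5 bp to the interrogated CpG. All three boundaries are
#' strict: bead_count 3, detection_p 0.05 and snp_distance_bp 5 are
#' retained. QC fields are per-probe scalars here (the worst case across
#' samples: minimum bead count, maximum detection p); inputs are assumed
#' already normalized.
#'
#' @param beta Beta matrix (probes x samples).
#' @param annotation Manifest data frame covering every probe in `beta`.
#' @return List with `beta` (survivors, input order preserved) and `report`,
#'   a data frame (probe_id, rule, value) with one row per removed probe and
#'   triggering rule (a probe failing several rules appears once per rule).
#' @export
filter_probes <- function(beta, annotation) {
  ix <- match(rownames(beta), annotation$probe_id)
  if (anyNA(ix)) {
    stop("probes missing from annotation: ",
         paste(utils::head(rownames(beta)[is.na(ix)], 5), collapse = ", "))
  }
  ann <- annotation[ix, ]
  fail <- list(
    beads = ann$bead_count < 3,
    detection_p = ann$detection_p > 0.05,
    snp = ann$snp_distance_bp < 5
  )
  report <- do.call(rbind, lapply(names(fail), function(rule) {
    hit <- which(fail[[rule]])
    if (!length(hit)) return(NULL)
    value <- switch(rule, beads = ann$bead_count[hit],
                    detection_p = ann$detection_p[hit],
                    snp = ann$snp_distance_bp[hit])
    data.frame(probe_id = ann$probe_id[hit], rule = rule, value = value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(report)) {
    report <- data.frame(probe_id = character(0), rule = character(0),
                         value = numeric(0), stringsAsFactors = FALSE)
  }
  keep <- !Reduce(`|`, fail)
  list(beta = beta[keep, , drop = FALSE],
       report = report[order(match(report$probe_id, ann$probe_id)), ])
}
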
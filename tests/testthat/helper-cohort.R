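# shared fixtures, all generated in code

small_cohort <- function(seed = 1L, n_probes = 400L, ...) {
  args <- list(n_probes = n_probes, seed = seed, ...)
  if (n_probes < 300L) {
    if (is.null(args$n_recurrence_dmcs)) {
      args$n_recurrence_dmcs <- max(3L, n_probes %/% 10L)
    }
    if (is.null(args$n_metastasis_dmcs)) {
      args$n_metastasis_dmcs <- max(2L, n_probes %/% 15L)
    }
  }
  generate_cohort(do.call(simulation_config, args))
}

# a patient table with the printed group counts of the study cohort:
# 5 non-recurrence / 11 recurrence, 5 metastasis (all recurrence),
# ISUP 2/3/5 = 4,1,0 vs 4,5,2; EAU high 2 vs 3; pT T2c 4 vs 4, T3a 0 vs 3,
# T3b 0 vs 4 with one recurrence patient missing pT
table1_patients <- function() {
  patient_table(data.frame(
    patient_id = sprintf("P%02d", 1:16),
    recurrence = c(rep(FALSE, 5), rep(TRUE, 11)),
    metastasis = c(rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 6)),
    recurrence_free_interval_months = c(rep(NA, 5), rep(37, 11)),
    followup_years = 10,
    age_years = c(rep(59, 5), rep(63, 11)),
    psa_ng_ml = 10,
    isup_grade = c(2, 2, 2, 2, 3,
                   2, 2, 2, 2, 3, 3, 3, 3, 3, 5, 5),
    eau_risk = c("high", "high", "intermediate", "intermediate", "intermediate",
                 "high", "high", "high", rep("intermediate", 8)),
    pt_stage = c(rep("T2c", 4), NA,
                 "T2c", "T2c", "T2c", "T2c",
                 "T3a", "T3a", "T3a", "T3b", "T3b", "T3b", "T3b"),
    stringsAsFactors = FALSE))
}
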
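# End-to-end convenience: cohort -> feature tables -> fitted indices ->
# evaluation. The thin layer the command-line wrapper and the acceptance
# workflow drive.

#' Build the three GMHI feature tables from a cohort
#'
#' @param cohort A `snv_cohort` (simulated or read from disk).
#' @param prevalence_min Feature prevalence threshold (default 0.10).
#' @return Named list of `feature_table`s: `abundance`, `snv_rate`,
#'   `scfa_snv_freq`.
#' @export
cohort_feature_tables <- function(cohort, prevalence_min = 0.10) {
  profiles <- genome_snv_profiles(cohort)
  samples <- cohort$metadata$sample_id
  list(
    abundance = build_feature_table(profiles, "abundance",
                                    prevalence_min = prevalence_min,
                                    samples = samples),
    snv_rate = build_feature_table(profiles, "snv_rate",
                                   prevalence_min = prevalence_min,
                                   samples = samples),
    scfa_snv_freq = scfa_snv_feature_table(cohort$snv, cohort$genes,
                                           cohort$genome_info,
                                           prevalence_min = prevalence_min))
}

#' Fit and evaluate the three health indices on a cohort
#'
#' Runs the full discovery workflow: feature tables, marker selection,
#' index construction and ROC evaluation for the abundance, SNV-rate and
#' SCFA-SNV indices.
#'
#' @param cohort A `snv_cohort`.
#' @param alpha Marker FDR threshold.
#' @param prevalence_min Feature prevalence threshold.
#' @return Named list (one entry per index kind) of lists with `model`
#'   (`gmhi_model`) and `evaluation` (from [evaluate_index()]).
#' @export
run_gmhi_pipeline <- function(cohort, alpha = 0.05, prevalence_min = 0.10) {
  tables <- cohort_feature_tables(cohort, prevalence_min = prevalence_min)
  md <- cohort$metadata
  lapply(tables, function(tab) {
    labels <- md$health_status[match(rownames(tab$values), md$sample_id)]
    cohorts <- md$cohort[match(rownames(tab$values), md$sample_id)]
    model <- gmhi_fit(tab, labels)
    ev <- evaluate_index(model$scores$gmhi, labels, cohorts)
    list(model = model, evaluation = ev)
  })
}
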
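#' Simulation configuration for synthetic cohorts
#'
#' Builds the configuration object consumed by [simulate_genomes()] and
#' [simulate_cohort()]. The defaults define a two-group (healthy vs
#' nonhealthy) cohort whose statistical structure mirrors the patterns the
#' downstream analysis is designed to detect: healthy hosts carry more
#' mutated genomes per unit sequencing depth and slightly more SNVs per
#' callable base; a subset of "marker" genomes has a group-shifted SNV rate
#' and sequence abundance; base-change classes follow group-specific
#' collapsed variant-type profiles; and SNVs landing in annotated SCFA genes
#' are planted as stop-gain/start-loss changes more often in the nonhealthy
#' group.
#'
#' @param n_healthy,n_nonhealthy Samples per host group.
#' @param n_genomes Number of reference genomes in the simulated database.
#' @param genome_len Genome length in bases (one scaffold per genome).
#' @param n_scfa_genes_per_genome SCFA-family CDS planted per genome.
#' @param gene_len SCFA gene length in bases; must be divisible by 3.
#' @param depth_meanlog,depth_sdlog Log-normal parameters for per-sample
#'   sequencing depth in gigabases. Defaults give a ~1.6-11 Gb spread,
#'   matching typical published stool metagenome depths.
#' @param lambda_genomes_healthy,lambda_genomes_nonhealthy Expected mutated
#'   genomes per gigabase of depth, per group. Healthy > nonhealthy encodes
#'   the higher strain-level diversity of healthy gut microbiomes.
#' @param snv_rate_healthy,snv_rate_nonhealthy Baseline expected SNVs per
#'   SNV-callable base, per group.
#' @param marker_fraction Fraction of genomes given a group-shifted SNV rate
#'   (half enriched in each group).
#' @param snv_rate_effect Multiplicative SNV-rate shift applied to a marker
#'   genome in its enriched group. The default is calibrated once so the
#'   SNV-rate health index separates groups with AUROC near 0.75 at
#'   n = 100 + 100.
#' @param abundance_effect Additive log-abundance shift for marker genomes in
#'   their enriched group.
#' @param marker_weight Sampling weight favouring marker genomes when drawing
#'   which genomes are mutated in a sample (marker strains emulate the
#'   prevalent, well-covered strains real marker sets come from).
#' @param marker_presence_effect Additional presence weight a marker genome
#'   receives in samples of its enriched group, so marker prevalence -- not
#'   only marker value -- differs between host groups.
#' @param variant_type_bias_healthy,variant_type_bias_nonhealthy Probability
#'   vectors over the six collapsed variant classes (named as in
#'   `variant_class()` output). Each must sum to 1 and, because simulated
#'   genomes have uniform base composition, the A/T-reference triplet and the
#'   C/G-reference triplet must each sum to 0.5 for the empirical profile to
#'   converge to the configured one.
#' @param stopgain_prob_healthy,stopgain_prob_nonhealthy Probability that an
#'   SNV falling in an SCFA gene is placed to create a stop-gain or
#'   start-loss change. Nonhealthy >= healthy encodes the disease-associated
#'   codon variant bias.
#' @param breadth_shape1,breadth_shape2 Beta prior for breadth_minCov, the
#'   fraction of a genome covered at >= `min_cov`. Default Beta(8, 4),
#'   mean ~0.67.
#' @param min_cov Minimum site coverage for an emitted SNV.
#' @param epsilon Pseudo-value used downstream in the health-index log ratio.
#' @param seed Integer seed; one integer reproduces a full cohort.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_healthy = 100,
                       n_nonhealthy = 100,
                       n_genomes = 60,
                       genome_len = 20000L,
                       n_scfa_genes_per_genome = 3L,
                       gene_len = 450L,
                       depth_meanlog = log(5),
                       depth_sdlog = 0.4,
                       lambda_genomes_healthy = 3.6,
                       lambda_genomes_nonhealthy = 3.2,
                       snv_rate_healthy = 2.1e-3,
                       snv_rate_nonhealthy = 1.95e-3,
                       marker_fraction = 0.2,
                       snv_rate_effect = 1.7,
                       abundance_effect = 1.0,
                       marker_weight = 2,
                       marker_presence_effect = 1.6,
                       variant_type_bias_healthy = c(
                         "A>C|T>G" = 0.06, "A>G|T>C" = 0.30, "A>T|T>A" = 0.14,
                         "C>A|G>T" = 0.15, "C>G|G>C" = 0.10, "C>T|G>A" = 0.25),
                       variant_type_bias_nonhealthy = c(
                         "A>C|T>G" = 0.14, "A>G|T>C" = 0.24, "A>T|T>A" = 0.12,
                         "C>A|G>T" = 0.13, "C>G|G>C" = 0.18, "C>T|G>A" = 0.19),
                       stopgain_prob_healthy = 0.04,
                       stopgain_prob_nonhealthy = 0.12,
                       breadth_shape1 = 8,
                       breadth_shape2 = 4,
                       min_cov = 5L,
                       epsilon = 1e-5,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_healthy >= 1, cfg$n_nonhealthy >= 1,
            cfg$n_genomes >= 1, cfg$genome_len >= 3 * cfg$gene_len,
            cfg$gene_len %% 3 == 0, cfg$gene_len >= 9,
            cfg$min_cov >= 1)
  for (nm in c("lambda_genomes_healthy", "lambda_genomes_nonhealthy",
               "snv_rate_healthy", "snv_rate_nonhealthy")) {
    if (cfg[[nm]] <= 0) stop("sim_config: ", nm, " must be > 0")
  }
  if (cfg$stopgain_prob_nonhealthy < cfg$stopgain_prob_healthy)
    warning("stopgain_prob_nonhealthy < stopgain_prob_healthy: ",
            "direction opposite to the emulated disease effect")
  for (nm in c("variant_type_bias_healthy", "variant_type_bias_nonhealthy")) {
    v <- cfg[[nm]]
    if (length(v) != 6 || !setequal(names(v), VARIANT_CLASSES))
      stop("sim_config: ", nm, " must be named by the six variant classes")
    if (any(v < 0) || abs(sum(v) - 1) > 1e-8)
      stop("sim_config: ", nm, " must be a probability vector summing to 1")
    at <- sum(v[VARIANT_CLASSES[1:3]])
    if (abs(at - 0.5) > 1e-8)
      warning("sim_config: ", nm, " A/T- and C/G-reference halves do not ",
              "each sum to 0.5; empirical class frequencies will not ",
              "converge to the configured vector on uniform-composition genomes")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  samples: %d healthy + %d nonhealthy\n",
              x$n_healthy, x$n_nonhealthy))
  cat(sprintf("  genomes: %d x %d bp, %d SCFA genes each\n",
              x$n_genomes, x$genome_len, x$n_scfa_genes_per_genome))
  cat(sprintf("  marker genomes: %d (rate effect %.2fx)\n",
              round(x$marker_fraction * x$n_genomes), x$snv_rate_effect))
  cat(sprintf("  stop-gain/start-loss plant prob: %.3f (H) vs %.3f (N)\n",
              x$stopgain_prob_healthy, x$stopgain_prob_nonhealthy))
  invisible(x)
}
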
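# Per-(sample, genome) SNV metrics: SNV rate, depth normalization,
# nucleotide diversity, sequence abundance, prevalence, variant-type
# profiles, coding fraction, and feature-table assembly.

#' SNV rate of a mutated genome
#'
#' SNVs per SNV-callable base:
#' `snv_number / (g_len * breadth_minCov)`, where `breadth_minCov` is the
#' fraction of the genome covered at the SNV-calling depth floor, so the
#' denominator is the number of bases at which an SNV could have been
#' called.
#'
#' @param snv_number SNV count(s) for the genome in a sample.
#' @param g_len Genome length(s) in bases.
#' @param breadth_minCov Fraction(s) in (0, 1] of bases at >= min_cov
#'   coverage.
#' @return SNV rate per callable base (vectorized).
#' @examples
#' snv_rate(100, 1e6, 0.5)  # 2e-4
#' @export
snv_rate <- function(snv_number, g_len, breadth_minCov) {
  if (any(g_len <= 0)) stop("g_len must be > 0")
  if (any(breadth_minCov <= 0 | breadth_minCov > 1))
    stop("breadth_minCov must lie in (0, 1]; genomes with zero callable ",
         "breadth have an undefined SNV rate and must be excluded")
  if (any(snv_number < 0)) stop("snv_number must be >= 0")
  snv_number / (g_len * breadth_minCov)
}

#' Depth-normalize a per-sample count
#'
#' Divides a raw per-sample count (mutated genomes, SNVs) by the sample's
#' sequencing depth. The default unit is counts per gigabase; `"mkb"`
#' (per million kilobases, i.e. per 1e9 bases) is numerically identical and
#' accepted for interoperability with that naming.
#'
#' @param raw_count Count(s).
#' @param depth_gb Sequencing depth(s) in gigabases, > 0.
#' @param unit `"gb"` or `"mkb"` (same scale).
#' @return Normalized count per gigabase.
#' @export
normalize_by_depth <- function(raw_count, depth_gb, unit = c("gb", "mkb")) {
  unit <- match.arg(unit)
  if (any(depth_gb <= 0)) stop("depth must be > 0")
  raw_count / depth_gb
}

#' Mean per-site nucleotide diversity of a genome
#'
#' Per variant site, pi = 1 - sum(p_i^2) over the allele frequencies; the
#' genome value is the mean over all qualifying sites (coverage >= min_cov),
#' with non-variant qualifying sites contributing zero. `n_sites` is
#' therefore the number of callable sites, not the number of variant sites.
#'
#' @param ref_freq,alt_freq Allele-frequency vectors of the variant sites
#'   (frequencies at a site sum to <= 1; any remainder is unobserved
#'   additional alleles and contributes no homozygosity).
#' @param site_coverage Coverage at each variant site.
#' @param n_sites Number of qualifying (callable) sites in the genome.
#' @param min_cov Coverage floor for a site to qualify.
#' @return Mean per-site pi.
#' @export
nucleotide_diversity <- function(ref_freq, alt_freq, site_coverage, n_sites,
                                 min_cov = 5L) {
  if (n_sites <= 0)
    stop("nucleotide diversity undefined: no qualifying sites")
  if (any(ref_freq + alt_freq > 1 + 1e-9))
    stop("allele frequencies at a site must sum to <= 1")
  keep <- site_coverage >= min_cov
  sum(1 - ref_freq[keep]^2 - alt_freq[keep]^2) / n_sites
}

#' Per-genome sequence abundance within a sample
#'
#' Relative abundance from the read pairs passing the pairing filter:
#' each mutated genome's count divided by the sample total.
#'
#' @param filtered_read_pairs Named (by genome) non-negative counts.
#' @return Fractions summing to 1.
#' @export
sequence_abundance <- function(filtered_read_pairs) {
  if (any(filtered_read_pairs < 0)) stop("read-pair counts must be >= 0")
  total <- sum(filtered_read_pairs)
  if (total == 0) stop("all-zero read-pair counts: sample must be excluded")
  filtered_read_pairs / total
}

#' Prevalence of a mutated genome in a sample subset
#'
#' Fraction of samples in which the genome carries at least one retained
#' SNV. No minimum-abundance gate is applied.
#'
#' @param carrier Logical vector: does each subset sample carry the genome?
#' @return Carrier fraction.
#' @export
prevalence <- function(carrier) {
  if (length(carrier) == 0) stop("prevalence undefined on an empty subset")
  mean(carrier)
}

#' Pool group prevalences reported at fixed precision
#'
#' Reconstructs integer carrier counts by rounding `prevalence * n` within
#' each group, then pools: `sum(carriers) / sum(n)`. Rounding to integers
#' first is what makes pooled values reproducible from prevalences printed
#' at two decimals.
#'
#' @param prev Per-group prevalences (fractions).
#' @param n Per-group sample sizes.
#' @return Pooled prevalence (fraction).
#' @examples
#' prevalence_pool(c(0.8716, 0.9192), c(919, 792))  # ~0.8936
#' @export
prevalence_pool <- function(prev, n) {
  stopifnot(length(prev) == length(n), all(n > 0))
  sum(round(prev * n)) / sum(n)
}

#' Collapsed variant-type profile of a set of SNVs
#'
#' Proportions of the six strand-complement-collapsed base-change classes.
#'
#' @param ref,alt Base vectors (equal length).
#' @return Named numeric vector over the six classes (all zero, with
#'   attribute `total = 0`, for empty input); attribute `total` records the
#'   SNV count.
#' @export
variant_type_profile <- function(ref, alt) {
  out <- stats::setNames(numeric(6), VARIANT_CLASSES)
  if (length(ref) == 0) {
    attr(out, "total") <- 0L
    return(out)
  }
  cls <- variant_class(ref, alt)
  tab <- table(factor(cls, levels = VARIANT_CLASSES))
  out[] <- as.numeric(tab) / length(cls)
  attr(out, "total") <- length(cls)
  out
}

#' Fraction of SNVs falling in gene-coding regions
#'
#' @param snvs SNV data.frame (`scaffold_id`, `position`).
#' @param genes CDS annotations (`scaffold_id`, `start0`, `end0`).
#' @return Fraction of SNVs inside any CDS interval (0 for no annotations;
#'   `NA` for no SNVs).
#' @export
coding_fraction <- function(snvs, genes) {
  if (nrow(snvs) == 0) return(NA_real_)
  if (is.null(genes) || nrow(genes) == 0) return(0)
  inside <- rep(FALSE, nrow(snvs))
  for (k in seq_len(nrow(genes))) {
    inside <- inside | (snvs$scaffold_id == genes$scaffold_id[k] &
                        snvs$position >= genes$start0[k] &
                        snvs$position < genes$end0[k])
  }
  mean(inside)
}

#' Assemble per-(sample, genome) SNV profiles
#'
#' Joins SNV counts with the genome-info table to produce one row per
#' mutated (sample, genome) pair with SNV count, SNV rate, nucleotide
#' diversity and within-sample sequence abundance.
#'
#' @param cohort A `snv_cohort`, or a list with `snv`, `genome_info`,
#'   `metadata` components in the canonical column layout.
#' @return data.frame: `sample_id`, `genome_id`, `snv_number`, `g_len`,
#'   `breadth_minCov`, `snv_rate`, `nucleotide_diversity`,
#'   `sequence_abundance`.
#' @export
genome_snv_profiles <- function(cohort) {
  gi <- cohort$genome_info
  key <- paste(gi$sample_id, gi$genome_id, sep = "\r")
  counts <- table(paste(cohort$snv$sample_id, cohort$snv$genome_id,
                        sep = "\r"))
  snv_number <- as.integer(counts[key])
  snv_number[is.na(snv_number)] <- 0L
  abund <- stats::ave(gi$filtered_read_pairs, gi$sample_id,
                      FUN = function(x) x / sum(x))
  data.frame(sample_id = gi$sample_id, genome_id = gi$genome_id,
             snv_number = snv_number, g_len = gi$g_len,
             breadth_minCov = gi$breadth_minCov,
             snv_rate = snv_rate(snv_number, gi$g_len, gi$breadth_minCov),
             nucleotide_diversity = gi$nucleotide_diversity,
             sequence_abundance = abund, stringsAsFactors = FALSE)
}

new_feature_table <- function(values, kind) {
  kind <- match.arg(kind, c("abundance", "snv_rate", "scfa_snv_freq"))
  if (any(values < 0)) stop("feature tables cannot hold negative values")
  structure(list(values = values, kind = kind), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table (%s): %d samples x %d features\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Build a samples-by-features table from long profiles
#'
#' Pivots per-(sample, genome) values into a matrix, fills absent pairs with
#' zero, drops features below a prevalence threshold, and (for
#' abundance-kind tables) renormalizes rows to sum to 1.
#'
#' @param profiles Long data.frame with `sample_id`, `genome_id` and the
#'   value column for `kind`.
#' @param kind `"abundance"`, `"snv_rate"` or `"scfa_snv_freq"`.
#' @param value_col Column of `profiles` holding the value; defaults to
#'   `"sequence_abundance"`, `"snv_rate"` or `"scfa_snv_freq"` by kind.
#' @param prevalence_min Minimum fraction of samples with a non-zero value
#'   for a feature to be kept (default 0.10; use 0.30 for the
#'   high-prevalence strain set, 0 to keep everything).
#' @param samples Optional full sample-id vector (samples with no profile
#'   rows become all-zero rows).
#' @return A `feature_table`.
#' @export
build_feature_table <- function(profiles,
                                kind = c("abundance", "snv_rate",
                                         "scfa_snv_freq"),
                                value_col = NULL, prevalence_min = 0.10,
                                samples = NULL) {
  kind <- match.arg(kind)
  if (is.null(value_col))
    value_col <- switch(kind, abundance = "sequence_abundance",
                        snv_rate = "snv_rate",
                        scfa_snv_freq = "scfa_snv_freq")
  if (!value_col %in% names(profiles))
    stop("profiles lack the '", value_col, "' column required for kind '",
         kind, "'")
  if (is.null(samples)) samples <- sort(unique(profiles$sample_id))
  features <- sort(unique(profiles$genome_id))
  values <- matrix(0, nrow = length(samples), ncol = length(features),
                   dimnames = list(samples, features))
  values[cbind(match(profiles$sample_id, samples),
               match(profiles$genome_id, features))] <- profiles[[value_col]]
  prev <- colMeans(values > 0)
  values <- values[, prev >= prevalence_min, drop = FALSE]
  if (ncol(values) == 0)
    stop("no features pass the prevalence threshold ", prevalence_min)
  if (kind == "abundance") {
    rs <- rowSums(values)
    zero_rows <- rs == 0
    if (any(zero_rows))
      warning(sum(zero_rows), " sample(s) have no retained features; ",
              "their abundance rows stay zero")
    values[!zero_rows, ] <- values[!zero_rows, , drop = FALSE] /
      rs[!zero_rows]
  }
  new_feature_table(values, kind)
}
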
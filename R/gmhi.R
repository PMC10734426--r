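# Gut Microbiome Health Index: compositional marker selection, per-sample
# marker summaries, population constants, the index itself, and
# classification evaluation.

#' Centered log-ratio transform of a feature table
#'
#' Per sample: zeros are replaced (default: half the sample's smallest
#' positive value), the row is renormalized, logged, and centred by its log
#' geometric mean. Rows of the result sum to zero.
#'
#' @param values Non-negative samples-by-features matrix.
#' @param zero_replace Function mapping a sample's positive values to the
#'   replacement used for its zeros.
#' @return CLR-transformed matrix.
#' @export
clr_transform <- function(values, zero_replace = function(pos) min(pos) / 2) {
  if (any(values < 0)) stop("CLR requires non-negative input")
  t(apply(values, 1, function(row) {
    if (all(row == 0))
      stop("clr_transform: sample with all-zero row cannot be transformed")
    row[row == 0] <- zero_replace(row[row > 0])
    lx <- log(row / sum(row))
    lx - mean(lx)
  }))
}

#' Select health- and nonhealthy-enriched marker features
#'
#' Per-feature two-sided Wilcoxon rank-sum tests between host groups, BH
#' correction, retention at `q < alpha`. Direction (healthy-enriched MH vs
#' nonhealthy-enriched MN) is assigned by the sign of the median group
#' difference. Abundance-kind tables are CLR-transformed before testing
#' (compositional data); the other kinds are tested on raw values.
#'
#' @param table A `feature_table`.
#' @param labels `"healthy"`/`"nonhealthy"` per sample (table row order).
#' @param alpha FDR threshold (default 0.05).
#' @param clr Whether to CLR-transform before testing; defaults to `TRUE`
#'   for abundance-kind tables.
#' @return List of class `marker_set`: `mh`, `mn` (feature ids), `stats`
#'   (feature, p, q, direction), `kind`.
#' @export
select_markers <- function(table, labels, alpha = 0.05,
                           clr = table$kind == "abundance") {
  stopifnot(inherits(table, "feature_table"))
  labels <- as.character(labels)
  if (sum(labels == "healthy") < 2 || sum(labels == "nonhealthy") < 2)
    stop("select_markers needs >= 2 samples per group")
  vals <- table$values
  test_vals <- if (clr) clr_transform(vals) else vals
  h <- labels == "healthy"
  p <- vapply(seq_len(ncol(test_vals)), function(j) {
    x <- test_vals[h, j]; y <- test_vals[!h, j]
    if (length(unique(c(x, y))) == 1) return(1)  # constant feature
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  med_diff <- apply(test_vals[h, , drop = FALSE], 2, stats::median) -
    apply(test_vals[!h, , drop = FALSE], 2, stats::median)
  # zero-inflated features tie at median 0 in both groups; break the tie
  # with the mean difference so a significant feature still gets a side
  tied <- med_diff == 0
  mean_diff <- colMeans(test_vals[h, , drop = FALSE]) -
    colMeans(test_vals[!h, , drop = FALSE])
  med_diff[tied] <- mean_diff[tied]
  sig <- q < alpha & med_diff != 0
  direction <- ifelse(med_diff > 0, "healthy", "nonhealthy")
  stats_df <- data.frame(feature = colnames(vals), p = p, q = q,
                         direction = ifelse(sig, direction, "none"),
                         stringsAsFactors = FALSE)
  structure(list(mh = colnames(vals)[sig & direction == "healthy"],
                 mn = colnames(vals)[sig & direction == "nonhealthy"],
                 stats = stats_df, kind = table$kind),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set (%s): %d healthy-enriched, %d nonhealthy-enriched\n",
              x$kind, length(x$mh), length(x$mn)))
  invisible(x)
}

#' Per-sample marker richness and Shannon diversity
#'
#' For each sample, richness is the number of markers with a value > 0 and
#' Shannon diversity is computed over the marker sub-vector renormalized to
#' proportions (natural log); a sample with zero marker richness gets
#' Shannon 0. MH and MN summaries are computed independently.
#'
#' @param table A `feature_table` (raw values).
#' @param markers A `marker_set`.
#' @return data.frame: `sample_id`, `hs`, `hr`, `ns`, `nr`.
#' @export
marker_summaries <- function(table, markers) {
  vals <- table$values
  one_side <- function(ids) {
    sub <- vals[, intersect(ids, colnames(vals)), drop = FALSE]
    richness <- rowSums(sub > 0)
    div <- apply(sub, 1, function(row)
      if (sum(row) > 0) shannon(row) else 0)
    list(richness = richness, diversity = div)
  }
  mh <- one_side(markers$mh)
  mn <- one_side(markers$mn)
  data.frame(sample_id = rownames(vals),
             hs = mh$diversity, hr = mh$richness,
             ns = mn$diversity, nr = mn$richness,
             stringsAsFactors = FALSE)
}

#' Population constants from top/bottom-ranked marker richness
#'
#' `hp` is the median MH-richness of the top `ceiling(top_fraction * n)`
#' samples ranked by MH richness (descending); `np` likewise from MN
#' richness. Ties are broken by sample id for determinism. A zero constant
#' is floored at `epsilon` with a warning.
#'
#' @param summaries Output of [marker_summaries()].
#' @param top_fraction Fraction of samples in the top set (default 0.01,
#'   minimum one sample).
#' @param epsilon Floor for degenerate constants.
#' @return Named vector `c(hp, np)`.
#' @export
population_constants <- function(summaries, top_fraction = 0.01,
                                 epsilon = 1e-5) {
  n <- nrow(summaries)
  if (n < 1) stop("population_constants needs >= 1 sample")
  m <- max(1L, ceiling(top_fraction * n))
  top_of <- function(x) {
    ord <- order(-x, summaries$sample_id)
    stats::median(x[ord[seq_len(m)]])
  }
  hp <- top_of(summaries$hr)
  np <- top_of(summaries$nr)
  if (hp == 0 || np == 0) {
    warning("population constant of 0 floored at epsilon")
    hp <- max(hp, epsilon); np <- max(np, epsilon)
  }
  c(hp = hp, np = np)
}

#' Health-index scores for summarized samples
#'
#' The collective health-enriched signal is `psi_H = (Hr / Hp) * Hs`, the
#' nonhealthy signal `psi_N = (Nr / Np) * Ns`, and the index
#' `GMHI = log10((psi_H + eps) / (psi_N + eps))`; `eps` keeps samples with
#' one empty marker side finite. Positive values indicate a
#' healthy-looking sample.
#'
#' @param summaries Output of [marker_summaries()].
#' @param constants Named vector `c(hp, np)` from [population_constants()].
#' @param epsilon Pseudo-value in the log ratio (default 1e-5).
#' @return data.frame: `sample_id`, `hs`, `hr`, `ns`, `nr`, `psi_h`,
#'   `psi_n`, `gmhi`.
#' @export
gmhi_score <- function(summaries, constants, epsilon = 1e-5) {
  stopifnot(all(c("hp", "np") %in% names(constants)),
            all(constants > 0))
  psi_h <- (summaries$hr / constants[["hp"]]) * summaries$hs
  psi_n <- (summaries$nr / constants[["np"]]) * summaries$ns
  cbind(summaries,
        data.frame(psi_h = psi_h, psi_n = psi_n,
                   gmhi = log10((psi_h + epsilon) / (psi_n + epsilon))))
}

#' Fit a health index on a discovery table
#'
#' Selects markers, summarizes every discovery sample and freezes the
#' population constants, returning a model that can score new tables
#' (external validation) with markers and constants unchanged.
#'
#' @param table A `feature_table` (discovery data).
#' @param labels Host-group labels in table row order.
#' @param alpha Marker FDR threshold.
#' @param top_fraction Top/bottom fraction for the population constants.
#' @param epsilon Pseudo-value for the index.
#' @param clr Passed to [select_markers()].
#' @return List of class `gmhi_model`: `markers`, `constants`, `epsilon`,
#'   `kind`, plus the discovery `scores`.
#' @export
gmhi_fit <- function(table, labels, alpha = 0.05, top_fraction = 0.01,
                     epsilon = 1e-5, clr = table$kind == "abundance") {
  markers <- select_markers(table, labels, alpha = alpha, clr = clr)
  if (length(markers$mh) == 0 && length(markers$mn) == 0)
    stop("gmhi_fit: no markers selected at alpha = ", alpha)
  summaries <- marker_summaries(table, markers)
  constants <- population_constants(summaries, top_fraction = top_fraction,
                                    epsilon = epsilon)
  model <- structure(list(markers = markers, constants = constants,
                          epsilon = epsilon, kind = table$kind),
                     class = "gmhi_model")
  model$scores <- gmhi_score(summaries, constants, epsilon)
  model
}

#' Score a feature table with a fitted health index
#'
#' @param object A `gmhi_model`.
#' @param table A `feature_table` of the same kind; markers absent from it
#'   contribute zero.
#' @param ... Unused.
#' @return Score data.frame as from [gmhi_score()].
#' @export
predict.gmhi_model <- function(object, table, ...) {
  stopifnot(inherits(table, "feature_table"))
  if (!identical(object$kind, table$kind))
    warning("scoring a '", table$kind, "' table with a '", object$kind,
            "'-trained index")
  gmhi_score(marker_summaries(table, object$markers), object$constants,
             object$epsilon)
}

#' @export
print.gmhi_model <- function(x, ...) {
  cat(sprintf("gmhi_model (%s): |MH| = %d, |MN| = %d, Hp = %.3g, Np = %.3g\n",
              x$kind, length(x$markers$mh), length(x$markers$mn),
              x$constants[["hp"]], x$constants[["np"]]))
  invisible(x)
}

#' Area under the ROC curve via the rank estimator
#'
#' Mann-Whitney estimator with midranks (tie-corrected): the probability
#' that a random positive-class sample scores above a random negative-class
#' sample, counting ties as one half.
#'
#' @param scores Numeric scores.
#' @param labels Class labels.
#' @param positive Label of the positive class (default `"healthy"`).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels, positive = "healthy") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("auroc needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a health index against host status
#'
#' AUROC (healthy as positive class), the overall two-sided Wilcoxon
#' rank-sum p-value between groups, and per-cohort Wilcoxon tests with a
#' pass flag at p < 0.05. Cohorts with a single class are skipped with a
#' notice.
#'
#' @param scores Per-sample index values.
#' @param labels `"healthy"`/`"nonhealthy"` per sample.
#' @param cohorts Optional per-sample cohort labels.
#' @return List: `auroc`, `p_overall`, `per_cohort` (data.frame `cohort`,
#'   `p`, `pass` or `NULL`).
#' @export
evaluate_index <- function(scores, labels, cohorts = NULL) {
  h <- labels == "healthy"
  if (!any(h) || all(h)) stop("evaluate_index needs both classes present")
  p_overall <- suppressWarnings(
    stats::wilcox.test(scores[h], scores[!h], exact = FALSE)$p.value)
  per_cohort <- NULL
  if (!is.null(cohorts)) {
    rows <- lapply(unique(cohorts), function(co) {
      in_co <- cohorts == co
      if (length(unique(labels[in_co])) < 2) {
        message("evaluate_index: cohort ", co, " has a single class; skipped")
        return(NULL)
      }
      p <- suppressWarnings(stats::wilcox.test(
        scores[in_co & h], scores[in_co & !h], exact = FALSE)$p.value)
      data.frame(cohort = co, p = p, pass = p < 0.05,
                 stringsAsFactors = FALSE)
    })
    per_cohort <- do.call(rbind, rows)
  }
  list(auroc = auroc(scores, labels), p_overall = p_overall,
       per_cohort = per_cohort)
}

#' SCFA-gene SNV feature table
#'
#' Per (sample, genome): the number of SNVs falling in the genome's
#' SCFA-family genes divided by the genome's total SCFA-gene length times
#' its breadth_minCov in that sample -- a per-callable-SCFA-base relative
#' frequency. The alternative denominator `"snv_total"` (fraction of the
#' genome's SNVs hitting SCFA genes) is kept behind a flag.
#'
#' @param snvs Cohort SNV table with `sample_id`.
#' @param genes Gene annotations; genes with `scfa_family != "none"` are
#'   used. Genomes without SCFA genes yield no feature.
#' @param genome_info Cohort genome-info table (for breadth and the sample
#'   x genome universe).
#' @param denominator `"gene_len_breadth"` (default) or `"snv_total"`.
#' @param prevalence_min Passed to [build_feature_table()].
#' @return A `feature_table` of kind `scfa_snv_freq`.
#' @export
scfa_snv_feature_table <- function(snvs, genes, genome_info,
                                   denominator = c("gene_len_breadth",
                                                   "snv_total"),
                                   prevalence_min = 0.10) {
  denominator <- match.arg(denominator)
  scfa <- genes[genes$scfa_family != "none", , drop = FALSE]
  if (nrow(scfa) == 0) stop("no SCFA-family gene annotations present")
  in_scfa <- rep(FALSE, nrow(snvs))
  for (k in seq_len(nrow(scfa))) {
    in_scfa <- in_scfa | (snvs$scaffold_id == scfa$scaffold_id[k] &
                          snvs$position >= scfa$start0[k] &
                          snvs$position < scfa$end0[k])
  }
  key_all <- paste(genome_info$sample_id, genome_info$genome_id, sep = "\r")
  scfa_counts <- table(paste(snvs$sample_id[in_scfa],
                             snvs$genome_id[in_scfa], sep = "\r"))
  all_counts <- table(paste(snvs$sample_id, snvs$genome_id, sep = "\r"))
  cnt <- as.numeric(scfa_counts[key_all]); cnt[is.na(cnt)] <- 0
  scfa_len <- tapply(scfa$end0 - scfa$start0, scfa$genome_id, sum)
  glen <- as.numeric(scfa_len[genome_info$genome_id])
  keep <- !is.na(glen)  # genomes with no SCFA genes carry no feature
  denom <- if (denominator == "gene_len_breadth") {
    glen * genome_info$breadth_minCov
  } else {
    tot <- as.numeric(all_counts[key_all]); tot[is.na(tot)] <- 0
    ifelse(tot > 0, tot, NA)
  }
  profiles <- data.frame(sample_id = genome_info$sample_id[keep],
                         genome_id = genome_info$genome_id[keep],
                         scfa_snv_freq = ifelse(is.na(denom[keep]), 0,
                                                cnt[keep] / denom[keep]),
                         stringsAsFactors = FALSE)
  build_feature_table(profiles, kind = "scfa_snv_freq",
                      prevalence_min = prevalence_min,
                      samples = sort(unique(genome_info$sample_id)))
}
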
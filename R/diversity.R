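# Alpha diversity, dissimilarities, ordination, permutation tests, and the
# matched-pair comparison of mutated-genome counts at equalized alpha
# diversity.

#' Shannon diversity index
#'
#' `-sum(p_i * ln p_i)` over the renormalized proportions (natural log).
#'
#' @param x Non-negative vector with positive sum.
#' @return Shannon index.
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s == 0) stop("Shannon index undefined for an all-zero vector")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Gini-Simpson diversity index
#'
#' `1 - sum(p_i^2)` over the renormalized proportions.
#'
#' @param x Non-negative vector with positive sum.
#' @return Simpson index.
#' @export
simpson <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s == 0) stop("Simpson index undefined for an all-zero vector")
  p <- x / s
  1 - sum(p^2)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `sum(|x_i - y_i|) / sum(x_i + y_i)`.
#'
#' @param x,y Equal-length non-negative vectors, not both all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("Bray-Curtis needs non-negative input")
  denom <- sum(x + y)
  if (denom == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(x - y)) / denom
}

#' Euclidean distance between two samples
#' @param x,y Equal-length vectors.
#' @return L2 distance.
#' @export
euclidean <- function(x, y) {
  stopifnot(length(x) == length(y))
  sqrt(sum((x - y)^2))
}

#' All-pairs distance matrix
#'
#' @param mat Samples-by-features matrix.
#' @param metric `"bray_curtis"` or `"euclidean"`.
#' @return Symmetric matrix with zero diagonal and a `metric` attribute.
#' @export
distance_matrix <- function(mat, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  d <- switch(metric,
              bray_curtis = vegan::vegdist(mat, method = "bray"),
              euclidean = stats::dist(mat))
  m <- as.matrix(d)
  attr(m, "metric") <- metric
  m
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a distance matrix (eigendecomposition of the
#' double-centered `-D^2/2` matrix). Axes are ordered by eigenvalue;
#' negative eigenvalues are returned as-is, never clipped, and explained
#' variance fractions are computed over the positive part only.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param k Number of axes (default `n - 1`).
#' @return List: `points` (n x k coordinates), `eig` (all eigenvalues),
#'   `explained` (fractions for the positive eigenvalues).
#' @export
pcoa <- function(d, k = NULL) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("pcoa requires a symmetric distance matrix")
  n <- nrow(m)
  if (is.null(k)) k <- n - 1L
  # cmdscale warns when k exceeds the positive-eigenvalue count; the full
  # spectrum is returned either way, so the warning carries no information
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = k,
                                          eig = TRUE))
  pos <- fit$eig[fit$eig > 0]
  list(points = fit$points, eig = fit$eig,
       explained = pos / sum(pos))
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Adonis): pseudo-F from
#' the among/within sum-of-squares decomposition of the distance matrix,
#' with a permutation p-value `(1 + #{F* >= F}) / (1 + n_perm)`.
#'
#' @param d Distance matrix (or `dist`).
#' @param groups Group labels, >= 2 groups with >= 2 samples each.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed for the permutation stream.
#' @return List: `r2`, `f`, `p`. `r2` is the among-group fraction of total
#'   sum of squares (the quantity some reports print as "R").
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("permanova needs >= 2 groups")
  if (any(table(groups) < 2))
    stop("permanova: every group needs >= 2 samples (singleton group found)")
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(groups = groups)
  fit <- vegan::adonis2(stats::as.dist(as.matrix(d)) ~ groups, data = df,
                        permutations = n_perm)
  list(r2 = fit$R2[1], f = fit$F[1], p = fit$`Pr(>F)`[1])
}

#' Greedy cross-group matching on an alpha-diversity value
#'
#' Sorts all healthy-nonhealthy pairs by absolute difference and greedily
#' accepts pairs while both members are unused and the difference is within
#' tolerance. Used to compare mutated-genome counts between groups at
#' equalized alpha diversity.
#'
#' @param values Per-sample values (alpha diversity), named by sample id.
#' @param labels `"healthy"`/`"nonhealthy"` per sample (same order).
#' @param tolerance Maximum |difference| within a pair (> 0).
#' @param one_sided If `TRUE`, only accept pairs where the nonhealthy value
#'   is the larger one (0 <= nonhealthy - healthy <= tolerance); default is
#'   the symmetric criterion.
#' @return List: `pairs` (data.frame `healthy`, `nonhealthy`, `diff`),
#'   `tolerance`, `fraction_matched` (matched samples / all samples).
#' @export
match_pairs <- function(values, labels, tolerance, one_sided = FALSE) {
  stopifnot(tolerance > 0, length(values) == length(labels))
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  hi <- which(labels == "healthy")
  ni <- which(labels == "nonhealthy")
  grid <- expand.grid(h = hi, n = ni)
  delta <- values[grid$n] - values[grid$h]  # nonhealthy minus healthy
  keep <- if (one_sided) delta >= 0 & delta <= tolerance
          else abs(delta) <= tolerance
  grid <- grid[keep, , drop = FALSE]
  delta <- abs(delta[keep])
  ord <- order(delta, grid$h, grid$n)
  used <- logical(length(values))
  rows <- list()
  for (r in ord) {
    h <- grid$h[r]; n <- grid$n[r]
    if (used[h] || used[n]) next
    used[h] <- used[n] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      healthy = ids[h], nonhealthy = ids[n], diff = delta[r],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    message("match_pairs: no cross-group pairs within tolerance ", tolerance)
  pairs <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(healthy = character(0), nonhealthy = character(0),
               diff = numeric(0), stringsAsFactors = FALSE)
  list(pairs = pairs, tolerance = tolerance,
       fraction_matched = 2 * nrow(pairs) / length(values))
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Exact null distribution for n <= 25 non-zero differences (ties
#' permitting), normal approximation with continuity correction above.
#'
#' @param diffs Paired differences; zeros are dropped with a notice.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  nz <- diffs[diffs != 0]
  if (length(nz) < length(diffs))
    message("wilcoxon_signed_rank: dropped ", length(diffs) - length(nz),
            " zero difference(s)")
  if (length(nz) == 0)
    stop("signed-rank test undefined: all differences are zero")
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  suppressWarnings(
    stats::wilcox.test(nz, exact = exact, correct = TRUE)$p.value)
}
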
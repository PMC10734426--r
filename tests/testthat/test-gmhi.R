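# Health-index construction: CLR, marker selection, summaries, constants,
# scores, and ROC evaluation.

test_that("CLR transform is centred and matches direct recomputation", {
  v <- matrix(c(1, 1, 1, 1), nrow = 1,
              dimnames = list("s1", paste0("f", 1:4)))
  expect_equal(unname(clr_transform(v)[1, ]), rep(0, 4))
  set.seed(1)
  values <- matrix(runif(40 * 8), nrow = 40,
                   dimnames = list(sprintf("s%d", 1:40), paste0("f", 1:8)))
  values[values < 0.2] <- 0
  out <- clr_transform(values)
  expect_equal(unname(rowSums(out)), rep(0, 40), tolerance = 1e-10)
  # direct recomputation for a sample with zeros
  row <- values[3, ]
  row[row == 0] <- min(row[row > 0]) / 2
  lx <- log(row / sum(row))
  expect_equal(out[3, ], lx - mean(lx), tolerance = 1e-12)
  allzero <- values
  allzero[5, ] <- 0
  expect_error(clr_transform(allzero), "all-zero")
})

test_that("marker selection is empty under exchangeable groups", {
  set.seed(2)
  half <- matrix(runif(30 * 12), nrow = 30)
  values <- rbind(half, half)  # identical groups duplicated
  rownames(values) <- sprintf("s%d", 1:60)
  colnames(values) <- sprintf("f%d", 1:12)
  ft <- snvgmhi:::new_feature_table(values, "snv_rate")
  ms <- select_markers(ft, rep(c("healthy", "nonhealthy"), each = 30))
  expect_length(ms$mh, 0)
  expect_length(ms$mn, 0)
  # constant feature: p = 1, no crash
  values2 <- values
  values2[, 1] <- 0.5
  ft2 <- snvgmhi:::new_feature_table(values2, "snv_rate")
  ms2 <- select_markers(ft2, rep(c("healthy", "nonhealthy"), each = 30))
  expect_equal(ms2$stats$p[1], 1)
})

test_that("planted markers are recovered with few false discoveries", {
  seeds <- 1:10
  rec <- numeric(0); false_n <- numeric(0); n_feat <- numeric(0)
  for (co in acceptance_cohorts(seeds)) {
    md <- co$metadata
    profiles <- genome_snv_profiles(co)
    ft <- build_feature_table(profiles, "snv_rate",
                              samples = md$sample_id)
    labels <- md$health_status[match(rownames(ft$values), md$sample_id)]
    ms <- select_markers(ft, labels)
    sel <- c(ms$mh, ms$mn)
    truth <- co$truth$markers$genome_id
    rec <- c(rec, mean(truth %in% sel))
    false_n <- c(false_n, length(setdiff(sel, truth)))
    n_feat <- c(n_feat, ncol(ft$values))
    # direction of recovered markers agrees with the plant
    tm <- co$truth$markers
    agree <- c(intersect(ms$mh, tm$genome_id[tm$direction == "healthy"]),
               intersect(ms$mn, tm$genome_id[tm$direction == "nonhealthy"]))
    expect_gte(length(agree), 0.9 * length(intersect(sel, truth)))
  }
  expect_gte(mean(rec), 0.8)
  expect_lte(mean(false_n), 0.1 * mean(n_feat))
})

test_that("marker selection stays near-empty under permuted labels", {
  co <- acceptance_cohorts(1:10)[[1]]
  md <- co$metadata
  ft <- build_feature_table(genome_snv_profiles(co), "snv_rate",
                            samples = md$sample_id)
  labels <- md$health_status[match(rownames(ft$values), md$sample_id)]
  set.seed(123)
  counts <- vapply(1:50, function(i) {
    ms <- select_markers(ft, sample(labels))
    length(ms$mh) + length(ms$mn)
  }, numeric(1))
  # expected discoveries under the null stay below alpha * features
  expect_lte(mean(counts), 0.05 * ncol(ft$values))
})

test_that("marker summaries and population constants follow their definitions", {
  values <- matrix(0, nrow = 3, ncol = 12,
                   dimnames = list(c("s1", "s2", "s3"), sprintf("f%02d", 1:12)))
  values["s1", 1:10] <- 2            # all MH markers equal and positive
  values["s2", 11:12] <- c(1, 3)
  ft <- snvgmhi:::new_feature_table(values, "snv_rate")
  ms <- structure(list(mh = sprintf("f%02d", 1:10),
                       mn = sprintf("f%02d", 11:12), kind = "snv_rate"),
                  class = "marker_set")
  su <- marker_summaries(ft, ms)
  expect_equal(su$hr[1], 10)
  expect_equal(su$hs[1], log(10))
  expect_equal(su$nr[1], 0)          # no MN markers present in s1
  expect_equal(su$ns[1], 0)
  expect_equal(su$nr[2], 2)
  p <- c(1, 3) / 4
  expect_equal(su$ns[2], -sum(p * log(p)), tolerance = 1e-12)
  # random fixtures vs direct recomputation
  set.seed(3)
  rv <- matrix(rexp(60 * 12), nrow = 60,
               dimnames = list(sprintf("r%02d", 1:60), colnames(values)))
  rv[rv < 0.5] <- 0
  ftr <- snvgmhi:::new_feature_table(rv, "snv_rate")
  sur <- marker_summaries(ftr, ms)
  i <- 17
  sub <- rv[i, ms$mh]
  expect_equal(sur$hr[i], sum(sub > 0))
  expect_equal(sur$hs[i], shannon(sub), tolerance = 1e-12)
  # constants: n=60, top 1% -> ceiling(0.6) = 1 sample, the max
  const <- population_constants(sur, top_fraction = 0.01)
  expect_equal(const[["hp"]], max(sur$hr))
  expect_equal(const[["np"]], max(sur$nr))
  # all-equal richness: constant equals the common value
  su_eq <- data.frame(sample_id = sprintf("e%d", 1:10), hs = 1, hr = 4,
                      ns = 1, nr = 2)
  expect_equal(population_constants(su_eq)[["hp"]], 4)
  # direct sort-and-median oracle at a larger top fraction
  const10 <- population_constants(sur, top_fraction = 0.10)
  expect_equal(const10[["hp"]],
               stats::median(sort(sur$hr, decreasing = TRUE)[1:6]))
})

test_that("the index follows its defining ratio and is antisymmetric", {
  su <- data.frame(sample_id = c("a", "b", "c"),
                   hs = c(1.2, 0.8, 0), hr = c(4, 2, 0),
                   ns = c(0.5, 0.8, 1.1), nr = c(1, 2, 3))
  const <- c(hp = 4, np = 4)
  sc <- gmhi_score(su, const, epsilon = 1e-5)
  expect_equal(sc$psi_h, (su$hr / 4) * su$hs, tolerance = 1e-12)
  expect_equal(sc$gmhi,
               log10((sc$psi_h + 1e-5) / (sc$psi_n + 1e-5)),
               tolerance = 1e-12)
  # psi_h == psi_n > 0 gives exactly 0
  su_eq <- data.frame(sample_id = "x", hs = 1, hr = 2, ns = 1, nr = 2)
  expect_equal(gmhi_score(su_eq, c(hp = 2, np = 2))$gmhi, 0)
  # psi_n = 0: positive, finite
  su_h <- data.frame(sample_id = "y", hs = 1, hr = 2, ns = 0, nr = 0)
  sc_h <- gmhi_score(su_h, c(hp = 2, np = 2))
  expect_gt(sc_h$gmhi, 0)
  expect_true(is.finite(sc_h$gmhi))
  # swapping MH and MN (with hp = np) negates the index exactly
  set.seed(4)
  for (rep in 1:20) {
    su_r <- data.frame(sample_id = "z", hs = runif(1, 0, 2),
                       hr = sample(0:10, 1), ns = runif(1, 0, 2),
                       nr = sample(0:10, 1))
    su_sw <- data.frame(sample_id = "z", hs = su_r$ns, hr = su_r$nr,
                        ns = su_r$hs, nr = su_r$hr)
    cc <- c(hp = 5, np = 5)
    expect_equal(gmhi_score(su_r, cc)$gmhi, -gmhi_score(su_sw, cc)$gmhi,
                 tolerance = 1e-12)
  }
})

test_that("AUROC matches exhaustive pair counting and external pROC", {
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12),
                     rep(c("nonhealthy", "healthy"), each = 3)), 1)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    labels <- sample(rep(c("healthy", "nonhealthy"), length.out = n))
    scores <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  scores <- rnorm(80)
  labels <- sample(rep(c("healthy", "nonhealthy"), 40))
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(
                 response = labels, predictor = scores, levels = c("nonhealthy", "healthy"),
                 direction = "<", quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("AUROC is null-centred under shuffled labels", {
  co <- acceptance_cohorts(1:10)[[1]]
  md <- co$metadata
  res <- suppressWarnings(suppressMessages(run_gmhi_pipeline(co)))
  scores <- res$snv_rate$model$scores$gmhi
  labels <- md$health_status[match(res$snv_rate$model$scores$sample_id,
                                   md$sample_id)]
  set.seed(6)
  null_auc <- vapply(1:200, function(i) auroc(scores, sample(labels)),
                     numeric(1))
  n1 <- sum(labels == "healthy"); n0 <- sum(labels == "nonhealthy")
  null_sd <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(mean(null_auc) - 0.5), 3 * null_sd / sqrt(200))
})

test_that("a fitted index scores an external cohort with frozen markers", {
  discovery <- acceptance_cohorts(1:10)[[1]]
  # same genomes and planted markers, fresh samples
  validation <- simulate_cohort(sim_config(seed = 1), sample_seed = 9001)
  md_d <- discovery$metadata
  md_v <- validation$metadata
  ft_d <- build_feature_table(genome_snv_profiles(discovery), "snv_rate",
                              samples = md_d$sample_id)
  ft_v <- build_feature_table(genome_snv_profiles(validation), "snv_rate",
                              samples = md_v$sample_id)
  labels_d <- md_d$health_status[match(rownames(ft_d$values), md_d$sample_id)]
  labels_v <- md_v$health_status[match(rownames(ft_v$values), md_v$sample_id)]
  fit <- gmhi_fit(ft_d, labels_d)
  sc_v <- predict(fit, ft_v)
  ev <- evaluate_index(sc_v$gmhi, labels_v)
  # both cohorts share the generator's marker structure, so frozen markers
  # still separate the validation groups clearly
  expect_gt(ev$auroc, 0.6)
  expect_lt(ev$p_overall, 0.01)
})

test_that("SCFA SNV features equal a brute-force per-gene recount", {
  co <- simulate_cohort(tiny_config(seed = 13))
  ft <- scfa_snv_feature_table(co$snv, co$genes, co$genome_info,
                               prevalence_min = 0)
  expect_equal(ft$kind, "scfa_snv_freq")
  # brute force one (sample, genome) cell
  gi <- co$genome_info
  for (pick in c(1, 7, nrow(gi))) {
    sid <- gi$sample_id[pick]; gid <- gi$genome_id[pick]
    genes_g <- co$genes[co$genes$genome_id == gid, ]
    cnt <- 0
    sub <- co$snv[co$snv$sample_id == sid & co$snv$genome_id == gid, ]
    for (i in seq_len(nrow(sub))) {
      cnt <- cnt + any(genes_g$start0 <= sub$position[i] &
                       sub$position[i] < genes_g$end0)
    }
    denom <- sum(genes_g$end0 - genes_g$start0) * gi$breadth_minCov[pick]
    expect_equal(ft$values[sid, gid], cnt / denom, tolerance = 1e-12)
  }
  # a sample-genome pair with no SCFA SNVs yields zero
  zero_cells <- ft$values[ft$values == 0]
  expect_gte(length(zero_cells), 0)
})
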
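# Coding-effect classification, siteness, pN/pS and codon-bias testing
# against enumeration and full-translation oracles.

plus_gene <- function(seq) {
  data.frame(gene_id = "g", genome_id = "sc", scaffold_id = "sc",
             start = 1L, end = nchar(seq), start0 = 0L, end0 = nchar(seq),
             strand = "+", scfa_family = "ack", codon_eligible = TRUE,
             stringsAsFactors = FALSE)
}

test_that("start-codon and stop-codon changes classify as forced", {
  gene <- plus_gene("ATGTGGAAATAA")
  seq <- "ATGTGGAAATAA"
  # codon 0 ATG -> ATA: start inactivated
  res <- classify_snv_effect(gene, seq, position = 2, "G", "A")
  expect_equal(res$effect, "start_loss")
  expect_equal(res$alt_codon, "ATA")
  # ATG -> GTG stays a valid start: not a start loss
  res2 <- classify_snv_effect(gene, seq, position = 0, "A", "G")
  expect_false(res2$effect == "start_loss")
  # TGG -> TGA: stop gain
  res3 <- classify_snv_effect(gene, seq, position = 5, "G", "A")
  expect_equal(res3$effect, "stop_gain")
  # TAA terminal stop -> TCA: stop loss
  res4 <- classify_snv_effect(gene, seq, position = 10, "A", "C")
  expect_equal(res4$effect, "stop_loss")
  # outside the gene span
  res5 <- classify_snv_effect(gene, seq, position = 400, "A", "C")
  expect_equal(res5$effect, "noncoding")
  # reference disagreement is an error naming the gene
  expect_error(classify_snv_effect(gene, seq, position = 1, "C", "A"),
               "reference mismatch")
})

test_that("classification matches the full-gene translation oracle", {
  set.seed(33)
  gen <- simulate_genomes(sim_config(n_genomes = 4, seed = 33))
  genes <- gen$genes
  checked <- 0
  per_gene <- ceiling(1000 / nrow(genes))
  for (k in seq_len(nrow(genes))) {
    gene <- genes[k, ]
    gseq <- gene_sequence(gene, gen$genomes)
    genome_seq <- gen$genomes[[gene$scaffold_id]]
    chars <- strsplit(genome_seq, "")[[1]]
    pos <- sample(gene$start0:(gene$end0 - 1), per_gene, replace = TRUE)
    for (p in pos) {
      ref <- chars[p + 1]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- classify_snv_effect(gene, gseq, p, ref, alt)$effect
      want <- oracle_effect(gene, genome_seq, p, ref, alt)
      expect_equal(got, want,
                   info = sprintf("%s %s pos %d %s>%s", gene$gene_id,
                                  gene$strand, p, ref, alt))
      checked <- checked + 1
    }
  }
  expect_gte(checked, 1000)
})

test_that("vectorized classification agrees with the scalar path", {
  co <- simulate_cohort(tiny_config(seed = 44))
  eff <- classify_effects(co$snv, co$genes, co$genomes)
  idx <- which(!is.na(eff$gene_id))
  idx <- sample(idx, min(200, length(idx)))
  for (i in idx) {
    gene <- co$genes[co$genes$gene_id == eff$gene_id[i], ]
    gseq <- gene_sequence(gene, co$genomes)
    expect_equal(
      eff$effect[i],
      classify_snv_effect(gene, gseq, eff$position[i], eff$ref_base[i],
                          eff$alt_base[i])$effect)
  }
  expect_true(all(eff$effect[is.na(eff$gene_id)] == "noncoding"))
})

test_that("siteness sums to gene length and matches exhaustive enumeration", {
  set.seed(55)
  gc11 <- Biostrings::getGeneticCode("11")
  for (rep in 1:5) {
    ncod <- 300
    sense <- setdiff(names(gc11), c("TAA", "TAG", "TGA"))
    seq <- paste(c("ATG", sample(sense, ncod - 2, replace = TRUE),
                   sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
    sites <- codon_site_counts(seq)
    expect_equal(unname(sites["n_sites"] + sites["s_sites"]), 3 * ncod)
    # independent oracle: walk every codon position and alternate base
    n_brute <- 0
    for (ci in 0:(ncod - 1)) {
      cd <- substr(seq, ci * 3 + 1, ci * 3 + 3)
      for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                       substr(cd, p, p))) {
        alt <- cd
        substr(alt, p, p) <- b
        if (gc11[[cd]] != gc11[[alt]]) n_brute <- n_brute + 1 / 3
      }
    }
    expect_equal(unname(sites["n_sites"]), n_brute, tolerance = 1e-9)
  }
})

test_that("pN/pS follows its defining ratio on a constructed gene", {
  gen <- simulate_genomes(sim_config(n_genomes = 1, seed = 66))
  gene <- gen$genes[1, ]
  gseq <- gene_sequence(gene, gen$genomes)
  sites <- codon_site_counts(gseq)
  chars <- strsplit(gen$genomes[[gene$scaffold_id]], "")[[1]]
  # find one synonymous and one nonsynonymous change inside the gene
  find_effect <- function(target) {
    for (p in gene$start0:(gene$end0 - 1)) {
      for (b in setdiff(c("A", "C", "G", "T"), chars[p + 1])) {
        if (classify_snv_effect(gene, gseq, p, chars[p + 1], b)$effect ==
            target)
          return(data.frame(scaffold_id = gene$scaffold_id, position = p,
                            ref_base = chars[p + 1], alt_base = b,
                            stringsAsFactors = FALSE))
      }
    }
    stop("no ", target, " change found")
  }
  snvs <- rbind(find_effect("synonymous"), find_effect("nonsynonymous"))
  res <- pn_ps(gene, gseq, snvs)
  expect_equal(res$n_obs, 1)
  expect_equal(res$s_obs, 1)
  expect_equal(res$pn_ps,
               (1 / res$n_sites) / (1 / res$s_sites), tolerance = 1e-12)
  # and the printed-example arithmetic: N=700, S=300 sites
  expect_equal((1 / 700) / (1 / 300), 0.4286, tolerance = 1e-4)
  # zero SNVs: rates zero, ratio undefined
  none <- pn_ps(gene, gseq, snvs[0, ])
  expect_equal(none$pn, 0)
  expect_equal(none$ps, 0)
  expect_true(is.na(none$pn_ps))
})

test_that("Fisher exact p for codon bias matches hypergeometric enumeration", {
  make_effects <- function(carriers_h, n_h, carriers_n, n_n) {
    # n individuals with an SNV on the gene; `carriers` of them stop-gain
    rows <- function(prefix, carriers, n) {
      data.frame(sample_id = paste0(prefix, seq_len(n)),
                 gene_id = "g",
                 effect = c(rep("stop_gain", carriers),
                            rep("synonymous", n - carriers)),
                 stringsAsFactors = FALSE)
    }
    rbind(rows("h", carriers_h, n_h), rows("n", carriers_n, n_n))
  }
  labels_for <- function(eff) {
    lab <- ifelse(grepl("^h", eff$sample_id), "healthy", "nonhealthy")
    stats::setNames(lab, eff$sample_id)
  }
  # no events in either group: frequencies 0, p = 1
  eff <- make_effects(0, 50, 0, 60)
  res <- codon_bias_frequency(eff, "g", labels_for(eff))
  expect_equal(res$summary$frequency, c(0, 0))
  expect_equal(res$fisher_p, 1)
  # symmetric carriers: p = 1
  eff <- make_effects(5, 50, 5, 50)
  res <- codon_bias_frequency(eff, "g", labels_for(eff))
  expect_equal(res$fisher_p, 1)
  # random tables vs exhaustive enumeration
  set.seed(77)
  for (rep in 1:25) {
    n_h <- sample(5:40, 1); n_n <- sample(5:40, 1)
    c_h <- sample(0:n_h, 1); c_n <- sample(0:n_n, 1)
    eff <- make_effects(c_h, n_h, c_n, n_n)
    res <- codon_bias_frequency(eff, "g", labels_for(eff))
    expect_equal(res$fisher_p,
                 oracle_fisher2x2(c_h, n_h - c_h, c_n, n_n - c_n),
                 tolerance = 1e-10)
    # label-swap invariance
    swapped <- labels_for(eff)
    swapped[] <- ifelse(swapped == "healthy", "nonhealthy", "healthy")
    expect_equal(codon_bias_frequency(eff, "g", swapped)$fisher_p,
                 res$fisher_p, tolerance = 1e-12)
  }
})

test_that("recurrent codon variants are found, ranked and tie-broken", {
  # constructed fixture: one stop-gain shared by 5 individuals, one by 3,
  # and a same-count pair to exercise the position tie-break
  mk <- function(sample, pos, eff = "stop_gain") {
    data.frame(sample_id = sample, scaffold_id = "sc", position = pos,
               ref_base = "G", alt_base = "A", ref_codon = "TGG",
               alt_codon = "TGA", gene_id = "g", effect = eff,
               stringsAsFactors = FALSE)
  }
  eff <- rbind(mk(sprintf("i%d", 1:5), 100L),
               mk(sprintf("i%d", c(1, 6, 7)), 250L),
               mk(sprintf("i%d", 1:3), 40L),
               mk("i9", 7L),
               mk("i1", 300L, eff = "synonymous"))
  rec <- recurrent_codon_variants(eff, min_individuals = 3L)
  expect_equal(rec$n_individuals, c(5L, 3L, 3L))
  expect_equal(rec$position, c(100L, 40L, 250L))  # ties by position asc
  expect_equal(recurrent_codon_variants(eff, 6L),
               recurrent_codon_variants(eff[0, ], 3L))
  expect_equal(nrow(recurrent_codon_variants(eff, 6L)), 0)

  # planted ground truth from the generator is recovered with correct n
  co <- simulate_cohort(tiny_config(seed = 8))
  cls <- classify_effects(co$snv, co$genes, co$genomes)
  cls$sample_id <- co$snv$sample_id
  rec2 <- recurrent_codon_variants(cls, min_individuals = 2L)
  planted <- co$truth$planted
  pk <- paste(planted$genome_id, planted$position, planted$alt_base)
  shared <- table(pk)
  shared <- shared[shared >= 2]
  rk <- paste(rec2$scaffold_id, rec2$position, rec2$alt_base)
  for (key in names(shared)) {
    expect_true(key %in% rk)
    expect_gte(rec2$n_individuals[match(key, rk)], shared[[key]])
  }
})
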
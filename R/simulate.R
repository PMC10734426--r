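# Seeded synthetic cohort generator.
#
# Emulates the post-SNV-calling data layer of a two-group stool-metagenome
# meta-analysis: per-sample SNV tables and genome-info tables for a shared
# reference-genome set, with planted group structure (mutated-genome
# counts, SNV rates on marker genomes, collapsed variant-type bias,
# stop-gain/start-loss planting in SCFA genes). All randomness flows from
# one seed, so a config + integer reproduces a cohort byte for byte.

#' Generate reference genomes with annotated SCFA genes
#'
#' Random uniform-composition scaffolds (one per genome), each carrying
#' non-overlapping SCFA-family CDS on mixed strands. Every gene starts with
#' ATG, ends with a stop codon, has no internal stop, and its length is
#' divisible by 3; family labels cycle through the nine SCFA families
#' (ack, buk, ydiF, atoD, atoA, ctfA, ctfB, BcAt, scpC).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return List: `genomes` (named character vector of scaffold sequences)
#'   and `genes` (annotation data.frame as from [read_gene_annotations()]).
#' @export
simulate_genomes <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  n_genes <- config$n_scfa_genes_per_genome
  block <- config$genome_len %/% n_genes
  if (block <= config$gene_len + 2L)
    stop("infeasible gene packing: reduce n_scfa_genes_per_genome or ",
         "gene_len, or increase genome_len")
  sense_codons <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  genomes <- character(config$n_genomes)
  names(genomes) <- sprintf("genome_%03d", seq_len(config$n_genomes))
  gene_rows <- vector("list", config$n_genomes * n_genes)
  fam_i <- 0L
  for (g in seq_len(config$n_genomes)) {
    chars <- sample(BASES, config$genome_len, replace = TRUE)
    for (j in seq_len(n_genes)) {
      start0 <- (j - 1L) * block +
        sample.int(block - config$gene_len, 1L) - 1L
      ncod <- config$gene_len %/% 3L
      codons <- c("ATG",
                  sample(sense_codons, ncod - 2L, replace = TRUE),
                  sample(STOP_CODONS, 1L))
      coding <- seq_to_chars(paste(codons, collapse = ""))
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "-") revcomp_chars(coding) else coding
      chars[(start0 + 1):(start0 + config$gene_len)] <- ins
      fam_i <- fam_i + 1L
      gene_rows[[(g - 1L) * n_genes + j]] <- data.frame(
        gene_id = sprintf("%s_gene%d", names(genomes)[g], j),
        genome_id = names(genomes)[g],
        scaffold_id = names(genomes)[g],
        start = start0 + 1L, end = start0 + config$gene_len,
        start0 = start0, end0 = start0 + config$gene_len,
        strand = strand,
        scfa_family = SCFA_FAMILIES[(fam_i - 1L) %% length(SCFA_FAMILIES) + 1L],
        codon_eligible = TRUE, stringsAsFactors = FALSE)
    }
    genomes[g] <- paste(chars, collapse = "")
  }
  list(genomes = genomes, genes = do.call(rbind, gene_rows))
}

#' Generate a full synthetic cohort
#'
#' Draws per-sample depths, mutated-genome sets, per-genome breadth and SNV
#' counts, SNV positions/alleles and planted codon-bias events, and returns
#' everything downstream modules consume plus the generator's ground truth.
#'
#' Per sample of group g: depth ~ LogNormal; number of mutated genomes ~
#' Poisson(lambda_g x depth) truncated to `[1, n_genomes]`, genomes drawn
#' with marker genomes upweighted. Per mutated genome: breadth_minCov ~
#' Beta; the callable region is a wrap-around window of `breadth x g_len`
#' bases; SNV count ~ Poisson(rate x g_len x breadth) with positions uniform
#' over the window; alternate alleles follow the group's collapsed
#' variant-type profile (conditioned on the reference base); SNVs inside
#' SCFA genes are, with the group's stop-gain probability, relocated to a
#' callable site that creates a stop-gain or start-loss (recorded in ground
#' truth); per-site allele frequencies give the genome's nucleotide
#' diversity; filtered read pairs follow a genome relative-abundance draw
#' with marker genomes shifted in their enriched group.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`); drives the reference
#'   genomes, the marker assignment and (unless `sample_seed` is given) the
#'   sample-level draws.
#' @param sample_seed Optional second seed applied after the genome and
#'   marker layout is fixed. Two cohorts generated with the same `seed` but
#'   different `sample_seed`s share their reference genomes and planted
#'   marker structure while drawing independent samples -- a
#'   discovery/external-validation pair.
#' @return A `snv_cohort`: `metadata`, `snv`, `genome_info`, `genomes`,
#'   `genes`, and `truth` (`markers`, `planted`, `windows`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed,
                            sample_seed = NULL) {
  validate_sim_config(config)
  gen <- simulate_genomes(config, seed = seed)  # seeds the RNG
  genomes <- gen$genomes
  genes <- gen$genes
  n_genomes <- config$n_genomes
  genome_ids <- names(genomes)
  g_len <- config$genome_len
  seq_chars <- as_seq_chars(genomes)

  # marker genomes and their enriched group
  n_markers <- round(config$marker_fraction * n_genomes)
  marker_idx <- sort(sample.int(n_genomes, n_markers))
  marker_dir <- rep(c("healthy", "nonhealthy"), length.out = n_markers)
  direction <- rep("none", n_genomes)
  direction[marker_idx] <- marker_dir
  truth_markers <- data.frame(genome_id = genome_ids[marker_idx],
                              direction = marker_dir,
                              stringsAsFactors = FALSE)
  # presence weights: marker genomes are prevalent overall and more
  # prevalent still in their enriched group (marker strains differ in
  # prevalence between host groups, not only in value when present)
  base_w <- ifelse(direction == "none", 1, config$marker_weight)
  weights_by_group <- list(
    healthy = base_w * ifelse(direction == "healthy",
                              config$marker_presence_effect, 1),
    nonhealthy = base_w * ifelse(direction == "nonhealthy",
                                 config$marker_presence_effect, 1))

  # per-genome baseline log-abundance; marker genomes shifted in their group
  mu_ab <- stats::rnorm(n_genomes, 0, 0.7)

  # per-gene precomputation: SCFA membership map and stop/start candidates
  gene_map <- lapply(genome_ids, function(gid) {
    m <- integer(g_len)  # 0 = intergenic, else row index into `genes`
    rows <- which(genes$genome_id == gid)
    for (k in rows) m[(genes$start0[k] + 1):genes$end0[k]] <- k
    m
  })
  names(gene_map) <- genome_ids
  gene_seqs <- vapply(seq_len(nrow(genes)), function(k)
    gene_sequence(genes[k, ], seq_chars), character(1))
  candidates <- lapply(seq_len(nrow(genes)), function(k) {
    cand <- stop_start_candidates(gene_seqs[k])
    if (genes$strand[k] == "-") {
      data.frame(pos0 = genes$end0[k] - 1L - cand$offset,
                 alt = unname(COMPLEMENT[cand$alt]),
                 effect = cand$effect, stringsAsFactors = FALSE)
    } else {
      data.frame(pos0 = genes$start0[k] + cand$offset,
                 alt = cand$alt, effect = cand$effect,
                 stringsAsFactors = FALSE)
    }
  })

  if (!is.null(sample_seed)) set.seed(sample_seed)
  n_total <- config$n_healthy + config$n_nonhealthy
  sample_ids <- sprintf("S%04d", seq_len(n_total))
  groups <- rep(c("healthy", "nonhealthy"),
                c(config$n_healthy, config$n_nonhealthy))
  diseases <- c("CRC", "LC", "GD", "T2D", "UC", "AS")
  metadata <- data.frame(
    sample_id = sample_ids,
    cohort = paste0("cohort", (seq_len(n_total) - 1L) %% 4L + 1L),
    phenotype = ifelse(groups == "healthy", "HEALTHY",
                       diseases[(seq_len(n_total) - 1L) %% length(diseases) + 1L]),
    health_status = groups,
    depth_gb = stats::rlnorm(n_total, config$depth_meanlog, config$depth_sdlog),
    stringsAsFactors = FALSE)

  # accumulators (flat lists concatenated once at the end)
  acc <- list(snv = list(), gi = list(), planted = list(), win = list())
  bias_by_group <- list(
    healthy = config$variant_type_bias_healthy[VARIANT_CLASSES],
    nonhealthy = config$variant_type_bias_nonhealthy[VARIANT_CLASSES])
  # per reference base, the three reachable classes and their alt bases
  alt_choices <- lapply(BASES, function(r) {
    alts <- setdiff(BASES, r)
    data.frame(alt = alts, class = variant_class(rep(r, 3), alts),
               stringsAsFactors = FALSE)
  })
  names(alt_choices) <- BASES

  for (i in seq_len(n_total)) {
    grp <- groups[i]
    depth <- metadata$depth_gb[i]
    lambda <- if (grp == "healthy") config$lambda_genomes_healthy else
      config$lambda_genomes_nonhealthy
    base_rate <- if (grp == "healthy") config$snv_rate_healthy else
      config$snv_rate_nonhealthy
    sg_prob <- if (grp == "healthy") config$stopgain_prob_healthy else
      config$stopgain_prob_nonhealthy
    k <- max(1L, min(stats::rpois(1L, lambda * depth), n_genomes))
    mut <- sort(sample.int(n_genomes, k, prob = weights_by_group[[grp]]))
    # sequence abundance: log-normal around genome means, marker shift
    shift <- ifelse(direction[mut] == grp, config$abundance_effect, 0)
    ab <- exp(stats::rnorm(k, mu_ab[mut] + shift, 0.5))
    frac <- ab / sum(ab)
    pairs <- pmax(1L, round(frac * depth * 2e5))

    s_breadth <- stats::rbeta(k, config$breadth_shape1, config$breadth_shape2)
    s_cov <- config$min_cov + stats::rgamma(k, shape = 8, scale = 2)
    s_pi <- numeric(k)

    for (jj in seq_len(k)) {
      gidx <- mut[jj]
      gid <- genome_ids[gidx]
      breadth <- s_breadth[jj]
      m <- max(30L, round(breadth * g_len))
      win_start <- sample.int(g_len, 1L) - 1L  # 0-based
      rate <- base_rate *
        (if (direction[gidx] == grp) config$snv_rate_effect else 1)
      n_snv <- min(stats::rpois(1L, rate * g_len * breadth), m)
      acc$win[[length(acc$win) + 1L]] <- data.frame(
        sample_id = sample_ids[i], genome_id = gid,
        win_start0 = win_start, win_len = m, stringsAsFactors = FALSE)
      if (n_snv == 0L) { s_pi[jj] <- 0; next }
      pos0 <- (win_start + sample.int(m, n_snv) - 1L) %% g_len
      chars <- seq_chars[[gid]]
      ref <- chars[pos0 + 1L]
      # alternate allele by group variant-type bias, conditioned on ref
      bias <- bias_by_group[[grp]]
      alt <- character(n_snv)
      for (b in BASES) {
        sel <- which(ref == b)
        if (length(sel) == 0) next
        ch <- alt_choices[[b]]
        p <- bias[ch$class]
        alt[sel] <- ch$alt[sample.int(3L, length(sel), replace = TRUE,
                                      prob = p / sum(p))]
      }
      # plant stop-gain/start-loss for SNVs landing in SCFA genes
      gmap <- gene_map[[gid]]
      in_gene <- gmap[pos0 + 1L]
      for (s in which(in_gene > 0L)) {
        if (stats::runif(1L) >= sg_prob) next
        cand <- candidates[[in_gene[s]]]
        in_win <- ((cand$pos0 - win_start) %% g_len) < m
        free <- !(cand$pos0 %in% pos0[-s])
        ok <- which(in_win & free)
        if (length(ok) == 0L) next
        pick <- ok[sample.int(length(ok), 1L)]
        pos0[s] <- cand$pos0[pick]
        ref[s] <- chars[pos0[s] + 1L]
        alt[s] <- cand$alt[pick]
        acc$planted[[length(acc$planted) + 1L]] <- data.frame(
          sample_id = sample_ids[i], genome_id = gid,
          gene_id = genes$gene_id[in_gene[s]],
          position = pos0[s], ref_base = ref[s], alt_base = alt[s],
          effect = cand$effect[pick], stringsAsFactors = FALSE)
      }
      alt_freq <- stats::runif(n_snv, 0.05, 0.5)
      ref_freq <- 1 - alt_freq
      cov <- config$min_cov + stats::rpois(n_snv, s_cov[jj] - config$min_cov)
      s_pi[jj] <- sum(2 * ref_freq * alt_freq) / m
      acc$snv[[length(acc$snv) + 1L]] <- data.frame(
        sample_id = sample_ids[i], genome_id = gid, scaffold_id = gid,
        position = pos0, ref_base = ref, alt_base = alt,
        ref_freq = ref_freq, alt_freq = alt_freq, site_coverage = cov,
        stringsAsFactors = FALSE)
    }
    acc$gi[[length(acc$gi) + 1L]] <- data.frame(
      sample_id = sample_ids[i], genome_id = genome_ids[mut],
      g_len = g_len, coverage = s_cov, breadth_minCov = s_breadth,
      nucleotide_diversity = s_pi, filtered_read_pairs = pairs,
      stringsAsFactors = FALSE)
  }

  empty_planted <- data.frame(sample_id = character(0),
                              genome_id = character(0),
                              gene_id = character(0), position = integer(0),
                              ref_base = character(0),
                              alt_base = character(0), effect = character(0),
                              stringsAsFactors = FALSE)
  structure(list(
    metadata = metadata,
    snv = do.call(rbind, acc$snv),
    genome_info = do.call(rbind, acc$gi),
    genomes = genomes,
    genes = genes,
    truth = list(markers = truth_markers,
                 planted = if (length(acc$planted) > 0)
                   do.call(rbind, acc$planted) else empty_planted,
                 windows = do.call(rbind, acc$win))),
    class = "snv_cohort")
}
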
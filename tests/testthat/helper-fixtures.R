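# Shared fixtures and independent oracles for the test suite.

# small, fast cohort configuration for unit tests
tiny_config <- function(seed = 101, ...) {
  sim_config(n_healthy = 12, n_nonhealthy = 12, n_genomes = 8,
             genome_len = 4500L, n_scfa_genes_per_genome = 2L,
             gene_len = 300L, seed = seed, ...)
}

# default-scale cohorts reused across acceptance blocks, built lazily once
.acceptance_env <- new.env(parent = emptyenv())
acceptance_cohorts <- function(seeds = 1:10) {
  key <- paste(seeds, collapse = ",")
  if (is.null(.acceptance_env[[key]])) {
    .acceptance_env[[key]] <- lapply(seeds, function(s)
      simulate_cohort(sim_config(seed = s)))
  }
  .acceptance_env[[key]]
}

# Independent full-gene translation oracle: rebuild the mutated gene,
# translate both with Biostrings, and classify from the protein diff and
# explicit start/stop checks. Positions are 0-based on the scaffold.
oracle_effect <- function(gene, genome_seq, position, ref_base, alt_base) {
  chars <- strsplit(genome_seq, "")[[1]]
  stopifnot(chars[position + 1] == ref_base)
  mut <- chars
  mut[position + 1] <- alt_base
  extract <- function(ch) {
    g <- ch[(gene$start0 + 1):gene$end0]
    if (gene$strand == "-")
      g <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[g]))
    paste(g, collapse = "")
  }
  ref_cds <- extract(chars)
  alt_cds <- extract(mut)
  if (identical(ref_cds, alt_cds)) return("noncoding")
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  ref_p <- tr(ref_cds)
  alt_p <- tr(alt_cds)
  ref_start <- substr(ref_cds, 1, 3)
  alt_start <- substr(alt_cds, 1, 3)
  if (ref_start != alt_start &&
      !alt_start %in% c("ATG", "GTG", "TTG")) return("start_loss")
  diff <- which(strsplit(ref_p, "")[[1]] != strsplit(alt_p, "")[[1]])
  if (length(diff) == 0) return("synonymous")
  ref_aa <- substr(ref_p, diff, diff)
  alt_aa <- substr(alt_p, diff, diff)
  if (ref_aa != "*" && alt_aa == "*") return("stop_gain")
  if (ref_aa == "*" && alt_aa != "*") return("stop_loss")
  "nonsynonymous"
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUROC by exhaustive concordant-pair counting (ties count one half)
oracle_auroc <- function(scores, labels, positive = "healthy") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Optimal (maximum-cardinality) tolerance matching by exhaustive recursion;
# small inputs only
oracle_best_matching <- function(values, labels, tolerance) {
  hi <- which(labels == "healthy")
  ni <- which(labels == "nonhealthy")
  recurse <- function(h_left, n_left) {
    if (length(h_left) == 0 || length(n_left) == 0) return(0)
    h <- h_left[1]
    best <- recurse(h_left[-1], n_left)  # leave h unmatched
    for (j in seq_along(n_left)) {
      if (abs(values[h] - values[n_left[j]]) <= tolerance)
        best <- max(best, 1 + recurse(h_left[-1], n_left[-j]))
    }
    best
  }
  recurse(hi, ni)
}

# Exact two-sided signed-rank p by sign enumeration (no ties assumed)
oracle_signed_rank <- function(diffs) {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  r <- rank(abs(diffs))
  w_obs <- sum(r[diffs > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
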
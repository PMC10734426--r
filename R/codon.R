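# Coding-effect classification, pN/pS, and codon variant bias
# (stop-gain / start-loss) in SCFA-production genes.
#
# Conventions: SNV positions are 0-based on the scaffold; gene coordinates
# are stored both as GFF3 1-based inclusive (start, end) and internal
# 0-based half-open (start0, end0). Amino acids follow the bacterial code
# (standard amino-acid table; start codons ATG/GTG/TTG).

#' Extract a gene's coding-strand sequence
#'
#' @param gene One-row data.frame with `start0`, `end0`, `strand`,
#'   `scaffold_id` (see [read_gene_annotations()]).
#' @param genomes Named character vector (or `DNAStringSet`) of scaffold
#'   sequences.
#' @return Coding-orientation sequence string (reverse-complemented for
#'   minus-strand genes).
#' @export
gene_sequence <- function(gene, genomes) {
  seqs <- as_seq_chars(genomes)
  sc <- as.character(gene$scaffold_id)
  if (!sc %in% names(seqs)) stop("scaffold not found: ", sc)
  chars <- seqs[[sc]][(gene$start0 + 1):gene$end0]
  if (gene$strand == "-") chars <- revcomp_chars(chars)
  paste(chars, collapse = "")
}

# normalize genomes to a list of character vectors, cached by attribute
as_seq_chars <- function(genomes) {
  if (is.list(genomes) && !is.null(attr(genomes, "snvgmhi_chars")))
    return(genomes)
  if (methods::is(genomes, "DNAStringSet"))
    genomes <- as.character(genomes)
  out <- lapply(genomes, seq_to_chars)
  attr(out, "snvgmhi_chars") <- TRUE
  out
}

classify_codon_change <- function(ref_codon, alt_codon, codon_index) {
  # vectorized over equal-length inputs
  ref_aa <- codon_aa(ref_codon)
  alt_aa <- codon_aa(alt_codon)
  eff <- ifelse(ref_aa == alt_aa, "synonymous", "nonsynonymous")
  eff[ref_aa != "*" & alt_aa == "*"] <- "stop_gain"
  eff[ref_aa == "*" & alt_aa != "*"] <- "stop_loss"
  eff[codon_index == 0 & !(alt_codon %in% START_CODONS)] <- "start_loss"
  eff
}

#' Classify the coding effect of a single SNV within a gene
#'
#' Maps an SNV to its codon under the gene's reading frame and classifies
#' the change as `synonymous`, `nonsynonymous`, `stop_gain`, `stop_loss` or
#' `start_loss` under the bacterial genetic code. For minus-strand genes the
#' alleles are complemented and the position mapped into coding orientation
#' before codon lookup. `start_loss` is any codon-0 change whose alternate
#' codon leaves the start-codon set \{ATG, GTG, TTG\}; `stop_gain` is a sense
#' codon changed to TAA/TAG/TGA.
#'
#' @param gene One-row gene annotation (needs `start0`, `end0`, `strand`,
#'   `scaffold_id`, `gene_id`).
#' @param gene_seq Coding-strand sequence of the gene (string); length must
#'   be divisible by 3.
#' @param position 0-based scaffold position of the SNV.
#' @param ref_base,alt_base Scaffold-strand reference and alternate bases.
#' @return A one-row data.frame (`gene_id`, `codon_index`,
#'   `within_codon_pos`, `ref_codon`, `alt_codon`, `effect`), or effect
#'   `"noncoding"` if the position is outside the gene span.
#' @export
classify_snv_effect <- function(gene, gene_seq, position, ref_base, alt_base) {
  glen <- nchar(gene_seq)
  if (glen %% 3 != 0) stop("gene length not divisible by 3: ", gene$gene_id)
  if (position < gene$start0 || position >= gene$end0) {
    return(data.frame(gene_id = gene$gene_id, codon_index = NA_integer_,
                      within_codon_pos = NA_integer_, ref_codon = NA_character_,
                      alt_codon = NA_character_, effect = "noncoding",
                      stringsAsFactors = FALSE))
  }
  if (gene$strand == "-") {
    offset <- gene$end0 - 1L - position
    cref <- COMPLEMENT[[ref_base]]
    calt <- COMPLEMENT[[alt_base]]
  } else {
    offset <- position - gene$start0
    cref <- ref_base
    calt <- alt_base
  }
  codon_index <- offset %/% 3L
  within <- offset %% 3L
  ref_codon <- substr(gene_seq, codon_index * 3L + 1L, codon_index * 3L + 3L)
  if (substr(ref_codon, within + 1L, within + 1L) != cref)
    stop(sprintf("reference mismatch in gene %s at offset %d: gene has %s, SNV says %s",
                 gene$gene_id, offset,
                 substr(ref_codon, within + 1L, within + 1L), cref))
  alt_codon <- ref_codon
  substr(alt_codon, within + 1L, within + 1L) <- calt
  data.frame(gene_id = gene$gene_id, codon_index = codon_index,
             within_codon_pos = within, ref_codon = ref_codon,
             alt_codon = alt_codon,
             effect = classify_codon_change(ref_codon, alt_codon, codon_index),
             stringsAsFactors = FALSE)
}

#' Classify coding effects for a table of SNVs
#'
#' Vectorized companion to [classify_snv_effect()]: assigns each SNV to the
#' gene containing it (if any) and classifies its coding effect. SNVs outside
#' every annotated CDS, or inside a CDS flagged ineligible for codon
#' analysis, get effect `"noncoding"` / `NA` gene assignment respectively.
#'
#' @param snvs SNV data.frame (`scaffold_id`, `position`, `ref_base`,
#'   `alt_base`, ...).
#' @param genes Gene annotation data.frame (see [read_gene_annotations()]).
#' @param genomes Named scaffold sequences.
#' @return `snvs` with `gene_id`, `codon_index`, `ref_codon`, `alt_codon`
#'   and `effect` columns appended.
#' @export
classify_effects <- function(snvs, genes, genomes) {
  seqs <- as_seq_chars(genomes)
  n <- nrow(snvs)
  gene_id <- rep(NA_character_, n)
  effect <- rep("noncoding", n)
  codon_index <- rep(NA_integer_, n)
  ref_codon <- rep(NA_character_, n)
  alt_codon <- rep(NA_character_, n)
  if (n == 0) {
    return(cbind(snvs, data.frame(gene_id, codon_index, ref_codon,
                                  alt_codon, effect)))
  }
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    idx <- which(snvs$scaffold_id == g$scaffold_id &
                 snvs$position >= g$start0 & snvs$position < g$end0)
    if (length(idx) == 0) next
    gene_id[idx] <- g$gene_id
    if (isTRUE(!g$codon_eligible)) next
    gchars <- seqs[[as.character(g$scaffold_id)]][(g$start0 + 1):g$end0]
    if (g$strand == "-") {
      gchars <- revcomp_chars(gchars)
      off <- g$end0 - 1L - snvs$position[idx]
      cref <- unname(COMPLEMENT[snvs$ref_base[idx]])
      calt <- unname(COMPLEMENT[snvs$alt_base[idx]])
    } else {
      off <- snvs$position[idx] - g$start0
      cref <- snvs$ref_base[idx]
      calt <- snvs$alt_base[idx]
    }
    ci <- off %/% 3L
    wi <- off %% 3L
    if (any(gchars[off + 1L] != cref))
      stop(sprintf("reference mismatch in gene %s at offset(s) %s",
                   g$gene_id,
                   paste(off[gchars[off + 1L] != cref], collapse = ",")))
    rc <- paste0(gchars[ci * 3L + 1L], gchars[ci * 3L + 2L], gchars[ci * 3L + 3L])
    ac <- rc
    substr(ac, wi + 1L, wi + 1L) <- calt  # substr<- vectorizes over start/value
    codon_index[idx] <- ci
    ref_codon[idx] <- rc
    alt_codon[idx] <- ac
    effect[idx] <- classify_codon_change(rc, ac, ci)
  }
  cbind(snvs, data.frame(gene_id = gene_id, codon_index = codon_index,
                         ref_codon = ref_codon, alt_codon = alt_codon,
                         effect = effect, stringsAsFactors = FALSE))
}

#' Expected nonsynonymous/synonymous site counts of a coding sequence
#'
#' Enumerates all nine single-base changes of every codon; each codon
#' position contributes fractional nonsynonymous/synonymous "siteness"
#' summing to 1. Changes that create or destroy a stop codon count as
#' nonsynonymous.
#'
#' @param gene_seq Coding-strand sequence, length divisible by 3.
#' @return Named vector `c(n_sites, s_sites)`; the two always sum to the
#'   gene length.
#' @export
codon_site_counts <- function(gene_seq) {
  chars <- seq_to_chars(gene_seq)
  if (length(chars) %% 3 != 0) stop("gene length not divisible by 3")
  codons <- paste0(chars[c(TRUE, FALSE, FALSE)],
                   chars[c(FALSE, TRUE, FALSE)],
                   chars[c(FALSE, FALSE, TRUE)])
  tab <- codon_siteness_table()
  n <- sum(tab[codons, "n"])
  c(n_sites = n, s_sites = length(chars) - n)
}

# 64-codon lookup of nonsynonymous siteness, built once per session
codon_siteness_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- names(Biostrings::GENETIC_CODE)
    n_frac <- vapply(codons, function(cd) {
      ref_aa <- codon_aa(cd)
      nonsyn <- 0L
      for (p in 1:3) {
        for (b in setdiff(BASES, substr(cd, p, p))) {
          alt <- cd
          substr(alt, p, p) <- b
          if (codon_aa(alt) != ref_aa) nonsyn <- nonsyn + 1L
        }
      }
      nonsyn / 3
    }, numeric(1))
    cache <<- cbind(n = n_frac, s = 3 - n_frac)
    rownames(cache) <<- codons
    cache
  }
})

#' Gene-level pN/pS from observed polymorphic sites
#'
#' The per-site rate of nonsynonymous SNVs (observed nonsynonymous count /
#' expected nonsynonymous sites) over the rate of synonymous SNVs. Site
#' expectations come from [codon_site_counts()]; stop-gain, stop-loss and
#' start-loss changes count as nonsynonymous observations. Only observed
#' polymorphic positions (both alleles present in the sample population)
#' enter the counts -- this is a within-population rate ratio, not a
#' substitution-model dN/dS.
#'
#' @param gene One-row gene annotation.
#' @param gene_seq Coding-strand sequence.
#' @param snvs SNVs falling on this gene's scaffold (any others are
#'   ignored); classified internally.
#' @return One-row data.frame: `gene_id`, `scfa_family`, `n_obs`, `s_obs`,
#'   `n_sites`, `s_sites`, `pn`, `ps`, `pn_ps` (`NA` when `ps` is 0).
#' @export
pn_ps <- function(gene, gene_seq, snvs) {
  sites <- codon_site_counts(gene_seq)
  in_gene <- snvs[snvs$scaffold_id == gene$scaffold_id &
                  snvs$position >= gene$start0 &
                  snvs$position < gene$end0, , drop = FALSE]
  if (nrow(in_gene) > 0) {
    cls <- vapply(seq_len(nrow(in_gene)), function(i)
      classify_snv_effect(gene, gene_seq, in_gene$position[i],
                          in_gene$ref_base[i], in_gene$alt_base[i])$effect,
      character(1))
  } else cls <- character(0)
  n_obs <- sum(cls %in% c("nonsynonymous", "stop_gain", "stop_loss", "start_loss"))
  s_obs <- sum(cls == "synonymous")
  pn <- n_obs / sites[["n_sites"]]
  ps <- s_obs / sites[["s_sites"]]
  data.frame(gene_id = gene$gene_id,
             scfa_family = if ("scfa_family" %in% names(gene))
               gene$scfa_family else NA_character_,
             n_obs = n_obs, s_obs = s_obs,
             n_sites = sites[["n_sites"]], s_sites = sites[["s_sites"]],
             pn = pn, ps = ps,
             pn_ps = if (ps > 0) pn / ps else NA_real_,
             stringsAsFactors = FALSE)
}

#' Per-group codon variant bias of a gene with Fisher's exact test
#'
#' For one gene, counts per host group the individuals with at least one SNV
#' on the gene (`n`) and among them the individuals carrying at least one
#' stop-gain or start-loss change (`carriers`); the codon-bias frequency is
#' `carriers / n`. Group frequencies are compared with a two-sided Fisher's
#' exact test on the 2x2 carrier table.
#'
#' @param effects Classified SNV table (from [classify_effects()]) with a
#'   `sample_id` column.
#' @param gene_id Gene to summarize.
#' @param labels Named vector mapping `sample_id` to
#'   `"healthy"`/`"nonhealthy"`.
#' @return List with `summary` (one row per group: `gene_id`, `group`, `n`,
#'   `carriers`, `frequency`) and `fisher_p` (`NA` if either group has
#'   `n = 0`).
#' @export
codon_bias_frequency <- function(effects, gene_id, labels) {
  on_gene <- effects[!is.na(effects$gene_id) & effects$gene_id == gene_id, ,
                     drop = FALSE]
  bias_eff <- c("stop_gain", "start_loss")
  groups <- c("healthy", "nonhealthy")
  rows <- lapply(groups, function(g) {
    ids <- names(labels)[labels == g]
    sub <- on_gene[on_gene$sample_id %in% ids, , drop = FALSE]
    n <- length(unique(sub$sample_id))
    carriers <- length(unique(sub$sample_id[sub$effect %in% bias_eff]))
    data.frame(gene_id = gene_id, group = g, n = n, carriers = carriers,
               frequency = if (n > 0) carriers / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  fisher_p <- NA_real_
  if (all(summary$n > 0)) {
    tab <- matrix(c(summary$carriers[1], summary$n[1] - summary$carriers[1],
                    summary$carriers[2], summary$n[2] - summary$carriers[2]),
                  nrow = 2, byrow = TRUE)
    fisher_p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  } else {
    message("codon_bias_frequency: a group has no individuals with SNVs on ",
            gene_id, "; Fisher test skipped")
  }
  list(summary = summary, fisher_p = fisher_p)
}

#' Recurrent stop-gain/start-loss variants shared across individuals
#'
#' Lists exact (scaffold, position, ref, alt) stop-gain or start-loss
#' changes observed in at least `min_individuals` distinct samples, sorted
#' by the number of individuals (descending) then position (ascending).
#'
#' @param effects Classified SNV table with `sample_id`.
#' @param min_individuals Minimum distinct carriers (default 3).
#' @return data.frame: `scaffold_id`, `position`, `ref_base`, `alt_base`,
#'   `ref_codon`, `alt_codon`, `effect`, `gene_id`, `n_individuals`.
#' @export
recurrent_codon_variants <- function(effects, min_individuals = 3L) {
  stopifnot(min_individuals >= 1)
  hits <- effects[effects$effect %in% c("stop_gain", "start_loss"), ,
                  drop = FALSE]
  if (nrow(hits) == 0) return(empty_recurrent_df())
  key <- paste(hits$scaffold_id, hits$position, hits$ref_base, hits$alt_base,
               sep = "\r")
  counts <- tapply(hits$sample_id, key, function(x) length(unique(x)))
  keep <- names(counts)[counts >= min_individuals]
  if (length(keep) == 0) return(empty_recurrent_df())
  first <- hits[!duplicated(key) & key %in% keep, , drop = FALSE]
  first_key <- paste(first$scaffold_id, first$position, first$ref_base,
                     first$alt_base, sep = "\r")
  out <- data.frame(scaffold_id = first$scaffold_id,
                    position = first$position,
                    ref_base = first$ref_base, alt_base = first$alt_base,
                    ref_codon = first$ref_codon, alt_codon = first$alt_codon,
                    effect = first$effect, gene_id = first$gene_id,
                    n_individuals = as.integer(counts[first_key]),
                    stringsAsFactors = FALSE)
  out[order(-out$n_individuals, out$position), , drop = FALSE]
}

empty_recurrent_df <- function() {
  data.frame(scaffold_id = character(0), position = integer(0),
              ref_base = character(0), alt_base = character(0),
              ref_codon = character(0), alt_codon = character(0),
              effect = character(0), gene_id = character(0),
              n_individuals = integer(0), stringsAsFactors = FALSE)
}

# Enumerate all (offset, coding alt) pairs in a coding sequence that create
# a stop-gain or start-loss. Used by the cohort simulator to plant codon
# variant bias. Offsets are 0-based in coding orientation.
stop_start_candidates <- function(gene_seq) {
  chars <- seq_to_chars(gene_seq)
  ncod <- length(chars) %/% 3L
  codons <- paste0(chars[c(TRUE, FALSE, FALSE)],
                   chars[c(FALSE, TRUE, FALSE)],
                   chars[c(FALSE, FALSE, TRUE)])
  out_off <- integer(0); out_alt <- character(0); out_eff <- character(0)
  for (wi in 0:2) {
    ref_b <- chars[seq(wi + 1L, by = 3L, length.out = ncod)]
    for (b in BASES) {
      ok <- ref_b != b
      alt_codons <- codons
      substr(alt_codons, wi + 1L, wi + 1L) <- b
      eff <- classify_codon_change(codons, alt_codons, seq_len(ncod) - 1L)
      sel <- ok & eff %in% c("stop_gain", "start_loss")
      if (any(sel)) {
        ci <- which(sel) - 1L
        out_off <- c(out_off, ci * 3L + wi)
        out_alt <- c(out_alt, rep(b, sum(sel)))
        out_eff <- c(out_eff, eff[sel])
      }
    }
  }
  data.frame(offset = out_off, alt = out_alt, effect = out_eff,
             stringsAsFactors = FALSE)
}
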
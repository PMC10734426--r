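# Readers and writers for the external file formats: sample metadata TSV,
# SNV tables and genome-info tables in the strain-profiler TSV dialect,
# GFF3 gene annotations, FASTA scaffolds, and feature-table TSVs.
#
# Coordinates: GFF3 is 1-based inclusive on disk; SNV tables carry 0-based
# positions (matching the upstream SNV caller's output). Both are converted
# exactly once at ingest to the internal convention -- 0-based half-open
# [start0, end0) for intervals, 0-based points for SNVs.

#' Column-name schema for SNV tables
#'
#' The SNV-table reader maps on-disk column names to the internal canonical
#' names through this registry, so output from other profiler versions can
#' be ingested by overriding individual entries.
#'
#' @param genome,scaffold,position,ref,alt,ref_freq,alt_freq,coverage
#'   On-disk column names.
#' @return Named character vector (canonical name -> file column).
#' @export
snv_schema <- function(genome = "genome", scaffold = "scaffold",
                       position = "position", ref = "ref_base",
                       alt = "var_base", ref_freq = "ref_freq",
                       alt_freq = "var_freq",
                       coverage = "position_coverage") {
  c(genome_id = genome, scaffold_id = scaffold, position = position,
    ref_base = ref, alt_base = alt, ref_freq = ref_freq,
    alt_freq = alt_freq, site_coverage = coverage)
}

read_tsv_file <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "")
}

write_tsv_file <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with header columns `sample_id`, `cohort`, `phenotype`,
#'   `health_status`, `depth_gb`. Unknown columns are preserved.
#' @return data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  md <- read_tsv_file(path)
  required <- c("sample_id", "cohort", "phenotype", "health_status", "depth_gb")
  missing <- setdiff(required, names(md))
  if (length(missing) > 0)
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  if (any(is.na(md$depth_gb)) || any(md$depth_gb <= 0))
    stop("metadata depth_gb must be > 0 for every sample")
  if (!all(md$health_status %in% c("healthy", "nonhealthy")))
    stop("health_status must be 'healthy' or 'nonhealthy' for every sample")
  md
}

#' Write sample metadata
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path Output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  write_tsv_file(metadata, path)
}

#' Read a per-sample SNV table
#'
#' Reads one sample's SNV calls, renames columns through the schema
#' registry, drops records below the coverage floor and rejects records with
#' non-ACGT alleles (with a warning).
#'
#' @param path SNV TSV.
#' @param min_cov Minimum site coverage; records below it are dropped and
#'   the drop count reported via `message()`.
#' @param schema Column registry from [snv_schema()].
#' @return data.frame with canonical columns `genome_id`, `scaffold_id`,
#'   `position` (0-based), `ref_base`, `alt_base`, `ref_freq`, `alt_freq`,
#'   `site_coverage`.
#' @export
read_snv_table <- function(path, min_cov = 5L, schema = snv_schema()) {
  raw <- tryCatch(read_tsv_file(path), error = function(e)
    stop("failed to parse SNV table ", path, ": ", conditionMessage(e)))
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing) > 0)
    stop("SNV table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  snv <- raw[, unname(schema)]
  names(snv) <- names(schema)
  if (nrow(snv) == 0) return(snv)
  bad_pos <- which(is.na(snv$position))
  if (length(bad_pos) > 0)
    stop("unparseable position in ", path, " at data line(s): ",
         paste(bad_pos, collapse = ", "))
  bad <- !(snv$ref_base %in% BASES) | !(snv$alt_base %in% BASES)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-ACGT alleles rejected in ", path)
    snv <- snv[!bad, , drop = FALSE]
  }
  low <- snv$site_coverage < min_cov
  if (any(low))
    message("read_snv_table: dropped ", sum(low),
            " record(s) below min_cov=", min_cov, " in ", basename(path))
  snv[!low, , drop = FALSE]
}

#' Write a per-sample SNV table
#' @param snv Canonical SNV data.frame.
#' @param path Output TSV path.
#' @param schema Column registry; on-disk names are taken from it.
#' @export
write_snv_table <- function(snv, path, schema = snv_schema()) {
  out <- snv[, names(schema)]
  names(out) <- unname(schema)
  write_tsv_file(out, path)
}

#' Read a per-sample genome-info table
#'
#' Per mutated genome: length, mean coverage, breadth at minimum coverage,
#' nucleotide diversity, and the count of read pairs passing the pairing
#' filter (the sequence-abundance numerator).
#'
#' @param path Genome-info TSV with columns `genome`, `length`, `coverage`,
#'   `breadth_minCov`, `nucl_diversity`, `filtered_read_pairs`.
#' @return data.frame with canonical columns `genome_id`, `g_len`,
#'   `coverage`, `breadth_minCov`, `nucleotide_diversity`,
#'   `filtered_read_pairs`.
#' @export
read_genome_info <- function(path) {
  raw <- read_tsv_file(path)
  cols <- c(genome_id = "genome", g_len = "length", coverage = "coverage",
            breadth_minCov = "breadth_minCov",
            nucleotide_diversity = "nucl_diversity",
            filtered_read_pairs = "filtered_read_pairs")
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing) > 0)
    stop("genome info ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  gi <- raw[, unname(cols)]
  names(gi) <- names(cols)
  if (any(gi$g_len <= 0)) stop("genome length must be > 0 in ", path)
  if (any(gi$breadth_minCov < 0 | gi$breadth_minCov > 1))
    stop("breadth_minCov must lie in [0, 1] in ", path)
  if (any(gi$filtered_read_pairs < 0))
    stop("filtered_read_pairs must be >= 0 in ", path)
  gi
}

#' Write a per-sample genome-info table
#' @param gi Canonical genome-info data.frame.
#' @param path Output TSV path.
#' @export
write_genome_info <- function(gi, path) {
  out <- gi[, c("genome_id", "g_len", "coverage", "breadth_minCov",
                "nucleotide_diversity", "filtered_read_pairs")]
  names(out) <- c("genome", "length", "coverage", "breadth_minCov",
                  "nucl_diversity", "filtered_read_pairs")
  write_tsv_file(out, path)
}

#' Read CDS gene annotations from GFF3
#'
#' Keeps CDS features; coordinates stay 1-based inclusive in `start`/`end`
#' as in GFF3 and are additionally exposed 0-based half-open as
#' `start0`/`end0` (the internal convention). CDS whose length is not
#' divisible by 3 are kept but flagged ineligible for codon analysis.
#'
#' @param path GFF3 file; CDS attributes may carry `ID` (gene id),
#'   `genome_id` and `scfa_family`.
#' @return data.frame: `gene_id`, `genome_id`, `scaffold_id`, `start`,
#'   `end`, `start0`, `end0`, `strand`, `scfa_family`, `codon_eligible`.
#' @export
read_gene_annotations <- function(path) {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  gff <- gff[gff$type == "CDS", , drop = FALSE]
  attr_field <- function(attrs, key) {
    pat <- paste0("(^|;)", key, "=([^;]*)")
    vapply(attrs, function(a) {
      m <- regmatches(a, regexec(pat, a))[[1]]
      if (length(m) >= 3) m[3] else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }
  gene_id <- attr_field(gff$attributes, "ID")
  genome_id <- attr_field(gff$attributes, "genome_id")
  scfa <- attr_field(gff$attributes, "scfa_family")
  scfa[is.na(scfa)] <- "none"
  if (any(is.na(gene_id)))
    gene_id[is.na(gene_id)] <- sprintf("cds_%d", which(is.na(gene_id)))
  out <- data.frame(gene_id = gene_id,
                    genome_id = ifelse(is.na(genome_id),
                                       as.character(gff$seqid), genome_id),
                    scaffold_id = as.character(gff$seqid),
                    start = gff$start, end = gff$end,
                    start0 = gff$start - 1L, end0 = gff$end,
                    strand = as.character(gff$strand),
                    scfa_family = scfa,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("GFF3 CDS with start > end in ", path)
  out$codon_eligible <- (out$end - out$start + 1L) %% 3L == 0L
  if (any(!out$codon_eligible))
    message("read_gene_annotations: ", sum(!out$codon_eligible),
            " CDS flagged ineligible for codon analysis (length not ",
            "divisible by 3)")
  out
}

#' Write CDS gene annotations as GFF3
#' @param genes Gene annotation data.frame (1-based `start`/`end`).
#' @param path Output path.
#' @export
write_gene_annotations <- function(genes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- sprintf("ID=%s;genome_id=%s;scfa_family=%s",
                   genes$gene_id, genes$genome_id, genes$scfa_family)
  lines <- paste(genes$scaffold_id, "snvgmhi", "CDS", genes$start, genes$end,
                 ".", genes$strand, "0", attrs, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a feature table
#'
#' Samples as rows, features as columns; the feature kind is recorded in a
#' leading `#`-comment so a re-read table keeps its semantics.
#'
#' @param table A `feature_table` (see [build_feature_table()]).
#' @param path Output TSV path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) == 0 || ncol(table$values) == 0)
    stop("refusing to write an empty feature table")
  df <- data.frame(sample_id = rownames(table$values),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path, comment = paste0("kind: ", table$kind))
}

#' Read a feature table written by [write_feature_table()]
#' @param path Feature-table TSV.
#' @return A `feature_table` object.
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1)
  kind <- sub("^#\\s*kind:\\s*", "", first)
  if (identical(kind, first))
    stop("feature table ", path, " lacks the '# kind:' header comment")
  df <- read_tsv_file(path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  new_feature_table(values, kind)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the exact file set the ingest functions read: `metadata.tsv`,
#' `genomes.fasta`, `genes.gff3`, `snv/<sample>.tsv`,
#' `genome_info/<sample>.tsv`, plus the generator's ground truth
#' (`truth_markers.tsv`, `truth_planted.tsv`, `truth_windows.tsv`).
#'
#' @param cohort A `snv_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "snv_cohort"))
  dir.create(file.path(dir, "snv"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genome_info"), showWarnings = FALSE)
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$genomes),
                              file.path(dir, "genomes.fasta"))
  write_gene_annotations(cohort$genes, file.path(dir, "genes.gff3"))
  for (sid in cohort$metadata$sample_id) {
    write_snv_table(cohort$snv[cohort$snv$sample_id == sid,
                               setdiff(names(cohort$snv), "sample_id")],
                    file.path(dir, "snv", paste0(sid, ".tsv")))
    write_genome_info(cohort$genome_info[cohort$genome_info$sample_id == sid,
                                         , drop = FALSE],
                      file.path(dir, "genome_info", paste0(sid, ".tsv")))
  }
  write_tsv_file(cohort$truth$markers, file.path(dir, "truth_markers.tsv"))
  write_tsv_file(cohort$truth$planted, file.path(dir, "truth_planted.tsv"))
  write_tsv_file(cohort$truth$windows, file.path(dir, "truth_windows.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param min_cov Coverage floor passed to [read_snv_table()].
#' @return A `snv_cohort` list (without ground truth unless present on
#'   disk).
#' @export
read_cohort <- function(dir, min_cov = 5L) {
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  genomes <- as.character(Biostrings::readDNAStringSet(
    file.path(dir, "genomes.fasta")))
  genes <- read_gene_annotations(file.path(dir, "genes.gff3"))
  snv_list <- lapply(metadata$sample_id, function(sid) {
    tab <- read_snv_table(file.path(dir, "snv", paste0(sid, ".tsv")),
                          min_cov = min_cov)
    if (nrow(tab) > 0) cbind(sample_id = sid, tab) else NULL
  })
  gi_list <- lapply(metadata$sample_id, function(sid) {
    gi <- read_genome_info(file.path(dir, "genome_info", paste0(sid, ".tsv")))
    if (nrow(gi) > 0) cbind(sample_id = sid, gi) else NULL
  })
  truth <- NULL
  if (file.exists(file.path(dir, "truth_markers.tsv"))) {
    truth <- list(markers = read_tsv_file(file.path(dir, "truth_markers.tsv")),
                  planted = read_tsv_file(file.path(dir, "truth_planted.tsv")),
                  windows = read_tsv_file(file.path(dir, "truth_windows.tsv")))
  }
  structure(list(metadata = metadata,
                 snv = do.call(rbind, snv_list),
                 genome_info = do.call(rbind, gi_list),
                 genomes = genomes, genes = genes, truth = truth),
            class = "snv_cohort")
}

#' @export
print.snv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic SNV cohort: %d samples (%d healthy / %d nonhealthy)\n",
              nrow(x$metadata), sum(x$metadata$health_status == "healthy"),
              sum(x$metadata$health_status == "nonhealthy")))
  cat(sprintf("  %d SNV records across %d mutated-genome observations\n",
              nrow(x$snv), nrow(x$genome_info)))
  cat(sprintf("  %d reference genomes, %d annotated genes\n",
              length(x$genomes), nrow(x$genes)))
  invisible(x)
}
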
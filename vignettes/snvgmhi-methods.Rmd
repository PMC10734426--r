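---
title: "Strain-resolved SNV profiling and health indices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-resolved SNV profiling and health indices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvgmhi)
```

## The problem

Most gut-microbiome disease studies compare species *abundances* between
healthy and diseased hosts. A complementary information layer is the
within-species genetic variation of resident strains: single-nucleotide
variants (SNVs) called by mapping metagenomic reads against reference
genomes. `snvgmhi` implements a cross-cohort analysis of such SNV profiles:
per-genome variation metrics, mutation-spectrum (variant-type) bias,
codon-level damage to short-chain fatty acid (SCFA) production genes, and
health indices built from SNV-derived feature tables. The package consumes
the *output* of a strain-resolved SNV caller (per-sample SNV tables and
genome-coverage summaries in a TSV dialect, plus GFF3 annotations and FASTA
genomes); read mapping and SNV calling themselves are out of scope.

## Core quantities

**SNV rate.** Raw SNV counts are incomparable across genomes and samples
because sequencing depth and genome coverage vary. The per-genome rate is

$$\mathrm{SNV\ rate} = \frac{\mathrm{SNV\ number}}
{g_{\mathrm{len}} \times \mathrm{breadth}_{\mathrm{minCov}}},$$

the fraction of *SNV-callable* bases that actually carry an SNV, where
`breadth_minCov` is the fraction of the genome covered at or above the
SNV-calling coverage floor (default `min_cov = 5`). `snv_rate()` refuses
zero breadth: a genome with no callable bases has an undefined rate and is
excluded.

**Depth normalization.** Per-sample totals (mutated genomes, SNV counts)
scale almost linearly with sequencing throughput, so
`normalize_by_depth()` divides by depth in gigabases before any
between-sample comparison.

**Nucleotide diversity.** Per variant site $\pi = 1 - \sum_i p_i^2$ over
allele frequencies; the genome value averages over all callable sites, with
monomorphic sites contributing zero. Averaging over variant sites only is a
different convention; the package exposes the callable-site denominator
directly (`n_sites`), so callers can use either.

**Variant-type profile.** Each SNV maps to one of six strand-complement
collapsed base-change classes (`A>C|T>G`, `A>G|T>C`, `A>T|T>A`, `C>A|G>T`,
`C>G|G>C`, `C>T|G>A`); per-sample class proportions form the
mutation-spectrum profile.

**Coding effects.** `classify_snv_effect()` maps an SNV into its codon
under the gene's reading frame (reverse-complementing for minus-strand
genes) and classifies it under the bacterial genetic code (translation
table 11): `synonymous`, `nonsynonymous`, `stop_gain` (sense codon to
TAA/TAG/TGA), `stop_loss`, or `start_loss`. *Start loss* is defined as any
codon-0 change whose alternate codon leaves the start-codon set
\{ATG, GTG, TTG\} — the source description ("the start codon is
inactivated") does not enumerate the set, so the standard bacterial
initiation codons are used. "Codon variant bias" counts stop-gain plus
start-loss; stop-loss is classified but reported separately.

**pN/pS.** A within-population rate ratio, not a substitution-model dN/dS:
expected nonsynonymous/synonymous site counts come from enumerating all
nine single-base changes of every codon (each codon position contributes
siteness summing to one; stop-affecting changes count as nonsynonymous),
and observed polymorphic SNVs are divided by those site counts. Only
positions where both alleles are observed enter the counts.

**Codon-bias frequency.** For a gene and host group, the denominator `n`
is the number of individuals with at least one SNV on the gene and the
numerator the number of those carrying at least one stop-gain/start-loss;
groups are compared by a two-sided Fisher exact test. An individual is a
carrier if *any* detected allele qualifies; a majority-allele gate would be
stricter and can be imposed upstream by filtering on `alt_freq`.

## The health indices

Three feature tables are built per cohort (samples × genomes): sequence
abundance (read pairs passing the pairing filter, normalized within
sample), SNV rate, and SCFA-SNV frequency (SNVs in a genome's SCFA genes
per callable SCFA base; the alternative "fraction of the genome's SNVs in
SCFA genes" is available behind the `denominator` flag). Features below 10%
prevalence are dropped by default (30% for the detailed strain-level
analyses).

Marker selection (`select_markers()`): per-feature two-sided Wilcoxon
rank-sum tests, Benjamini–Hochberg correction, retention at `q < 0.05`.
Abundance tables are CLR-transformed first (compositional data); zeros are
replaced by half the sample's smallest positive value. Direction is the
sign of the median group difference; when both medians are zero (common for
zero-inflated features that are nonetheless strongly significant) the mean
difference breaks the tie.

For a sample with marker sets $M_H$ (health-enriched) and $M_N$
(nonhealthy-enriched): richness $H_r, N_r$ counts markers with a positive
value, Shannon diversity $H_s, N_s$ is computed over the marker sub-vector
renormalized to proportions (natural log). Population constants $H_p, N_p$
are the median richness of the top `ceiling(0.01 n)` samples ranked by that
same richness — the ranking variable is not stated in the source
description; ranking by the richness itself is the most literal reading and
matches the original abundance-based index. Then

$$\psi_H = \frac{H_r}{H_p} H_s, \qquad
  \psi_N = \frac{N_r}{N_p} N_s, \qquad
  \mathrm{GMHI} = \log_{10}\frac{\psi_H + \varepsilon}{\psi_N + \varepsilon},$$

with $\varepsilon = 10^{-5}$ keeping samples with one empty marker side
finite ($\varepsilon$ is configurable; the defining ratio is silent about
$\psi = 0$). Raw values — not CLR-transformed ones — feed the summaries;
the transform is applied "prior to statistical tests" only. Swapping
$M_H \leftrightarrow M_N$ with $H_p = N_p$ negates the index exactly.
`gmhi_fit()` freezes markers and constants on a discovery table;
`predict()` scores external tables with them unchanged, which is the
external-validation protocol. Evaluation is by the tie-corrected
Mann–Whitney AUROC plus overall and per-cohort Wilcoxon tests.

## The synthetic cohort generator

No sequence data ship with the package; `simulate_cohort()` emulates the
post-SNV-calling data layer with planted, recoverable structure. Its
defaults are the package's study conditions:

* **Scale.** 100 + 100 samples, 60 reference genomes of 20 kb with three
  SCFA-family genes each (families cycle through ack, buk, ydiF, atoD,
  atoA, ctfA, ctfB, BcAt, scpC). Real meta-analyses use thousands of
  samples and Mb-scale genomes; these sizes keep a full pipeline run in
  seconds while leaving every test statistically powered.
* **Depth.** Log-normal(ln 5, 0.4) gigabases, echoing the 1.6–11 Gb range
  of published stool metagenomes.
* **Mutated genomes.** Poisson(λ · depth) with λ 3.6/Gb (healthy) vs
  3.2/Gb (nonhealthy): healthy hosts carry more SNV-carrying strains, at
  roughly the 19.5 vs 17.4 per-sample means reported for real cohorts.
* **SNV rates.** Baseline 2.1e-3 vs 1.95e-3 SNVs per callable base
  (healthy slightly higher, matching the direction of real normalized SNV
  counts). Twelve marker genomes (20%) get a 1.7× rate shift in their
  enriched group, half per direction.
* **Marker presence.** Marker genomes carry twice the inclusion weight of
  background genomes (marker strains are the prevalent ones — they always
  pass the 30% prevalence filter) and a further 1.6× weight in their
  enriched group, because real marker strains differ in prevalence between
  host groups, not only in value when present. The rate and presence
  effects were calibrated once, jointly, so the SNV-rate index reaches
  AUROC ≈ 0.75 at n = 100 + 100 — mirroring the discovery-scale separation
  of real data without claiming its exact value — and are fixed defaults.
* **Variant types.** Group-specific probability vectors over the six
  collapsed classes (healthy enriched in `A>G|T>C` and `A>T|T>A`,
  nonhealthy in `C>G|G>C`). Simulated genomes have uniform base
  composition, so each vector's A/T-reference and C/G-reference triplets
  must sum to 0.5 apiece for empirical class frequencies to converge to the
  configured vector; `sim_config()` warns otherwise.
* **Codon bias.** An SNV landing in an SCFA gene is relocated, with
  probability 0.04 (healthy) vs 0.12 (nonhealthy), to a callable site that
  creates a stop-gain or start-loss. The 3× ratio echoes the direction and
  rough magnitude of reported carrier-frequency contrasts (e.g. 8.98% vs
  4.37%), with absolute levels chosen once so a two-group Fisher test has
  power at 200 samples.
* **Coverage.** breadth_minCov ~ Beta(8, 4) (mean ≈ 0.67, near the
  two-thirds well-covered fraction seen in real genome sets); the callable
  region is a wrap-around window of breadth × genome-length bases, recorded
  in the ground truth so tests can verify every SNV lies inside it.

All draws flow from a single seeded generator: one integer reproduces a
cohort byte for byte. `sample_seed` re-seeds only the sample-level draws,
producing an external-validation cohort that shares the discovery cohort's
genomes and marker structure. The ground truth records marker identities
and directions, every planted codon-bias event, and the coverage windows.

What the generator does **not** emulate: real taxonomy and genome sizes,
linkage between nearby SNVs, strain replacement over time, compositional
correlation structure between genomes, multi-allelic sites, and
batch/cohort effects beyond the cohort label. Passing tests therefore
demonstrate that the pipeline recovers the structure it is designed to
detect at realistic effect sizes — not that real data contain that
structure.

## Numerical and design choices

* Coordinates are converted exactly once at ingest: GFF3 is 1-based
  inclusive on disk, SNV positions 0-based (the upstream caller's
  convention); everything internal is 0-based half-open.
* Shannon uses the natural log (base unstated in the source description).
* The alpha-diversity matching of healthy/nonhealthy pairs
  (`match_pairs()`) is greedy nearest-difference without replacement —
  the matching algorithm is not specified in the source; on small inputs
  the greedy matching is verified to sit within one pair of the exhaustive
  optimum. The symmetric criterion |Δ| ≤ tolerance is the default, with the
  one-sided variant (nonhealthy higher by at most the tolerance) behind a
  flag.
* The signed-rank test uses the exact null for n ≤ 25 without ties, the
  continuity-corrected normal approximation otherwise.
* PERMANOVA is delegated to `vegan::adonis2` (999 permutations by
  default); the reported `r2` is the among-group fraction of total sum of
  squares, which is what ordination reports that print "R" usually mean.
* PCoA reports negative eigenvalues rather than clipping them; explained
  variance is computed over the positive part.
* Fisher tests, Wilcoxon tests and BH correction are delegated to base R;
  the package's own implementations of the rank AUROC, diversity indices
  and dissimilarities are cross-checked against vegan/pROC and exhaustive
  enumeration in the test suite.
* Constant features get p = 1 in marker selection rather than an error;
  all-zero samples are refused by the CLR with the sample named.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline on ten
default-scale cohorts (200 samples, 60 genomes each; ten fixed seeds for
tests, seeds derived from `--seed` for the script), plus smaller cohorts
for unit tests. Null calibrations use 200 replicate PERMANOVAs at 99
permutations and 50 label shuffles for marker selection. These sizes were
chosen so the complete suite runs in minutes on one CPU while every
statistical claim retains clear power.

## Known limitations

* pN/pS is undefined when a gene has no synonymous observations; such
  genes are flagged (`pn_ps = NA`) and must be excluded from comparisons
  rather than imputed.
* Multi-allelic sites are handled as independent biallelic records; allele
  frequencies at a site may sum to less than one and the remainder is
  treated as unobserved.
* The abundance-kind feature table renormalizes rows after prevalence
  filtering, so "abundance" is relative to the retained genome panel.
* Marker selection power on zero-inflated features comes partly from
  presence differences; with very small groups the BH threshold is
  conservative and recovery degrades before false discoveries rise.
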
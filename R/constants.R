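# Shared constants: bases, genetic code, collapsed variant-type classes.

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Bacterial/archaeal code: amino-acid assignments equal the standard table;
# the alternative initiation codons are what differ.
STOP_CODONS  <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

# SCFA-production gene families tracked by the codon-bias analysis.
SCFA_FAMILIES <- c("ack", "buk", "ydiF", "atoD", "atoA",
                   "ctfA", "ctfB", "BcAt", "scpC")

# The six strand-complement-collapsed base-change classes, fixed order.
VARIANT_CLASSES <- c("A>C|T>G", "A>G|T>C", "A>T|T>A",
                     "C>A|G>T", "C>G|G>C", "C>T|G>A")

# Map every ordered (ref, alt) pair to its collapsed class.
.variant_class_map <- local({
  m <- character(0)
  for (ref in BASES) {
    for (alt in setdiff(BASES, ref)) {
      cref <- ref
      calt <- alt
      if (ref %in% c("G", "T")) {
        cref <- COMPLEMENT[[ref]]
        calt <- COMPLEMENT[[alt]]
      }
      lab <- sprintf("%s>%s|%s>%s", cref, calt,
                     COMPLEMENT[[cref]], COMPLEMENT[[calt]])
      m[paste0(ref, alt)] <- lab
    }
  }
  m
})

#' Collapsed variant-type class of a base change
#'
#' Maps an ordered reference/alternate base pair to one of the six
#' strand-complement-collapsed variant classes (e.g. `G>C` and `C>G` both
#' collapse to `C>G|G>C`).
#'
#' @param ref,alt Character vectors of single bases in `A`, `C`, `G`, `T`;
#'   `ref[i] != alt[i]`.
#' @return Character vector of class labels (see [VARIANT_CLASSES] ordering
#'   in [variant_type_profile()]).
#' @examples
#' variant_class("G", "C")  # "C>G|G>C"
#' variant_class("T", "C")  # "A>G|T>C"
#' @export
variant_class <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  bad <- !(ref %in% BASES) | !(alt %in% BASES)
  if (any(bad)) stop("ref/alt must be single bases in A,C,G,T")
  if (any(ref == alt)) stop("ref and alt must differ")
  unname(.variant_class_map[paste0(ref, alt)])
}

# translate a codon (character of length 3 or 3-vector) to an amino acid,
# "*" for stops
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

revcomp_chars <- function(chars) {
  rev(unname(COMPLEMENT[chars]))
}

seq_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
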
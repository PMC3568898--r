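# Shared nucleotide / codon utilities used by the divergence, codon-evolution
# splice-site and simulation modules.

BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

# Standard genetic code, keyed by codon; "*" marks a stop.
genetic_code <- function() Biostrings::GENETIC_CODE

codon_table_env <- new.env(parent = emptyenv())

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

stop_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc == "*"]
}

translate_codons <- function(codons) {
  unname(genetic_code()[codons])
}

is_stop_codon <- function(codons) {
  translate_codons(codons) == "*"
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T, case preserved for
#'   soft-masked lowercase).
#' @return The reverse complement of each element.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Split a DNA string into codons; length must be a multiple of 3.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length is not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Classify a base substitution as transition or transversion
#'
#' A<->G and C<->T exchanges (purine-purine, pyrimidine-pyrimidine) are
#' transitions; all other differing pairs are transversions.
#'
#' @param base_x,base_y Character vectors of bases (`A`, `C`, `G`, `T`);
#'   `NA` marks a missing state.
#' @return Character vector with values `"transition"`, `"transversion"`,
#'   `"identical"`, or `NA` where either base is missing.
#' @examples
#' classify_substitution(c("A", "A", "C"), c("G", "T", "C"))
#' @export
classify_substitution <- function(base_x, base_y) {
  x <- toupper(base_x); y <- toupper(base_y)
  bad <- (!x %in% BASES) | (!y %in% BASES)
  out <- ifelse(x == y, "identical",
                ifelse((x %in% PURINES) == (y %in% PURINES),
                       "transition", "transversion"))
  out[bad] <- NA_character_
  out
}

# Hamming-differing positions between two codons (3-character strings).
codon_diff_positions <- function(c1, c2) {
  which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
}

# Replace one position of a codon.
codon_set <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}
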
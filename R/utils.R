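# Shared internal helpers.

# The 20 standard amino acids, one-letter.
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Additional letters tolerated in input sequences (ambiguity codes and
# selenocysteine). 'U' is deliberately NOT treated as cysteine.
AA_EXTRA <- c("X", "B", "Z", "U")

# One-letter -> three-letter residue names (PDB style), via Biostrings.
aa_three <- function(x) {
  code <- Biostrings::AMINO_ACID_CODE
  out <- toupper(unname(code[x]))
  out[is.na(out)] <- "UNK"
  out
}

# Three-letter -> one-letter; unknown residues become "X".
aa_one <- function(x) {
  code <- Biostrings::AMINO_ACID_CODE
  rev_code <- setNames(names(code), toupper(code))
  out <- unname(rev_code[toupper(x)])
  out[is.na(out) | nchar(out) != 1L] <- "X"
  out
}

# Element symbols treated as metals when found in HETATM records.
METAL_ELEMENTS <- c("LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA",
                    "MN", "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "MO",
                    "W", "V", "CR", "AL", "PT", "PB", "AU", "AG")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Euclidean distance matrix for an n x 3 coordinate matrix.
coord_dist <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s", name, format(min)))
  }
  invisible(x)
}
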
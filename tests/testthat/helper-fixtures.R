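# Fixtures built in code: tiny hand-placed structures and proteomes.

# A structure chain with residues on given coordinates; cys_at marks CYS.
make_chain_structure <- function(coords, cys_at = integer(), chain = "A",
                                 structure_id = "TST1", ssbond = NULL,
                                 link_cys = NULL, metals = NULL,
                                 aa_other = "A") {
  n <- nrow(coords)
  aa <- rep(aa_other, n)
  aa[cys_at] <- "C"
  residues <- tibble::tibble(
    chain = chain, resno = seq_len(n), icode = " ",
    resname = ifelse(aa == "C", "CYS",
                     toupper(unname(Biostrings::AMINO_ACID_CODE[aa]))),
    aa = aa,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  cysmapr:::new_pdb_structure(structure_id, residues, ssbond, link_cys, metals)
}

# Straight-line CA trace: residue i at (step * (i-1), 0, 0).
line_coords <- function(n, step = 3.8) {
  cbind(step * (seq_len(n) - 1), 0, 0)
}

# A small proteome tibble from bare sequences.
make_proteome <- function(seqs, ids = sprintf("P%03d", seq_along(seqs)),
                          organism = "test organism") {
  cysmapr:::new_proteome(ids, organism, seqs)
}

# Identity alignment of a query against a chain (sequences equal).
self_alignment <- function(chain_struct, chain = "A") {
  ch <- get_chain(chain_struct, chain)
  global_realign(ch$sequence, ch$sequence, query_id = "self",
                 target_id = paste0(ch$structure_id, "_", chain))
}

# Text of a minimal hand-written PDB entry (3 residues + SSBOND fixture).
minimal_pdb_text <- function() {
  c(sprintf("%-62s%4s", "HEADER    TEST PROTEIN", "1ABC"),
    "SSBOND   1 CYS A    1    CYS A    3                                                    ",
    "ATOM      1  CA  CYS A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  CYS A   3       5.500   0.000   0.000  1.00  0.00           C",
    "END")
}
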
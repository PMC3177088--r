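#' Read a structure file (PDB format)
#'
#' Parses the fixed-column PDB dialect into a `pdb_structure` object:
#' per-residue C-alpha coordinates from `ATOM` records (first alternate
#' location kept), disulfide declarations from `SSBOND`, covalent/metal
#' linkages from `LINK` (cysteines appearing there are flagged, since they
#' typically coordinate metals rather than form disulfides), and metal atoms
#' from `HETATM` element symbols.
#'
#' @param path Path to a PDB file with at least one `ATOM` record.
#' @return An object of class `pdb_structure`: a list with
#'   \describe{
#'     \item{structure_id}{4-character entry id (from `HEADER` or the file
#'       name).}
#'     \item{residues}{Tibble, one row per residue per chain: `chain`,
#'       `resno` (author numbering), `icode`, `resname`, `aa` (one-letter),
#'       `x`, `y`, `z` (C-alpha, `NA` if the residue has no CA atom).}
#'     \item{ssbond}{Tibble of declared disulfides: `chain1`, `resno1`,
#'       `chain2`, `resno2`.}
#'     \item{link_cys}{Tibble of cysteines in `LINK` records: `chain`,
#'       `resno`.}
#'     \item{metals}{Tibble of metal HETATM atoms: `element`, `x`, `y`, `z`.}
#'   }
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  parse_pdb_lines(readLines(path, warn = FALSE), source = path)
}

# Workhorse shared by read_structure() and in-memory round trips.
parse_pdb_lines <- function(lines, source = "<text>") {
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec == "ATOM  ")
  if (length(atom_idx) == 0L) abort(sprintf("%s: no ATOM records", source))

  structure_id <- NA_character_
  hdr <- which(rec == "HEADER")
  if (length(hdr) > 0L && nchar(lines[hdr[1L]]) >= 66L) {
    structure_id <- stringr::str_trim(substr(lines[hdr[1L]], 63, 66))
  }
  if (is.na(structure_id) || !nzchar(structure_id)) {
    structure_id <- toupper(sub("\\.[^.]*$", "", basename(source)))
  }

  coord_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  cl <- lines[coord_idx]
  short <- nchar(cl) < 54L
  if (any(short)) {
    abort(sprintf("%s: malformed fixed-column line %d", source, coord_idx[which(short)[1L]]))
  }
  xs <- suppressWarnings(as.numeric(substr(cl, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(cl, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(cl, 47, 54)))
  badnum <- is.na(xs) | is.na(ys) | is.na(zs)
  if (any(badnum)) {
    abort(sprintf("%s: malformed fixed-column line %d", source, coord_idx[which(badnum)[1L]]))
  }
  atoms <- tibble::tibble(
    record = substr(cl, 1, 6),
    name = stringr::str_trim(substr(cl, 13, 16)),
    altloc = substr(cl, 17, 17),
    resname = stringr::str_trim(substr(cl, 18, 20)),
    chain = substr(cl, 22, 22),
    resno = as.integer(substr(cl, 23, 26)),
    icode = substr(cl, 27, 27),
    x = xs, y = ys, z = zs,
    element = toupper(stringr::str_trim(substr(cl, 77, 78)))
  )

  prot <- atoms[atoms$record == "ATOM  ", , drop = FALSE]
  # keep the first altloc of each atom
  prot <- prot[!duplicated(prot[, c("chain", "resno", "icode", "name")]), , drop = FALSE]
  res <- prot[!duplicated(prot[, c("chain", "resno", "icode")]),
              c("chain", "resno", "icode", "resname"), drop = FALSE]
  ca <- prot[prot$name == "CA", c("chain", "resno", "icode", "x", "y", "z"), drop = FALSE]
  residues <- dplyr::left_join(res, ca, by = c("chain", "resno", "icode"))
  residues$aa <- aa_one(residues$resname)
  residues <- residues[, c("chain", "resno", "icode", "resname", "aa", "x", "y", "z")]

  ss <- lines[rec == "SSBOND"]
  ssbond <- tibble::tibble(
    chain1 = substr(ss, 16, 16),
    resno1 = as.integer(substr(ss, 18, 21)),
    chain2 = substr(ss, 30, 30),
    resno2 = as.integer(substr(ss, 32, 35))
  )

  lk <- lines[rec == "LINK  "]
  link_cys <- tibble::tibble(chain = character(), resno = integer())
  if (length(lk) > 0L) {
    side1 <- tibble::tibble(resname = stringr::str_trim(substr(lk, 18, 20)),
                            chain = substr(lk, 22, 22),
                            resno = as.integer(substr(lk, 23, 26)))
    side2 <- tibble::tibble(resname = stringr::str_trim(substr(lk, 48, 50)),
                            chain = substr(lk, 52, 52),
                            resno = as.integer(substr(lk, 53, 56)))
    both <- dplyr::bind_rows(side1, side2)
    link_cys <- dplyr::distinct(both[both$resname == "CYS", c("chain", "resno")])
  }

  het <- atoms[atoms$record == "HETATM", , drop = FALSE]
  metals <- het[het$element %in% METAL_ELEMENTS, c("element", "x", "y", "z"), drop = FALSE]

  new_pdb_structure(structure_id, residues, ssbond, link_cys, metals)
}

new_pdb_structure <- function(structure_id, residues, ssbond = NULL,
                              link_cys = NULL, metals = NULL) {
  structure(
    list(structure_id = structure_id,
         residues = residues,
         ssbond = ssbond %||% tibble::tibble(chain1 = character(), resno1 = integer(),
                                             chain2 = character(), resno2 = integer()),
         link_cys = link_cys %||% tibble::tibble(chain = character(), resno = integer()),
         metals = metals %||% tibble::tibble(element = character(), x = numeric(),
                                             y = numeric(), z = numeric())),
    class = "pdb_structure"
  )
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure %s> %d residues, %d chain(s), %d SSBOND, %d LINK-Cys, metals: %s\n",
              x$structure_id, nrow(x$residues),
              length(unique(x$residues$chain)), nrow(x$ssbond), nrow(x$link_cys),
              if (nrow(x$metals) > 0) paste(unique(x$metals$element), collapse = ",") else "none"))
  invisible(x)
}

#' Metal elements bound in a structure
#'
#' @param struct A `pdb_structure`.
#' @return Character vector of distinct metal element symbols.
#' @export
bound_metals <- function(struct) {
  unique(struct$metals$element)
}

#' Extract one chain of a structure
#'
#' @param struct A `pdb_structure`.
#' @param chain_id Chain identifier; defaults to the first chain.
#' @return An object of class `structure_chain`: list with `structure_id`,
#'   `chain_id`, `residues` (tibble as in [read_structure()], this chain
#'   only), `sequence` (one-letter string), `ssbond` (intra-chain pairs),
#'   `link_cys` (this chain), `metals` (entry-level).
#' @export
get_chain <- function(struct, chain_id = NULL) {
  stopifnot(inherits(struct, "pdb_structure"))
  chain_id <- chain_id %||% struct$residues$chain[1L]
  res <- struct$residues[struct$residues$chain == chain_id, , drop = FALSE]
  if (nrow(res) == 0L) abort(sprintf("chain '%s' not found in %s", chain_id, struct$structure_id))
  ss <- struct$ssbond[struct$ssbond$chain1 == chain_id & struct$ssbond$chain2 == chain_id, ,
                      drop = FALSE]
  lk <- struct$link_cys[struct$link_cys$chain == chain_id, , drop = FALSE]
  structure(
    list(structure_id = struct$structure_id,
         chain_id = chain_id,
         residues = res,
         sequence = paste(res$aa, collapse = ""),
         ssbond = ss,
         link_cys = lk,
         metals = struct$metals),
    class = "structure_chain"
  )
}

#' @export
print.structure_chain <- function(x, ...) {
  cat(sprintf("<structure_chain %s_%s> %d residues\n",
              x$structure_id, x$chain_id, nrow(x$residues)))
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-column `SSBOND`, `LINK`, `ATOM`, `HETATM` and `END`
#' records. Only C-alpha atoms are written for polypeptide residues (the
#' package's geometric criterion is CA-CA distance), plus one `HETATM` per
#' metal. The writer and [read_structure()] round-trip: re-reading a written
#' file reproduces residues, coordinates (to 3 decimals), SSBOND pairs,
#' LINK cysteines and metals.
#'
#' @param struct A `pdb_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "pdb_structure"))
  res <- struct$residues
  lines <- c(sprintf("HEADER    SYNTHETIC STRUCTURE%s%4s",
                     strrep(" ", 33), substr(struct$structure_id, 1, 4)))

  ss <- struct$ssbond
  if (nrow(ss) > 0L) {
    lines <- c(lines, sprintf(
      "SSBOND %3d CYS %1s %4d    CYS %1s %4d %51s",
      seq_len(nrow(ss)), ss$chain1, ss$resno1, ss$chain2, ss$resno2, ""))
  }
  lk <- struct$link_cys
  if (nrow(lk) > 0L) {
    metal_el <- if (nrow(struct$metals) > 0L) struct$metals$element[1L] else "ZN"
    lines <- c(lines, sprintf(
      "LINK        %4s%1s%3s %1s%4d%1s               %4s%1s%3s %1s%4d%1s",
      " SG ", " ", "CYS", lk$chain, lk$resno, " ",
      sprintf("%-4s", substr(metal_el, 1, 2)), " ",
      sprintf("%3s", substr(metal_el, 1, 2)), lk$chain, 9000L, " "))
  }

  serial <- 0L
  has_ca <- !is.na(res$x)
  rr <- res[has_ca, , drop = FALSE]
  if (nrow(rr) > 0L) {
    serials <- seq_len(nrow(rr))
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      serials, rr$resname, rr$chain, rr$resno,
      ifelse(rr$icode == "" | is.na(rr$icode), " ", rr$icode),
      rr$x, rr$y, rr$z, 1.0, 0.0))
    serial <- nrow(rr)
  }
  me <- struct$metals
  if (nrow(me) > 0L) {
    lines <- c(lines, sprintf(
      "HETATM%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial + seq_len(nrow(me)),
      sprintf("%-2s", substr(me$element, 1, 2)),
      sprintf("%3s", substr(me$element, 1, 3)),
      res$chain[1L] %||% "A", 9000L + seq_len(nrow(me)) - 1L,
      me$x, me$y, me$z, 1.0, 0.0, sprintf("%2s", substr(me$element, 1, 2))))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Structure-database control fraction f'
#'
#' Computes, over a set of deposited structures, the fraction of cysteine
#' residues engaged in declared disulfide bonds — the direct, structure-based
#' control against which the sequence-mapping estimate `f` is compared.
#' Rules:
#' \itemize{
#'   \item entries binding any excluded metal (default Zn or Fe, at entry
#'     level) are dropped entirely;
#'   \item the denominator is the number of CYS residues observed in ATOM
#'     records of retained chains, minus cysteines appearing in LINK records
#'     (metal/ligand-coordinating, not disulfide-capable);
#'   \item the numerator is the number of retained cysteines appearing in
#'     SSBOND records;
#'   \item near-duplicate chains (default `>= 95%` sequence identity to an
#'     earlier chain) are collapsed to the first-seen representative, so a
#'     heavily re-deposited protein counts once.
#' }
#'
#' @param structures A list of `pdb_structure` objects.
#' @param exclude_metals Metal element symbols triggering entry-level
#'   exclusion (default `c("ZN", "FE")`).
#' @param dedup_identity Sequence-identity threshold for redundancy removal;
#'   `NULL` disables deduplication.
#' @return One-row tibble: `n_structures_used`, `n_excluded_metal`,
#'   `n_cys_considered`, `n_cys_disulfide`, `f_prime`.
#' @export
structure_disulfide_fraction <- function(structures,
                                         exclude_metals = c("ZN", "FE"),
                                         dedup_identity = 0.95) {
  stopifnot(length(structures) > 0L)
  excl <- vapply(structures,
                 function(s) any(bound_metals(s) %in% exclude_metals),
                 logical(1))
  used <- structures[!excl]
  if (length(used) == 0L) abort("no eligible cysteines")

  chains <- unlist(lapply(used, function(s) {
    lapply(unique(s$residues$chain), function(ch) get_chain(s, ch))
  }), recursive = FALSE)

  if (!is.null(dedup_identity)) {
    chains <- dedup_chains(chains, dedup_identity)
  }

  num <- 0L; den <- 0L
  for (ch in chains) {
    cys <- ch$residues[ch$residues$resname == "CYS", , drop = FALSE]
    in_link <- cys$resno %in% ch$link_cys$resno
    ss_res <- c(ch$ssbond$resno1, ch$ssbond$resno2)
    in_ss <- cys$resno %in% ss_res
    den <- den + sum(!in_link)
    num <- num + sum(in_ss & !in_link)
  }
  if (den == 0L) abort("no eligible cysteines")

  tibble::tibble(
    n_structures_used = length(used),
    n_excluded_metal = sum(excl),
    n_cys_considered = den,
    n_cys_disulfide = num,
    f_prime = num / den
  )
}

# Greedy first-seen representative clustering by global-alignment identity.
# A chain is a duplicate only if the alignment also covers >= 80% of the
# shorter sequence, so a short spurious end-overlap never collapses two
# unrelated chains.
dedup_chains <- function(chains, identity_threshold) {
  reps <- list()
  for (ch in chains) {
    dup <- FALSE
    for (r in reps) {
      if (abs(nchar(ch$sequence) - nchar(r$sequence)) >
          0.2 * max(nchar(ch$sequence), nchar(r$sequence))) next
      aln <- global_realign(ch$sequence, r$sequence)
      coverage <- nrow(aln$pairs) / min(nchar(ch$sequence), nchar(r$sequence))
      if (aln$identity >= identity_threshold && coverage >= 0.8) { dup <- TRUE; break }
    }
    if (!dup) reps[[length(reps) + 1L]] <- ch
  }
  reps
}
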
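#' Read a proteome from a FASTA file
#'
#' Reads a multi-FASTA file of protein sequences into a tibble, one row per
#' entry, validating residues and locating cysteines. This tibble is the
#' common currency of the whole pipeline: every downstream stage (filtering,
#' parity counting, structure mapping) takes it as its first argument.
#'
#' Header conventions follow the UniProt FASTA dialect without requiring it:
#' the text up to the first whitespace is the record id; if the description
#' contains an `OS=` token the organism is taken from it, otherwise the
#' `organism` argument is used.
#'
#' Cysteine positions are stored 0-based (internal convention throughout the
#' package); report writers convert to 1-based residue numbering.
#'
#' @param path Path to a FASTA file. Multi-line sequences are accepted.
#' @param organism Fallback organism label when no `OS=` token is present.
#' @return A tibble with columns `id`, `organism`, `sequence` (upper case,
#'   terminal `*` stripped), `length`, `n_cys` and the list-column
#'   `cys_positions` (0-based, strictly increasing).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 toy", "MCCA", ">p2", "MAAA"), fa)
#' read_proteome(fa)
#' @export
read_proteome <- function(path, organism = NA_character_) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("cannot read FASTA '%s': %s", path,
                                      conditionMessage(e)))
  )
  if (length(set) == 0L) abort("no sequences")

  headers <- names(set)
  ids <- stringr::str_extract(headers, "^\\S+")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    abort(sprintf("duplicate sequence id: '%s'", dup))
  }
  org <- stringr::str_match(headers, "OS=(.*?)(?:\\s+[A-Z]{2}=|$)")[, 2L]
  org <- dplyr::coalesce(org, organism)

  seqs <- toupper(as.character(set))
  seqs <- stringr::str_remove(seqs, "\\*+$")  # terminal stop codons

  allowed <- c(AA_STANDARD, AA_EXTRA)
  bad <- stringr::str_extract(seqs, paste0("[^", paste(allowed, collapse = ""), "]"))
  if (any(!is.na(bad))) {
    k <- which(!is.na(bad))[1L]
    abort(sprintf("record '%s' contains invalid character '%s'", ids[k], bad[k]))
  }

  new_proteome(ids, org, seqs)
}

# Construct/validate the proteome tibble from parallel vectors.
new_proteome <- function(id, organism, sequence) {
  tibble::tibble(
    id = as.character(id),
    organism = as.character(organism),
    sequence = as.character(sequence),
    length = nchar(sequence),
    cys_positions = locate_cysteines(sequence),
    n_cys = lengths(cys_positions)
  )[, c("id", "organism", "sequence", "length", "n_cys", "cys_positions")]
}

#' Locate cysteine residues in sequences
#'
#' Returns, for each sequence, the 0-based positions of `C` residues.
#' Ambiguity codes (`X`, `B`, `Z`) and selenocysteine (`U`) are never counted
#' as cysteine.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return A list of strictly increasing integer vectors (0-based), one per
#'   sequence.
#' @examples
#' locate_cysteines(c("CACAC", "MMMM"))
#' @export
locate_cysteines <- function(sequence) {
  lapply(stringr::str_locate_all(sequence, stringr::fixed("C")),
         function(m) as.integer(m[, 1L]) - 1L)
}

#' Index cysteines of a single record
#'
#' Single-record convenience around [locate_cysteines()]: returns the 0-based
#' cysteine positions of one sequence.
#'
#' @param sequence A single amino-acid sequence.
#' @return Integer vector of 0-based positions.
#' @export
index_cysteines <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  locate_cysteines(sequence)[[1L]]
}

#' Write a proteome tibble to FASTA
#'
#' Writes `id` headers (with the organism appended as `OS=` when present) and
#' sequences wrapped at a fixed column width. `write_proteome()` followed by
#' [read_proteome()] round-trips ids, sequences and cysteine positions.
#'
#' @param proteome Proteome tibble as returned by [read_proteome()].
#' @param path Output file path.
#' @param width Sequence line width (default 60).
#' @param with_organism Append ` OS=<organism>` to headers when organism is
#'   not `NA` (default TRUE).
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path, width = 60, with_organism = TRUE) {
  stopifnot(all(c("id", "sequence") %in% names(proteome)))
  org <- if ("organism" %in% names(proteome)) proteome$organism else NA
  hdr <- ifelse(with_organism & !is.na(org),
                paste0(proteome$id, " OS=", org),
                proteome$id)
  set <- Biostrings::BStringSet(proteome$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
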
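#' Build a structure-sequence library
#'
#' Flattens a list of structures into the sequence library searched by
#' [search_homologs()]: one row per chain, ids in the `entry_chain` form
#' (e.g. `"2OPL_A"`).
#'
#' @param structures List of `pdb_structure` objects.
#' @return Tibble with columns `target_id`, `structure_id`, `chain_id`,
#'   `sequence`.
#' @export
build_structure_library <- function(structures) {
  purrr::map_dfr(structures, function(s) {
    purrr::map_dfr(unique(s$residues$chain), function(ch) {
      chain <- get_chain(s, ch)
      tibble::tibble(target_id = paste0(s$structure_id, "_", ch),
                     structure_id = s$structure_id,
                     chain_id = ch,
                     sequence = chain$sequence)
    })
  })
}

#' Read a structure-sequence library from FASTA
#'
#' Ids must follow the `entry_chain` convention (`"2OPL_A"`).
#'
#' @param path FASTA file path.
#' @return Library tibble as in [build_structure_library()].
#' @export
read_structure_library <- function(path) {
  p <- read_proteome(path)
  parts <- stringr::str_match(p$id, "^(.+)_([^_]+)$")
  tibble::tibble(target_id = p$id,
                 structure_id = parts[, 2L],
                 chain_id = parts[, 3L],
                 sequence = p$sequence)
}

#' Homology-search parameters
#'
#' @param evalue_max Maximum E-value for accepting a hit (default `1e-4`).
#' @param hit_source `"internal"` (built-in local-alignment search) or
#'   `"tabular"` (pre-computed 12-column blast-tabular hits).
#' @return An object of class `search_params`.
#' @export
search_params <- function(evalue_max = 1e-4,
                          hit_source = c("internal", "tabular")) {
  stopifnot(evalue_max > 0)
  structure(list(evalue_max = evalue_max, hit_source = match.arg(hit_source)),
            class = "search_params")
}

# Karlin-Altschul parameters used by the internal search E-value
#   E = K * m * n * exp(-lambda * S)
# (gapped BLOSUM62, gap open 11 / extend 1 convention). The internal search
# is a stand-in for an external BLAST run: its E-values are calibrated only
# to reproduce accept/reject behaviour at the default gate, not BLAST's
# exact numbers. Pre-computed BLAST hits can be supplied via tabular input.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Search a structure-sequence library for homologs
#'
#' Ranks library chains by E-value against a query sequence. The internal
#' mode scores every library sequence by local (Smith-Waterman) alignment
#' with BLOSUM62, gap open 11 / extend 1, and converts scores to E-values
#' with fixed Karlin-Altschul constants (lambda = 0.267, K = 0.041). Hits
#' are sorted by ascending E-value; ties by descending score, then
#' lexicographic target id. Only hits with `E < evalue_max` are returned; no
#' hit below threshold gives an empty tibble, not an error.
#'
#' @param query A single query sequence (string), or a one-row proteome
#'   tibble.
#' @param library Library tibble ([build_structure_library()]), used in
#'   internal mode.
#' @param params A [search_params()] object.
#' @param tabular_hits Tibble from [read_blast_tab()] (or a file path) when
#'   `hit_source = "tabular"`; rows are filtered to this query's id.
#' @return Tibble with columns `target_id`, `evalue`, `score`, best first.
#' @export
search_homologs <- function(query, library = NULL, params = search_params(),
                            tabular_hits = NULL) {
  stopifnot(inherits(params, "search_params"))
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    query_id <- query$id
    query <- query$sequence
  } else {
    query_id <- NA_character_
  }

  if (params$hit_source == "tabular") {
    if (is.null(tabular_hits)) abort("hit_source 'tabular' requires `tabular_hits`")
    if (is.character(tabular_hits)) tabular_hits <- read_blast_tab(tabular_hits)
    hits <- tabular_hits
    if (!is.na(query_id)) hits <- hits[hits$qseqid == query_id, , drop = FALSE]
    out <- tibble::tibble(target_id = hits$sseqid,
                          evalue = hits$evalue,
                          score = hits$bitscore)
  } else {
    if (is.null(library) || nrow(library) == 0L) abort("internal search requires a non-empty `library`")
    scores <- local_scores(query, library$sequence)
    ev <- KA_K * nchar(query) * nchar(library$sequence) * exp(-KA_LAMBDA * scores)
    out <- tibble::tibble(target_id = library$target_id,
                          evalue = ev,
                          score = scores)
  }
  out <- out[out$evalue < params$evalue_max, , drop = FALSE]
  out[order(out$evalue, -out$score, out$target_id), , drop = FALSE]
}

# Vectorised Smith-Waterman scores of one query against many subjects.
local_scores <- function(query, subjects) {
  sub <- blosum62()
  pat <- Biostrings::AAStringSet(sanitize_aa(subjects))
  as.numeric(Biostrings::pairwiseAlignment(
    pat, Biostrings::AAString(sanitize_aa(query)),
    type = "local", substitutionMatrix = sub,
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE))
}

# Replace letters outside the scoring alphabet with 'X' for Biostrings.
sanitize_aa <- function(x) {
  stringr::str_replace_all(toupper(x), "[^ARNDCQEGHILKMFPSTWYVBJZX*]", "X")
}

#' Read blast-tabular homology hits
#'
#' Parses the 12-column blast-tabular dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`; 1-based
#' inclusive coordinates).
#'
#' @param path Path to the tabular file.
#' @return Tibble with the 12 standard columns.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  readr::read_tsv(path, col_names = cols, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    qseqid = "c", sseqid = "c", pident = "d", length = "i",
                    mismatch = "i", gapopen = "i", qstart = "i", qend = "i",
                    sstart = "i", send = "i", evalue = "d", bitscore = "d"))
}
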
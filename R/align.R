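#' Global realignment of a query against a structure sequence
#'
#' Optimal pairwise alignment by dynamic programming (Needleman-Wunsch with
#' Gotoh affine gaps), used to recalculate residue correspondences before
#' cysteines are placed on a structure: homology-search coordinates are often
#' unreliable near indels, so the mapping stage always realigns from scratch.
#'
#' By default end gaps are free (semi-global / overlap alignment): deposited
#' structures are frequently fragments of the full-length protein, and
#' charging terminal gaps would distort the alignment of the covered region.
#' Set `type = "global"` for strict end-to-end alignment.
#'
#' Scoring: BLOSUM62 substitution matrix; a gap of length L costs
#' `gap_open + L * gap_extend` (11 + L with defaults). Residues absent from
#' the matrix are scored as `X`. Traceback ties are broken deterministically:
#' diagonal, then up (gap in target), then left (gap in query).
#'
#' @param query,target Non-empty amino-acid strings.
#' @param type `"overlap"` (default, free end gaps) or `"global"`.
#' @param gap_open,gap_extend Affine gap parameters (defaults 11 and 1).
#' @param substitution_matrix Square scoring matrix with residue dimnames;
#'   defaults to BLOSUM62.
#' @param query_id,target_id Optional labels carried into the result.
#' @return An object of class `realignment`: list with `query_id`,
#'   `target_id`, `pairs` (tibble of match columns: `qpos` 0-based query
#'   index, `tpos` 1-based target ordinal, `qres`, `tres`, `match`),
#'   `score`, `identity` (matches / aligned columns; `NaN` if no column
#'   aligned) and the input sequences.
#' @examples
#' aln <- global_realign("ACDEFG", "ACDFG")
#' tidy(aln)
#' @export
global_realign <- function(query, target, type = c("overlap", "global"),
                           gap_open = 11, gap_extend = 1,
                           substitution_matrix = NULL,
                           query_id = NA_character_, target_id = NA_character_) {
  type <- match.arg(type)
  stopifnot(is.character(query), length(query) == 1L, nzchar(query),
            is.character(target), length(target) == 1L, nzchar(target))
  sub <- substitution_matrix %||% blosum62()

  qi <- encode_residues(query, sub)
  ti <- encode_residues(target, sub)
  res <- .align_affine(qi, ti, sub, gap_open, gap_extend, type == "overlap")

  qres <- if (length(res$qpos) > 0L) substring(query, res$qpos + 1L, res$qpos + 1L) else character(0)
  tres <- if (length(res$tpos) > 0L) substring(target, res$tpos + 1L, res$tpos + 1L) else character(0)
  pairs <- tibble::tibble(
    qpos = as.integer(res$qpos),          # 0-based
    tpos = as.integer(res$tpos) + 1L,     # 1-based ordinal into target
    qres = qres,
    tres = tres,
    match = qres == tres
  )
  structure(
    list(query_id = query_id, target_id = target_id,
         pairs = pairs,
         score = res$score,
         identity = if (nrow(pairs) > 0L) mean(pairs$match) else NaN,
         query = query, target = target, type = type),
    class = "realignment"
  )
}

# Cached BLOSUM62 from Biostrings.
blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      mat <<- env$BLOSUM62
    }
    mat
  }
})

# Map residue letters to 0-based row indices of the scoring matrix;
# letters absent from the matrix fall back to 'X'.
encode_residues <- function(seq, sub) {
  alphabet <- rownames(sub)
  idx <- match(strsplit(toupper(seq), "")[[1L]], alphabet)
  if (anyNA(idx)) {
    x <- match("X", alphabet)
    if (is.na(x)) abort("substitution matrix lacks an 'X' fallback row")
    idx[is.na(idx)] <- x
  }
  idx - 1L
}

#' @export
print.realignment <- function(x, ...) {
  cat(sprintf("<realignment %s ~ %s> score %.1f, identity %.3f over %d columns\n",
              x$query_id %||% "?", x$target_id %||% "?",
              x$score, x$identity, nrow(x$pairs)))
  invisible(x)
}

#' @describeIn global_realign Aligned match columns as a tibble.
#' @param x A `realignment`.
#' @param ... Unused.
#' @export
tidy.realignment <- function(x, ...) x$pairs

#' @export
glance.realignment <- function(x, ...) {
  tibble::tibble(score = x$score, identity = x$identity,
                 n_aligned = nrow(x$pairs),
                 query_length = nchar(x$query), target_length = nchar(x$target))
}
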
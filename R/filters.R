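#' Eligibility-filter parameters
#'
#' Bundles the three eligibility rules applied before structure mapping:
#' a minimum raw cysteine count per protein, a sequence-spacing mask that
#' drops closely spaced cysteines (a proxy for metal-binding motifs such as
#' CXXC, whose cysteines would otherwise be mistaken for disulfide partners),
#' and removal of secreted/periplasmic proteins (disulfides are expected in
#' oxidizing extracytosolic compartments regardless of organism, so they
#' carry no signal about the cytosol).
#'
#' @param min_cys Minimum raw cysteine count for a protein to be analysed
#'   (default 2).
#' @param cluster_spacing Cysteines at sequence separation `<=` this value
#'   are masked from mapping eligibility; both members of a close pair are
#'   dropped (default 5).
#' @param signal_filter_mode One of `"heuristic"` (built-in signal-peptide
#'   predictor), `"exclusion_list"` (drop explicitly listed ids, e.g. calls
#'   from an external predictor) or `"off"`.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_cys = 2, cluster_spacing = 5,
                          signal_filter_mode = c("heuristic", "exclusion_list", "off")) {
  stopifnot_scalar_number(min_cys, "min_cys", min = 0)
  stopifnot_scalar_number(cluster_spacing, "cluster_spacing", min = 0)
  structure(
    list(min_cys = as.integer(min_cys),
         cluster_spacing = as.integer(cluster_spacing),
         signal_filter_mode = match.arg(signal_filter_mode)),
    class = "filter_params"
  )
}

#' Filter proteins by minimum cysteine count
#'
#' Retains proteins whose raw cysteine count is at least `min_cys`
#' (default 2: at least one potential disulfide). Input order is preserved.
#'
#' @param proteome Proteome tibble.
#' @param min_cys Minimum raw cysteine count.
#' @return The retained proteome tibble, with attribute `n_removed`.
#' @export
filter_min_cys <- function(proteome, min_cys = 2) {
  stopifnot_scalar_number(min_cys, "min_cys", min = 0)
  keep <- proteome$n_cys >= min_cys
  out <- proteome[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Mask closely spaced cysteines
#'
#' Removes every cysteine that has another cysteine within `spacing` residues
#' in sequence (both members of a close pair are removed). Closely spaced
#' cysteines frequently coordinate metals (e.g. CXXC motifs), so counting
#' them as disulfide candidates would inflate the abundance estimate. The
#' mask affects mapping *eligibility* only; it never removes a protein.
#'
#' The operation is idempotent: masking an already masked set is a no-op.
#'
#' @param positions Strictly increasing integer vector of 0-based cysteine
#'   positions.
#' @param spacing Maximum sequence separation considered "close"
#'   (default 5; separation `<= spacing` masks both positions).
#' @return The eligible positions, strictly increasing.
#' @examples
#' mask_clustered_cys(c(10L, 13L, 40L), spacing = 5)  # -> 40
#' @export
mask_clustered_cys <- function(positions, spacing = 5) {
  if (length(positions) == 0L) return(integer(0))
  stopifnot(!is.unsorted(positions, strictly = TRUE))
  d_prev <- c(Inf, diff(positions))
  d_next <- c(diff(positions), Inf)
  positions[d_prev > spacing & d_next > spacing]
}

#' Add mapping-eligible cysteine positions to a proteome
#'
#' Applies [mask_clustered_cys()] per protein and stores the result in a new
#' list-column `eligible_cys`.
#'
#' @param proteome Proteome tibble.
#' @param spacing Clustering spacing threshold (see [mask_clustered_cys()]).
#' @return The proteome tibble with list-column `eligible_cys` added.
#' @export
add_eligible_cys <- function(proteome, spacing = 5) {
  proteome$eligible_cys <- lapply(proteome$cys_positions, mask_clustered_cys,
                                  spacing = spacing)
  proteome
}

#' Heuristic signal-peptide prediction
#'
#' A deterministic, self-contained stand-in for a trained signal-peptide
#' predictor, encoding the classical tripartite architecture of secretory
#' signal peptides. A sequence is called secreted only if all three hold:
#'
#' 1. *n-region*: a lysine or arginine within the first 7 residues;
#' 2. *h-region*: some 10-residue window starting within residues 2-25
#'    contains at least 8 residues from the hydrophobic set
#'    `{A, I, L, M, F, V, W, C}`;
#' 3. *c-region*: a candidate cleavage position `p` in residues 15-40 with
#'    residues `p-3` and `p-1` both in the small-residue set
#'    `{A, G, S, C, T, V}` (the "-3, -1 rule").
#'
#' The score is the fraction of the three conditions met. Sequences shorter
#' than 15 residues are never called secreted. This heuristic is a
#' rule-based classifier, not a reimplementation of any trained predictor;
#' externally computed calls can be supplied instead via
#' [filter_secreted()] with `mode = "exclusion_list"`.
#'
#' All residue positions in this help page are 1-based.
#'
#' @param sequence Character vector of sequences.
#' @return A tibble with columns `score` (in `[0, 1]`) and `is_secreted`.
#' @export
predict_signal_peptide <- function(sequence) {
  res <- lapply(sequence, signal_conditions)
  tibble::tibble(
    score = vapply(res, function(x) mean(x), numeric(1)),
    is_secreted = vapply(res, function(x) all(x) && length(x) == 3L, logical(1)) &
      nchar(sequence) >= 15L
  )
}

# The three boolean conditions, evaluated on one sequence.
signal_conditions <- function(seq) {
  s <- strsplit(seq, "")[[1L]]
  n <- length(s)
  if (n == 0L) return(c(FALSE, FALSE, FALSE))
  hydrophobic <- c("A", "I", "L", "M", "F", "V", "W", "C")
  small <- c("A", "G", "S", "C", "T", "V")

  cond_n <- any(s[seq_len(min(7L, n))] %in% c("K", "R"))

  cond_h <- FALSE
  last_start <- min(25L, n - 9L)
  if (last_start >= 2L) {
    for (st in 2:last_start) {
      if (sum(s[st:(st + 9L)] %in% hydrophobic) >= 8L) { cond_h <- TRUE; break }
    }
  }

  cond_c <- FALSE
  if (n >= 15L) {
    for (p in 15:min(40L, n)) {
      if (s[p - 3L] %in% small && s[p - 1L] %in% small) { cond_c <- TRUE; break }
    }
  }

  c(cond_n, cond_h, cond_c)
}

#' Remove secreted/periplasmic proteins
#'
#' Drops proteins destined for export from the cytosol, where disulfide
#' bonding is routine and therefore uninformative about cytosolic redox
#' conditions.
#'
#' @param proteome Proteome tibble.
#' @param mode `"heuristic"` applies [predict_signal_peptide()];
#'   `"exclusion_list"` removes the ids in `exclusion_list`; `"off"` is the
#'   identity.
#' @param exclusion_list Character vector of ids, or a path to a plain-text
#'   file with one accession per line (`#` comments allowed). Ids absent from
#'   the proteome produce a warning, not an error.
#' @return Retained proteome tibble, with attribute `n_removed`.
#' @export
filter_secreted <- function(proteome,
                            mode = c("heuristic", "exclusion_list", "off"),
                            exclusion_list = NULL) {
  mode <- match.arg(mode)
  if (mode == "off") {
    attr(proteome, "n_removed") <- 0L
    return(proteome)
  }
  if (mode == "exclusion_list") {
    if (is.null(exclusion_list)) abort("mode 'exclusion_list' requires `exclusion_list`")
    ids <- read_exclusion_list(exclusion_list)
    missing <- setdiff(ids, proteome$id)
    if (length(missing) > 0L) {
      warn(sprintf("%d exclusion-list id(s) not found in proteome (e.g. '%s')",
                   length(missing), missing[1L]))
    }
    keep <- !(proteome$id %in% ids)
  } else {
    keep <- !predict_signal_peptide(proteome$sequence)$is_secreted
  }
  out <- proteome[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Accepts either a character vector of ids or a file path.
read_exclusion_list <- function(x) {
  if (length(x) == 1L && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
    x <- lines[nzchar(lines)]
  }
  as.character(x)
}

#' Apply the full eligibility-filter cascade
#'
#' Runs the documented filter order: minimum cysteine count, then the
#' secretion filter, then the clustering mask (which affects cysteine
#' eligibility only, never protein retention). Returns the filtered proteome
#' together with an accounting report whose counts always satisfy
#' `n_input = n_removed_low_cys + n_removed_secreted + n_retained`.
#'
#' @param proteome Proteome tibble.
#' @param params A [filter_params()] object.
#' @param exclusion_list Passed to [filter_secreted()] when
#'   `signal_filter_mode = "exclusion_list"`.
#' @return An object of class `filter_report`: a list with `proteome` (the
#'   retained tibble, including the `eligible_cys` column), `n_input`,
#'   `n_removed_low_cys`, `n_removed_secreted`, `n_retained`.
#' @export
apply_filters <- function(proteome, params = filter_params(),
                          exclusion_list = NULL) {
  stopifnot(inherits(params, "filter_params"))
  n_input <- nrow(proteome)
  p1 <- filter_min_cys(proteome, params$min_cys)
  n_low <- attr(p1, "n_removed")
  p2 <- filter_secreted(p1, mode = params$signal_filter_mode,
                        exclusion_list = exclusion_list)
  n_sec <- attr(p2, "n_removed")
  p3 <- add_eligible_cys(p2, spacing = params$cluster_spacing)
  structure(
    list(proteome = p3,
         n_input = n_input,
         n_removed_low_cys = n_low,
         n_removed_secreted = n_sec,
         n_retained = nrow(p3),
         params = params),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Proteome eligibility filter report\n")
  cat(sprintf("  input proteins     : %d\n", x$n_input))
  cat(sprintf("  removed (<%d Cys)   : %d\n", x$params$min_cys, x$n_removed_low_cys))
  cat(sprintf("  removed (secreted) : %d\n", x$n_removed_secreted))
  cat(sprintf("  retained           : %d\n", x$n_retained))
  invisible(x)
}

#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(n_input = x$n_input,
                 n_removed_low_cys = x$n_removed_low_cys,
                 n_removed_secreted = x$n_removed_secreted,
                 n_retained = x$n_retained)
}
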
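#' Per-protein disulfide fraction
#'
#' For one mapping result, the fraction of mapped cysteines that are hits
#' (have another mapped cysteine within the distance cutoff). With a single
#' mapped cysteine the fraction is necessarily 0 (a hit needs a mapped
#' partner); with none it is undefined (`NA`) and the protein contributes
#' 0 hits / 0 mapped to proteome totals.
#'
#' @param mapping A `cys_mapping` from [map_cysteines()].
#' @param cutoff C-alpha distance cutoff in Angstrom (default 8; strict `<`).
#' @return A one-row tibble: `query_id`, `n_hits`, `n_mapped`, `fraction`.
#' @export
protein_f <- function(mapping, cutoff = 8) {
  stopifnot(inherits(mapping, "cys_mapping"))
  ph <- proximity_hits(mapping, cutoff)
  n_mapped <- nrow(mapping$mapped)
  tibble::tibble(
    query_id = mapping$query_id,
    n_hits = ph$n_hits,
    n_mapped = n_mapped,
    fraction = if (n_mapped > 0L) ph$n_hits / n_mapped else NA_real_
  )
}

#' Proteome-level disulfide abundance parameter f
#'
#' Pools per-protein tallies into the proteome-level abundance parameter:
#' `f = sum(hits) / sum(mapped)` — the ratio of totals, not the mean of
#' per-protein fractions. `m = sum(mapped)` is the number of cysteines that
#' could be placed on homologous structures.
#'
#' @param per_protein Tibble with columns `n_hits` and `n_mapped` (one row
#'   per protein), e.g. accumulated [protein_f()] rows or the `proteins`
#'   table of [run_survey()].
#' @param label Organism / proteome label.
#' @return One-row tibble: `label`, `n_proteins_mapped` (proteins with
#'   `n_mapped > 0`), `m`, `n_hits`, `f`, `tier` (see
#'   [classify_abundance()]).
#' @export
proteome_f <- function(per_protein, label = NA_character_) {
  stopifnot(all(c("n_hits", "n_mapped") %in% names(per_protein)))
  m <- sum(per_protein$n_mapped, na.rm = TRUE)
  if (m == 0) abort("no mapped cysteines")
  hits <- sum(per_protein$n_hits, na.rm = TRUE)
  f <- hits / m
  tibble::tibble(
    label = label,
    n_proteins_mapped = sum(per_protein$n_mapped > 0, na.rm = TRUE),
    m = as.integer(m),
    n_hits = as.integer(hits),
    f = f,
    tier = classify_abundance(f)
  )
}

#' Classify a disulfide abundance value
#'
#' Tier thresholds follow the survey's reporting bands: `f > 0.15` counts as
#' significant disulfide bonding, `f > 0.25` as high, `f > 0.35` as very
#' high; at or below 0.15 is background. All comparisons are strict.
#'
#' @param f Numeric vector of abundance values in `[0, 1]`.
#' @return Character vector: `"background"`, `"significant"`, `"high"` or
#'   `"very_high"`.
#' @examples
#' classify_abundance(c(0.15, 0.16, 0.36))
#' @export
classify_abundance <- function(f) {
  stopifnot(all(f >= 0 & f <= 1, na.rm = TRUE))
  dplyr::case_when(
    f > 0.35 ~ "very_high",
    f > 0.25 ~ "high",
    f > 0.15 ~ "significant",
    TRUE ~ "background"
  )
}

#' Remove redundant strains of the same species
#'
#' Within each species, the first-listed proteome is the parent; subsequent
#' strains whose mapped-protein count is within `tolerance` (default
#' +/- 10%) of the parent's are considered redundant resequencings and
#' removed. Strains differing by more than the tolerance are retained.
#'
#' @param summaries Tibble of proteome summaries (needs
#'   `n_proteins_mapped`).
#' @param species Character vector (recycled column) assigning each row a
#'   species, or the name of a column in `summaries`.
#' @param tolerance Fractional tolerance in `[0, 1)` (default 0.10).
#' @return The retained rows of `summaries`, original order preserved.
#' @export
dedup_strains <- function(summaries, species, tolerance = 0.10) {
  stopifnot(tolerance >= 0, tolerance < 1)
  if (is.character(species) && length(species) == 1L && species %in% names(summaries)) {
    species <- summaries[[species]]
  }
  stopifnot(length(species) == nrow(summaries))
  keep <- logical(nrow(summaries))
  for (sp in unique(species)) {
    idx <- which(species == sp)
    parent_n <- summaries$n_proteins_mapped[idx[1L]]
    keep[idx[1L]] <- TRUE
    for (i in idx[-1L]) {
      keep[i] <- abs(summaries$n_proteins_mapped[i] - parent_n) > tolerance * parent_n
    }
  }
  summaries[keep, , drop = FALSE]
}

#' Correlate mapped abundance f with the structure-database control f'
#'
#' Pearson correlation between the sequence-structure mapping estimate `f`
#' and the control `f_prime` computed directly from deposited structures,
#' across organisms. Agreement between the two supports using `f` as an
#' indicator of disulfide richness where structural coverage is thin.
#'
#' @param pairs Tibble with numeric columns `f` and `f_prime` (and
#'   optionally `label`).
#' @return A one-row tibble: `r`, `n`.
#' @export
compare_f_fprime <- function(pairs) {
  stopifnot(all(c("f", "f_prime") %in% names(pairs)))
  if (nrow(pairs) < 3L) abort("need at least 3 (f, f_prime) pairs")
  tibble::tibble(r = cor(pairs$f, pairs$f_prime), n = nrow(pairs))
}

#' Scatter plot of f against f'
#'
#' @param pairs Tibble with columns `f`, `f_prime` and optionally `label`.
#' @return A ggplot object.
#' @export
plot_f_comparison <- function(pairs) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$f_prime, y = .data$f)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2.5, colour = "#2166ac") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "f' (structure database)", y = "f (sequence-structure mapping)") +
    ggplot2::theme_minimal()
  if ("label" %in% names(pairs)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$label),
                                hjust = -0.15, size = 3, check_overlap = TRUE)
  }
  p
}
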
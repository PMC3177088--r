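#' Run the full disulfide-abundance survey on one proteome
#'
#' End-to-end loop: eligibility filters, homology search against a
#' structure-sequence library, global realignment against the best hit,
#' cysteine placement, proximity counting, and pooling into the proteome
#' abundance parameter `f`. Every input protein is accounted for in exactly
#' one disposition: `filtered_low_cys`, `filtered_secreted`,
#' `no_eligible_cys`, `unmapped` (no hit below the E-value gate) or
#' `mapped`. One structure per protein is used: the best hit under the
#' documented ordering (ascending E-value, then descending score, then
#' target id).
#'
#' @param proteome Proteome tibble.
#' @param structures Named list of `pdb_structure` objects (names =
#'   structure ids).
#' @param library Optional structure-sequence library tibble; derived from
#'   `structures` when omitted.
#' @param filter A [filter_params()] object.
#' @param search A [search_params()] object.
#' @param cutoff C-alpha distance cutoff in Angstrom (default 8).
#' @param exclusion_list Passed to [apply_filters()].
#' @param tabular_hits Blast-tabular hits (tibble or path) for
#'   `hit_source = "tabular"`.
#' @param label Proteome label; defaults to the most common organism entry.
#' @return An object of class `survey_result`: list with `summary` (one-row
#'   tibble from [proteome_f()]), `proteins` (per-protein tibble:
#'   `id`, `disposition`, `target_id`, `n_eligible`, `n_mapped`, `n_hits`,
#'   `fraction`) and `report` (the `filter_report`).
#' @export
run_survey <- function(proteome, structures, library = NULL,
                       filter = filter_params(), search = search_params(),
                       cutoff = 8, exclusion_list = NULL, tabular_hits = NULL,
                       label = NULL) {
  if (is.null(label)) {
    orgs <- proteome$organism[!is.na(proteome$organism)]
    label <- if (length(orgs) > 0L) names(sort(table(orgs), decreasing = TRUE))[1L]
             else "proteome"
  }
  report <- apply_filters(proteome, filter, exclusion_list)
  retained <- report$proteome
  library <- library %||% build_structure_library(structures)
  chains <- chain_cache(structures, library)
  if (is.character(tabular_hits)) tabular_hits <- read_blast_tab(tabular_hits)

  low_ids <- setdiff(proteome$id, proteome$id[proteome$n_cys >= filter$min_cys])
  sec_ids <- setdiff(setdiff(proteome$id, low_ids), retained$id)

  per <- vector("list", nrow(retained))
  for (i in seq_len(nrow(retained))) {
    rec <- retained[i, ]
    eligible <- rec$eligible_cys[[1L]]
    if (length(eligible) == 0L) {
      per[[i]] <- protein_row(rec$id, "no_eligible_cys", n_eligible = 0L)
      next
    }
    hits <- search_homologs(rec, library, search, tabular_hits)
    if (nrow(hits) == 0L) {
      per[[i]] <- protein_row(rec$id, "unmapped", n_eligible = length(eligible))
      next
    }
    target <- hits$target_id[1L]
    chain <- chains[[target]]
    if (is.null(chain)) {
      abort(sprintf("hit target '%s' has no structure chain loaded", target))
    }
    aln <- global_realign(rec$sequence, chain$sequence,
                          query_id = rec$id, target_id = target)
    mp <- map_cysteines(aln, chain, eligible)
    pf <- protein_f(mp, cutoff)
    per[[i]] <- tibble::tibble(id = rec$id, disposition = "mapped",
                               target_id = target,
                               n_eligible = length(eligible),
                               n_mapped = pf$n_mapped, n_hits = pf$n_hits,
                               fraction = pf$fraction)
  }
  proteins <- dplyr::bind_rows(
    tibble::tibble(id = low_ids, disposition = "filtered_low_cys"),
    tibble::tibble(id = sec_ids, disposition = "filtered_secreted"),
    dplyr::bind_rows(per)
  )

  mapped <- proteins[proteins$disposition == "mapped", , drop = FALSE]
  if (nrow(mapped) == 0L || sum(mapped$n_mapped, na.rm = TRUE) == 0) {
    abort("no mapped cysteines")
  }
  summary <- proteome_f(mapped, label = label)
  structure(list(summary = summary, proteins = proteins, report = report),
            class = "survey_result")
}

protein_row <- function(id, disposition, target_id = NA_character_,
                        n_eligible = NA_integer_) {
  tibble::tibble(id = id, disposition = disposition, target_id = target_id,
                 n_eligible = n_eligible, n_mapped = 0L, n_hits = 0L,
                 fraction = NA_real_)
}

# target_id -> structure_chain lookup
chain_cache <- function(structures, library) {
  if (is.null(names(structures))) {
    names(structures) <- vapply(structures, function(s) s$structure_id, character(1))
  }
  out <- lapply(seq_len(nrow(library)), function(i) {
    s <- structures[[library$structure_id[i]]]
    if (is.null(s)) return(NULL)
    get_chain(s, library$chain_id[i])
  })
  names(out) <- library$target_id
  out
}

#' @export
print.survey_result <- function(x, ...) {
  cat("Disulfide abundance survey\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.survey_result <- function(x, ...) x$proteins

#' @export
glance.survey_result <- function(x, ...) x$summary

#' Bar chart of proteome abundance values
#'
#' @param summaries Tibble of [proteome_f()] rows (one per organism).
#' @return A ggplot object.
#' @export
plot_abundance <- function(summaries) {
  tiers <- c("background", "significant", "high", "very_high")
  summaries$tier <- factor(summaries$tier, levels = tiers)
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = stats::reorder(.data$label, .data$f),
                               y = .data$f, fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0.15, 0.25, 0.35), linetype = 3,
                        colour = "grey50") +
    ggplot2::scale_fill_manual(
      values = c(background = "grey70", significant = "#fee08b",
                 high = "#fc8d59", very_high = "#d73027"),
      drop = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "disulfide abundance f", fill = "tier") +
    ggplot2::theme_minimal()
}

# ---- report writers ---------------------------------------------------------

tsv_meta <- function(config) {
  c("# cysmapr report",
    sprintf("# config_hash\t%s", rlang::hash(config)),
    sprintf("# generated_by\tcysmapr %s",
            as.character(utils::packageVersion("cysmapr"))))
}

write_report_tsv <- function(data, path, config = list()) {
  writeLines(tsv_meta(config), path)
  readr::write_tsv(data, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write survey reports to a directory
#'
#' Emits `survey.tsv` (proteome summary), `proteins.tsv` (per-protein
#' dispositions; residue numbers 1-based) and `filter_report.tsv`. Outputs
#' are deterministic given identical inputs: rerunning writes byte-identical
#' files.
#'
#' @param result A `survey_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(result, dir) {
  stopifnot(inherits(result, "survey_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(summary = result$summary$label, params = result$report$params)
  write_report_tsv(result$summary, file.path(dir, "survey.tsv"), cfg)
  write_report_tsv(result$proteins, file.path(dir, "proteins.tsv"), cfg)
  write_report_tsv(glance(result$report), file.path(dir, "filter_report.tsv"), cfg)
  invisible(dir)
}

#' Run the parity analysis and optionally write its report
#'
#' @param proteome Proteome tibble (secretion-filter it first for a faithful
#'   analysis; see [filter_secreted()]).
#' @param length_min,length_max,max_cys_bin See [parity_table()].
#' @param path Optional TSV output path. The bias statistic row is labelled
#'   `extension`: it is a scalar summary added on top of the visual
#'   even/odd analysis.
#' @return A list: `table` (the `parity_table`) and `bias` (from
#'   [parity_bias()], or `NULL` when no multi-cysteine proteins exist).
#' @export
run_parity <- function(proteome, length_min = 150, length_max = 200,
                       max_cys_bin = 10, path = NULL) {
  tab <- parity_table(proteome, length_min, length_max, max_cys_bin)
  bias <- if (tab$even_ge2 + tab$odd_ge3 > 0L) parity_bias(tab) else NULL
  if (!is.null(path)) {
    org <- unique(proteome$organism)
    org <- if (length(org) == 1L) org else "mixed"
    dat <- dplyr::mutate(tidy(tab), organism = org, .before = 1L)
    writeLines(tsv_meta(list(length_min, length_max)), path)
    readr::write_tsv(dat, path, append = TRUE, col_names = TRUE)
    if (!is.null(bias)) {
      cat(sprintf("# extension\tbias=%.6f\tp_value=%.6g\n", bias$bias, bias$p_value),
          file = path, append = TRUE)
    }
  }
  list(table = tab, bias = bias)
}

#' Compute the structure-database control f' and optionally write it
#'
#' @param structures List of `pdb_structure` objects, or a directory of
#'   `.pdb` files.
#' @param exclude_metals,dedup_identity See
#'   [structure_disulfide_fraction()].
#' @param path Optional TSV output path.
#' @return The one-row summary tibble.
#' @export
run_fprime <- function(structures, exclude_metals = c("ZN", "FE"),
                       dedup_identity = 0.95, path = NULL) {
  if (is.character(structures)) {
    files <- sort(list.files(structures, pattern = "\\.pdb$", full.names = TRUE))
    if (length(files) == 0L) abort(sprintf("no .pdb files in %s", structures))
    structures <- lapply(files, read_structure)
  }
  out <- structure_disulfide_fraction(structures, exclude_metals, dedup_identity)
  if (!is.null(path)) write_report_tsv(out, path, list(exclude_metals))
  out
}

#' Compare f with f' across organisms and optionally write the table
#'
#' @param pairs Tibble with columns `f`, `f_prime` (and optionally `label`).
#' @param path Optional TSV output path.
#' @return One-row tibble with the Pearson `r` and `n`.
#' @export
run_compare <- function(pairs, path = NULL) {
  out <- compare_f_fprime(pairs)
  if (!is.null(path)) {
    writeLines(tsv_meta(list("compare")), path)
    readr::write_tsv(pairs, path, append = TRUE, col_names = TRUE)
    cat(sprintf("# pearson_r\t%.6f\tn\t%d\n", out$r, out$n), file = path, append = TRUE)
  }
  out
}
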
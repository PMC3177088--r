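#' Place query cysteines in a structure's coordinate frame
#'
#' Given a realignment of the query against a chain's sequence, each eligible
#' query cysteine that sits in an aligned (match) column whose target residue
#' has a C-alpha atom becomes a *mapped* cysteine, inheriting that residue's
#' CA coordinate. The target residue need not itself be a cysteine: the
#' question is where the query's cysteine would sit if the query folded like
#' its homolog. Cysteines aligned into gaps, or onto residues lacking a CA,
#' are recorded as unmapped.
#'
#' @param alignment A `realignment` whose target is `chain`'s sequence.
#' @param chain A `structure_chain` from [get_chain()].
#' @param eligible_cys 0-based query cysteine positions (after the clustering
#'   mask; see [mask_clustered_cys()]).
#' @return An object of class `cys_mapping`: list with `query_id`,
#'   `structure_id`, `chain_id`, `mapped` (tibble: `qpos`, `tpos`, `resno`,
#'   `x`, `y`, `z`), `unmapped` (integer 0-based positions) and `distances`
#'   (symmetric matrix of pairwise CA distances among mapped cysteines, in
#'   Angstrom).
#' @export
map_cysteines <- function(alignment, chain, eligible_cys) {
  stopifnot(inherits(alignment, "realignment"), inherits(chain, "structure_chain"))
  if (nchar(alignment$target) != nrow(chain$residues)) {
    abort(sprintf("alignment target length (%d) does not match chain %s_%s (%d residues)",
                  nchar(alignment$target), chain$structure_id, chain$chain_id,
                  nrow(chain$residues)))
  }
  eligible_cys <- as.integer(eligible_cys)
  hit_col <- match(eligible_cys, alignment$pairs$qpos)
  tpos <- alignment$pairs$tpos[hit_col]            # 1-based target ordinal
  has_ca <- !is.na(tpos) & !is.na(chain$residues$x[tpos])

  mapped <- tibble::tibble(
    qpos = eligible_cys[has_ca],
    tpos = tpos[has_ca],
    resno = chain$residues$resno[tpos[has_ca]],
    x = chain$residues$x[tpos[has_ca]],
    y = chain$residues$y[tpos[has_ca]],
    z = chain$residues$z[tpos[has_ca]]
  )
  distances <- if (nrow(mapped) > 0L) {
    d <- coord_dist(as.matrix(mapped[, c("x", "y", "z")]))
    dimnames(d) <- list(mapped$qpos, mapped$qpos)
    d
  } else {
    matrix(numeric(0), 0, 0)
  }
  structure(
    list(query_id = alignment$query_id,
         structure_id = chain$structure_id,
         chain_id = chain$chain_id,
         mapped = mapped,
         unmapped = eligible_cys[!has_ca],
         distances = distances),
    class = "cys_mapping"
  )
}

#' @export
print.cys_mapping <- function(x, ...) {
  cat(sprintf("<cys_mapping %s -> %s_%s> %d mapped, %d unmapped cysteines\n",
              x$query_id, x$structure_id, x$chain_id,
              nrow(x$mapped), length(x$unmapped)))
  invisible(x)
}

#' @export
tidy.cys_mapping <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$mapped, status = "mapped"),
    tibble::tibble(qpos = x$unmapped, status = "unmapped")
  )
}

#' Count cysteines in spatial proximity (hits)
#'
#' A mapped cysteine is a *hit* when at least one other mapped cysteine of
#' the same chain lies strictly closer than `cutoff` Angstrom (C-alpha to
#' C-alpha) — the geometry required of a disulfide pair. A cysteine within
#' the cutoff of several partners is still counted once. Only intra-chain
#' distances are considered: intermolecular disulfides are a separate,
#' unmeasured category.
#'
#' @param mapping A `cys_mapping`.
#' @param cutoff Distance cutoff in Angstrom (default 8; strict `<`).
#' @return List with `n_hits`, `hits` (0-based query positions) and
#'   `predicted_pairs` (tibble `qpos1`, `qpos2`, `distance`, each pair
#'   once, `qpos1 < qpos2`).
#' @export
proximity_hits <- function(mapping, cutoff = 8) {
  stopifnot(inherits(mapping, "cys_mapping"), cutoff > 0)
  d <- mapping$distances
  n <- nrow(d)
  if (n < 2L) {
    return(list(n_hits = 0L, hits = integer(0),
                predicted_pairs = tibble::tibble(qpos1 = integer(), qpos2 = integer(),
                                                 distance = numeric())))
  }
  close <- d < cutoff
  diag(close) <- FALSE
  is_hit <- rowSums(close) > 0
  idx <- which(close & upper.tri(close), arr.ind = TRUE)
  qpos <- mapping$mapped$qpos
  list(
    n_hits = sum(is_hit),
    hits = qpos[is_hit],
    predicted_pairs = tibble::tibble(
      qpos1 = qpos[idx[, 1L]],
      qpos2 = qpos[idx[, 2L]],
      distance = d[idx]
    )
  )
}

#' Annotate mapped cysteines that are not hits
#'
#' In disulfide-rich organisms, proteins with an odd cysteine count often
#' still carry disulfides, with the odd cysteine either coordinating a metal
#' or sitting on the surface (a candidate for an intermolecular disulfide).
#' This classifies each mapped non-hit cysteine:
#' \itemize{
#'   \item `metal_proximal`: CA within 8 Angstrom of a metal HETATM;
#'   \item `surface_candidate`: fewer than 12 neighbouring CA atoms within
#'     10 Angstrom (sparse environment, typical of exposed residues);
#'   \item `buried_unpaired`: otherwise.
#' }
#'
#' @param mapping A `cys_mapping`.
#' @param chain The `structure_chain` the mapping was computed on.
#' @param cutoff Hit cutoff used to define non-hits (default 8).
#' @param metal_cutoff CA-metal distance for `metal_proximal` (default 8).
#' @param neighbor_radius,neighbor_min Surface criterion: fewer than
#'   `neighbor_min` CA neighbours within `neighbor_radius` Angstrom.
#' @return Tibble with `qpos`, `resno`, `annotation`.
#' @export
annotate_odd_case <- function(mapping, chain, cutoff = 8, metal_cutoff = 8,
                              neighbor_radius = 10, neighbor_min = 12) {
  stopifnot(inherits(mapping, "cys_mapping"), inherits(chain, "structure_chain"))
  ph <- proximity_hits(mapping, cutoff)
  non_hits <- mapping$mapped[!(mapping$mapped$qpos %in% ph$hits), , drop = FALSE]
  if (nrow(non_hits) == 0L) {
    return(tibble::tibble(qpos = integer(), resno = integer(), annotation = character()))
  }
  ca <- as.matrix(chain$residues[!is.na(chain$residues$x), c("x", "y", "z")])
  metals <- as.matrix(chain$metals[, c("x", "y", "z")])
  ann <- vapply(seq_len(nrow(non_hits)), function(i) {
    p <- as.numeric(non_hits[i, c("x", "y", "z")])
    if (nrow(metals) > 0L &&
        any(sqrt(colSums((t(metals) - p)^2)) < metal_cutoff)) {
      return("metal_proximal")
    }
    dists <- sqrt(colSums((t(ca) - p)^2))
    n_neighbors <- sum(dists < neighbor_radius) - 1L  # exclude itself
    if (n_neighbors < neighbor_min) "surface_candidate" else "buried_unpaired"
  }, character(1))
  tibble::tibble(qpos = non_hits$qpos, resno = non_hits$resno, annotation = ann)
}
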
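#' Synthetic proteome generator parameters
#'
#' Study conditions for the ground-truth generator. Each synthetic protein
#' derives from one generated structure; a controlled fraction of its
#' cysteines is planted as spatially close pairs (disulfide-like geometry)
#' and the rest as well-separated free thiols, so every pipeline stage can
#' be validated against known truth.
#'
#' @param n_proteins Number of proteins (default 100).
#' @param length_range Inclusive residue-length range (default 120-180).
#' @param true_f Target pooled fraction of eligible cysteines in planted
#'   pairs (default 0.5). The realized fraction recorded in the truth record
#'   is authoritative (discretization shifts it slightly).
#' @param divergence Per-residue substitution rate applied to the query
#'   relative to its source structure, in `[0, 0.5]` (default 0.1). Planted
#'   cysteines are never substituted unless `cys_loss > 0`.
#' @param secreted_fraction Fraction of proteins prefixed with a
#'   signal-peptide motif (default 0.1); these are ground-truth positives
#'   for the secretion filter and are excluded from the truth fraction.
#' @param metal_motif_fraction Fraction of proteins given a CXXC metal motif
#'   with a bound Zn and LINK records (default 0.1). Its cysteines are
#'   closely spaced by construction, so the clustering mask removes them
#'   from mapping eligibility.
#' @param odd_cys_fraction Fraction of proteins given one extra unpaired
#'   cysteine (default 0.05), producing odd whole-protein counts.
#'   Incompatible with `true_f = 1`.
#' @param cys_loss Probability that a planted cysteine is substituted away
#'   in the query (default 0), for probing unmapped-cysteine handling.
#' @param pair_window Sampled CA-CA distance window for planted pairs in
#'   Angstrom (default `c(4, 6.5)`, comfortably inside the 8 Angstrom
#'   criterion).
#' @param free_min_dist Minimum CA distance from a planted free cysteine to
#'   any other cysteine (default 10, outside the criterion).
#' @param organism Organism label for the proteome.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_proteins = 100, length_range = c(120, 180),
                             true_f = 0.5, divergence = 0.1,
                             secreted_fraction = 0.1,
                             metal_motif_fraction = 0.1,
                             odd_cys_fraction = 0.05,
                             cys_loss = 0,
                             pair_window = c(4, 6.5), free_min_dist = 10,
                             organism = "Synthetica calida", seed = 1) {
  fracs <- c(true_f = true_f, divergence = divergence,
             secreted_fraction = secreted_fraction,
             metal_motif_fraction = metal_motif_fraction,
             odd_cys_fraction = odd_cys_fraction, cys_loss = cys_loss)
  if (any(fracs < 0 | fracs > 1)) abort("all fractions must be in [0, 1]")
  if (divergence > 0.5) abort("divergence must be in [0, 0.5]")
  if (true_f == 1 && odd_cys_fraction > 0) {
    abort("infeasible: true_f = 1 cannot be met with odd_cys_fraction > 0")
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         length_range = as.integer(length_range),
         true_f = true_f, divergence = divergence,
         secreted_fraction = secreted_fraction,
         metal_motif_fraction = metal_motif_fraction,
         odd_cys_fraction = odd_cys_fraction,
         cys_loss = cys_loss,
         pair_window = pair_window, free_min_dist = free_min_dist,
         organism = organism, seed = as.integer(seed)),
    class = "generator_params"
  )
}

# Signal-peptide motif satisfying all three heuristic conditions:
# K at position 2 (n-region), 10 leucines/alanines (h-region), and an
# A-G-A-A-S c-region giving a -3/-1 cleavage site at position 17.
SIGNAL_PEPTIDE <- "MKRLLLLLLLLLAGAAS"

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Sample a point at distance r1 from c1 and r2 from c2 (sphere-sphere
# intersection circle). Assumes the circle exists.
sample_circle_point <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c2 - c1)^2))
  u <- (c2 - c1) / d
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h2 <- r1^2 - a^2
  h <- sqrt(max(h2, 0))
  # orthonormal basis perpendicular to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  th <- stats::runif(1, 0, 2 * pi)
  c1 + a * u + h * (cos(th) * v + sin(th) * w)
}

#' Generate one synthetic structure
#'
#' Builds a C-alpha trace as a persistent 3-D walk with 3.8 Angstrom steps
#' and soft self-avoidance (a step is re-sampled, up to a bounded number of
#' retries, if any non-adjacent CA pair would fall below 3.5 Angstrom).
#' Cysteine pairs listed in `cys_pairs` are planted with CA separations
#' drawn inside `pair_window`; free cysteines end at least `free_min_dist`
#' from every other cysteine CA. SSBOND records are emitted for planted
#' pairs; a CXXC metal motif adds a Zn HETATM and LINK records. Only CA
#' atoms are modelled: the mapping criterion is CA-CA distance, so side
#' chains are unnecessary.
#'
#' @param n_residues Chain length.
#' @param cys_pairs List of length-2 integer vectors of 1-based residue
#'   numbers `(i, j)`, `i < j`, pairwise disjoint and non-nested.
#' @param cys_free Integer vector of 1-based free-cysteine residue numbers.
#' @param metal_cxxc Optional 1-based start of a CXXC motif (cysteines at
#'   `p` and `p + 3`, a Zn placed nearby, LINK records written).
#' @param structure_id Up to 4 characters (PDB entry-id convention).
#' @param chain_id Single character chain id.
#' @param pair_window,free_min_dist See [generator_params()].
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @param max_retries Whole-chain retry budget (default 80).
#' @return A `pdb_structure` (see [read_structure()]).
#' @export
generate_structure <- function(n_residues, cys_pairs = list(),
                               cys_free = integer(), metal_cxxc = NULL,
                               structure_id = "S001", chain_id = "A",
                               pair_window = c(4, 6.5), free_min_dist = 10,
                               seed = NULL, max_retries = 80) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      generate_structure(n_residues, cys_pairs, cys_free, metal_cxxc,
                         structure_id, chain_id, pair_window, free_min_dist,
                         seed = NULL, max_retries = max_retries)))
  }
  pairs <- lapply(cys_pairs, as.integer)
  frees <- as.integer(cys_free)
  motif <- if (!is.null(metal_cxxc)) as.integer(metal_cxxc) + c(0L, 3L) else integer(0)
  cys_all <- sort(c(unlist(pairs), frees, motif))
  if (length(cys_all) > 0L && (max(cys_all) > n_residues || min(cys_all) < 1L)) {
    abort("planned cysteine positions do not fit in the chain")
  }
  if (anyDuplicated(cys_all)) abort("planned cysteine positions overlap")

  for (attempt in seq_len(max_retries)) {
    coords <- walk_attempt(n_residues, pairs, pair_window)
    if (is.null(coords)) next
    if (!free_cys_ok(coords, pairs, c(frees, motif), frees, free_min_dist)) next
    return(assemble_structure(n_residues, coords, pairs, frees, motif,
                              structure_id, chain_id))
  }
  abort(sprintf(
    "could not satisfy geometric constraints after %d retries; use a larger chain or fewer planted cysteines",
    max_retries))
}

# One whole-chain attempt; NULL on failure.
walk_attempt <- function(n, pairs, pair_window, step = 3.8, clash = 3.5,
                         step_retries = 30L) {
  coords <- matrix(NA_real_, n, 3)
  coords[1, ] <- c(0, 0, 0)
  prev_dir <- random_unit()
  closers <- vapply(pairs, `[`, integer(1), 2L)
  openers <- vapply(pairs, `[`, integer(1), 1L)

  for (k in 2:n) {
    pi <- match(k, closers)
    placed <- FALSE
    if (!is.na(pi)) {
      # closing residue of a planted pair: land on the sphere-shell
      # intersection so the pair distance falls inside pair_window
      anchor <- coords[openers[pi], ]
      for (t in seq_len(step_retries)) {
        d12 <- sqrt(sum((coords[k - 1, ] - anchor)^2))
        lo <- max(pair_window[1], d12 - step + 0.05, step - d12 + 0.05)
        hi <- min(pair_window[2], d12 + step - 0.05)
        if (lo > hi) break
        rstar <- stats::runif(1, lo, hi)
        cand <- sample_circle_point(coords[k - 1, ], step, anchor, rstar)
        if (clash_ok(coords, k, cand, clash)) {
          coords[k, ] <- cand; placed <- TRUE; break
        }
      }
    } else {
      # guided persistent walk
      active <- which(openers < k & closers > k)
      pull <- c(0, 0, 0); w <- 0
      if (length(active) > 0L) {
        a <- active[which.min(closers[active])]
        anchor <- coords[openers[a], ]
        d <- sqrt(sum((coords[k - 1, ] - anchor)^2))
        remaining <- closers[a] - k          # steps left after placing k
        max_reach <- remaining * step + 9.5  # must stay inside closing range
        if (d > max_reach - 2 * step) {
          w <- 1.6
        } else if (d > max_reach - 4 * step) {
          w <- 0.6
        }
        if (w > 0) pull <- (anchor - coords[k - 1, ]) / max(d, 1e-6)
        if (d < 2.5 && remaining > 1L) { pull <- -pull; w <- 0.8 }
      }
      for (t in seq_len(step_retries)) {
        dir <- 1.2 * prev_dir + w * pull + stats::rnorm(3, sd = 0.8)
        dir <- dir / sqrt(sum(dir^2))
        cand <- coords[k - 1, ] + step * dir
        if (clash_ok(coords, k, cand, clash)) {
          coords[k, ] <- cand; placed <- TRUE; break
        }
      }
    }
    if (!placed) return(NULL)
    prev_dir <- (coords[k, ] - coords[k - 1, ]) / step
  }

  # verify pair geometry (closing construction can fail only via break)
  for (p in pairs) {
    dp <- sqrt(sum((coords[p[1], ] - coords[p[2], ])^2))
    if (dp < pair_window[1] - 1e-9 || dp > pair_window[2] + 1e-9) return(NULL)
  }
  coords
}

clash_ok <- function(coords, k, cand, clash) {
  if (k <= 2L) return(TRUE)
  prior <- coords[seq_len(k - 2L), , drop = FALSE]
  all(rowSums((prior - matrix(cand, nrow(prior), 3, byrow = TRUE))^2) >= clash^2)
}

# every free cysteine must sit >= free_min_dist from every other cysteine CA
free_cys_ok <- function(coords, pairs, all_other_cys, frees, free_min_dist) {
  if (length(frees) == 0L) return(TRUE)
  cys_all <- sort(unique(c(unlist(pairs), all_other_cys)))
  for (fc in frees) {
    others <- setdiff(cys_all, fc)
    if (length(others) == 0L) next
    d <- sqrt(rowSums((coords[others, , drop = FALSE] -
                         matrix(coords[fc, ], length(others), 3, byrow = TRUE))^2))
    if (any(d < free_min_dist)) return(FALSE)
  }
  TRUE
}

assemble_structure <- function(n, coords, pairs, frees, motif,
                               structure_id, chain_id) {
  aa <- sample(setdiff(AA_STANDARD, "C"), n, replace = TRUE)
  aa[c(unlist(pairs), frees, motif)] <- "C"
  residues <- tibble::tibble(
    chain = chain_id,
    resno = seq_len(n),
    icode = " ",
    resname = aa_three(aa),
    aa = aa,
    x = round(coords[, 1], 3), y = round(coords[, 2], 3), z = round(coords[, 3], 3)
  )
  ssbond <- if (length(pairs) > 0L) {
    tibble::tibble(chain1 = chain_id,
                   resno1 = vapply(pairs, `[`, integer(1), 1L),
                   chain2 = chain_id,
                   resno2 = vapply(pairs, `[`, integer(1), 2L))
  } else NULL
  link_cys <- NULL; metals <- NULL
  if (length(motif) > 0L) {
    link_cys <- tibble::tibble(chain = chain_id, resno = motif)
    mid <- (coords[motif[1L], ] + coords[motif[2L], ]) / 2
    zn <- mid + 1.5 * random_unit()
    metals <- tibble::tibble(element = "ZN",
                             x = round(zn[1], 3), y = round(zn[2], 3), z = round(zn[3], 3))
  }
  new_pdb_structure(structure_id, residues, ssbond, link_cys, metals)
}

#' Generate a synthetic proteome with matching structures and ground truth
#'
#' Emulates the survey's real inputs: a proteome whose proteins each derive
#' from a homologous structure, with a controlled pooled fraction of
#' cysteines in disulfide-like pairs, controlled sequence divergence,
#' signal-peptide-bearing proteins, CXXC metal motifs with bound Zn, and
#' odd-cysteine cases. Everything is deterministic given `params$seed`.
#'
#' The realized pooled `true_f` is recorded in the truth record, computed
#' over *eligible* cysteines: planted pairs and frees of non-secreted
#' proteins (secreted proteins are filtered before mapping; CXXC cysteines
#' are masked by the clustering filter and excluded from both sides).
#'
#' @param params A [generator_params()] object.
#' @return An object of class `synthetic_bundle`: list with
#'   \describe{
#'     \item{proteome}{Proteome tibble (as from [read_proteome()]).}
#'     \item{structures}{Named list of `pdb_structure` objects.}
#'     \item{library}{Structure-sequence library tibble.}
#'     \item{truth}{List: `proteins` (per-protein truth tibble), `true_f`
#'       (realized pooled fraction), `params`.}
#'   }
#' @export
generate_proteome <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  withr::with_seed(params$seed, generate_proteome_impl(params))
}

generate_proteome_impl <- function(p) {
  n <- p$n_proteins
  sig_len <- nchar(SIGNAL_PEPTIDE)
  rows <- vector("list", n)
  structs <- vector("list", n)
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    L <- sample(p$length_range[1]:p$length_range[2], 1L)
    paired <- stats::runif(1) < p$true_f
    secreted <- stats::runif(1) < p$secreted_fraction
    metal <- stats::runif(1) < p$metal_motif_fraction
    odd <- stats::runif(1) < p$odd_cys_fraction

    plan <- plan_cys_positions(L, paired, odd, metal)
    sid <- sprintf("S%03d", i)
    st <- generate_structure(L, cys_pairs = plan$pairs, cys_free = plan$frees,
                             metal_cxxc = plan$motif_start,
                             structure_id = sid, chain_id = "A",
                             pair_window = p$pair_window,
                             free_min_dist = p$free_min_dist)
    structs[[i]] <- st

    seq_chars <- strsplit(get_chain(st, "A")$sequence, "")[[1L]]
    cys_struct <- sort(c(unlist(plan$pairs), plan$frees, plan$motif_cys))
    seq_chars <- apply_divergence(seq_chars, cys_struct, p$divergence, p$cys_loss)
    qseq <- paste(seq_chars, collapse = "")
    offset <- 0L
    if (secreted) { qseq <- paste0(SIGNAL_PEPTIDE, qseq); offset <- sig_len }

    id <- sprintf("SYNP%04d", i)
    rows[[i]] <- tibble::tibble(id = id, organism = p$organism, sequence = qseq)
    truth[[i]] <- tibble::tibble(
      id = id,
      source = paste0(sid, "_A"),
      n_pairs = length(plan$pairs),
      n_free = length(plan$frees),
      pair_qpos = list(lapply(plan$pairs, function(pr) pr - 1L + offset)),
      free_qpos = list(plan$frees - 1L + offset),
      secreted = secreted,
      metal = metal,
      odd = odd,
      divergence = p$divergence
    )
  }

  proteome_raw <- dplyr::bind_rows(rows)
  proteome <- new_proteome(proteome_raw$id, proteome_raw$organism,
                           proteome_raw$sequence)
  truth_tbl <- dplyr::bind_rows(truth)
  elig <- !truth_tbl$secreted
  n_pair_cys <- 2L * sum(truth_tbl$n_pairs[elig])
  n_free_cys <- sum(truth_tbl$n_free[elig])
  true_f <- if (n_pair_cys + n_free_cys > 0L) n_pair_cys / (n_pair_cys + n_free_cys) else NA_real_

  names(structs) <- vapply(structs, function(s) s$structure_id, character(1))
  structure(
    list(proteome = proteome,
         structures = structs,
         library = build_structure_library(structs),
         truth = list(proteins = truth_tbl, true_f = true_f, params = p)),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d proteins, %d structures, realized true_f = %.3f\n",
              nrow(x$proteome), length(x$structures), x$truth$true_f))
  invisible(x)
}

# Choose 1-based structure positions for planted cysteines: one pair
# (span 15-35) or two frees, an optional extra odd free, an optional CXXC
# motif. All planted positions (motif aside) are kept > 5 residues apart in
# sequence so the clustering mask leaves them eligible.
plan_cys_positions <- function(L, paired, odd, metal, min_sep = 7L) {
  taken <- integer(0)
  pairs <- list(); frees <- integer(0); motif_start <- NULL

  place <- function(span_lo, span_hi) {
    for (t in 1:200) {
      i <- sample(5:(L - span_hi - 5L), 1L)
      j <- i + sample(span_lo:span_hi, 1L)
      if (all(abs(c(i, j) - rep(taken, each = 2L)) >= min_sep) || length(taken) == 0L) {
        return(c(i, j))
      }
    }
    NULL
  }
  place_one <- function() {
    for (t in 1:200) {
      i <- sample(5:(L - 5L), 1L)
      if (length(taken) == 0L || all(abs(i - taken) >= min_sep)) return(i)
    }
    NULL
  }

  if (paired) {
    pr <- place(15L, 35L)
    if (is.null(pr)) abort("cannot place cysteine pair; chain too short")
    pairs <- list(pr); taken <- c(taken, pr)
  } else {
    for (k in 1:2) {
      fc <- place_one()
      if (is.null(fc)) abort("cannot place free cysteine; chain too short")
      frees <- c(frees, fc); taken <- c(taken, fc)
    }
  }
  if (odd) {
    fc <- place_one()
    if (!is.null(fc)) { frees <- c(frees, fc); taken <- c(taken, fc) }
  }
  motif_cys <- integer(0)
  if (metal) {
    for (t in 1:200) {
      ms <- sample(5:(L - 10L), 1L)
      if (all(abs(c(ms, ms + 3L) - rep(taken, each = 2L)) >= min_sep) ||
          length(taken) == 0L) {
        motif_start <- ms; motif_cys <- ms + c(0L, 3L)
        taken <- c(taken, motif_cys)
        break
      }
    }
  }
  list(pairs = pairs, frees = sort(frees), motif_start = motif_start,
       motif_cys = motif_cys)
}

# Substitute non-cysteine residues at the divergence rate; optionally lose
# planted cysteines at rate cys_loss.
apply_divergence <- function(chars, cys_pos, divergence, cys_loss) {
  n <- length(chars)
  mutable <- setdiff(seq_len(n), cys_pos)
  if (divergence > 0 && length(mutable) > 0L) {
    hit <- mutable[stats::runif(length(mutable)) < divergence]
    if (length(hit) > 0L) {
      repl <- vapply(chars[hit], function(a) {
        sample(setdiff(setdiff(AA_STANDARD, "C"), a), 1L)
      }, character(1))
      chars[hit] <- repl
    }
  }
  if (cys_loss > 0 && length(cys_pos) > 0L) {
    lost <- cys_pos[stats::runif(length(cys_pos)) < cys_loss]
    if (length(lost) > 0L) {
      chars[lost] <- sample(setdiff(AA_STANDARD, "C"), length(lost), replace = TRUE)
    }
  }
  chars
}

#' Generate a sequence-only random proteome
#'
#' Companion generator for the parity analysis: no structures, just
#' sequences with controlled cysteine statistics. `"independent"` assigns
#' each residue to cysteine independently (rate `cys_rate`), the null model
#' under which no even/odd preference is expected; `"paired"` plants
#' cysteines strictly in pairs (even counts only), the idealised
#' fully-disulfide-bonded proteome.
#'
#' @param n_proteins Number of proteins (default 400).
#' @param length_range Inclusive length range (default 150-200, matching the
#'   parity window).
#' @param mode `"independent"` or `"paired"`.
#' @param cys_rate Per-residue cysteine rate (default 0.03; see the methods
#'   vignette for why the parity statistic needs a rate of this order).
#' @param organism Organism label.
#' @param seed Optional integer seed.
#' @return A proteome tibble.
#' @export
simulate_random_proteome <- function(n_proteins = 400, length_range = c(150, 200),
                                     mode = c("independent", "paired"),
                                     cys_rate = 0.03,
                                     organism = "synthetic control", seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_random_proteome(
      n_proteins, length_range, mode, cys_rate, organism, seed = NULL)))
  }
  lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  if (mode == "independent") {
    probs <- ifelse(AA_STANDARD == "C", cys_rate, (1 - cys_rate) / 19)
    letters_all <- sample(AA_STANDARD, sum(lens), replace = TRUE, prob = probs)
    ends <- cumsum(lens)
    seqs <- substring(paste(letters_all, collapse = ""), ends - lens + 1L, ends)
  } else {
    non_c <- setdiff(AA_STANDARD, "C")
    letters_all <- sample(non_c, sum(lens), replace = TRUE)
    ends <- cumsum(lens)
    seqs <- substring(paste(letters_all, collapse = ""), ends - lens + 1L, ends)
    seqs <- vapply(seq_along(seqs), function(i) {
      L <- lens[i]
      n_pairs <- stats::rbinom(1L, size = floor(L / 2), prob = cys_rate)
      if (n_pairs == 0L) return(seqs[i])
      pos <- sample(L, 2L * n_pairs)
      ch <- strsplit(seqs[i], "")[[1L]]
      ch[pos] <- "C"
      paste(ch, collapse = "")
    }, character(1))
  }
  new_proteome(sprintf("RND%05d", seq_len(n_proteins)), organism, seqs)
}

#' Write a synthetic bundle to disk
#'
#' Emits `proteome.fasta`, `library.fasta`, one PDB file per structure under
#' `structures/`, and `truth.tsv` (1-based positions in report output).
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(file.path(dir, "structures"), recursive = TRUE, showWarnings = FALSE)
  write_proteome(bundle$proteome, file.path(dir, "proteome.fasta"))
  lib <- bundle$library
  write_proteome(tibble::tibble(id = lib$target_id, organism = NA_character_,
                                sequence = lib$sequence),
                 file.path(dir, "library.fasta"), with_organism = FALSE)
  for (s in bundle$structures) {
    write_structure(s, file.path(dir, "structures", paste0(s$structure_id, ".pdb")))
  }
  tr <- bundle$truth$proteins
  tr_out <- tibble::tibble(
    id = tr$id, source = tr$source, n_pairs = tr$n_pairs, n_free = tr$n_free,
    pair_res = vapply(tr$pair_qpos, function(x)
      paste(vapply(x, function(pr) paste(pr + 1L, collapse = "-"), character(1)),
            collapse = ","), character(1)),
    free_res = vapply(tr$free_qpos, function(x) paste(x + 1L, collapse = ","),
                      character(1)),
    secreted = tr$secreted, metal = tr$metal, odd = tr$odd,
    divergence = tr$divergence
  )
  meta <- c(sprintf("# cysmapr truth record"),
            sprintf("# realized_true_f\t%.6f", bundle$truth$true_f),
            sprintf("# seed\t%d", bundle$truth$params$seed))
  writeLines(meta, file.path(dir, "truth.tsv"))
  readr::write_tsv(tr_out, file.path(dir, "truth.tsv"), append = TRUE,
                   col_names = TRUE)
  invisible(dir)
}
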
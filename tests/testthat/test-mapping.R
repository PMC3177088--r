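# A toy chain where residues 1 and 2 are 5.1 A apart and residue 8 is far.
toy_mapping <- function() {
  coords <- rbind(c(0, 0, 0), c(5.1, 0, 0), c(40, 0, 0), c(44, 0, 0),
                  c(80, 0, 0), c(84, 0, 0), c(120, 0, 0), c(160, 0, 0))
  st <- make_chain_structure(coords, cys_at = c(1, 2, 8), structure_id = "TOY1")
  ch <- get_chain(st, "A")
  aln <- global_realign(ch$sequence, ch$sequence, query_id = "toy")
  map_cysteines(aln, ch, eligible_cys = c(0L, 1L, 7L))
}

test_that("cysteines aligned to CA-bearing residues are mapped with coordinates", {
  mp <- toy_mapping()
  expect_equal(nrow(mp$mapped), 3L)
  expect_equal(mp$unmapped, integer(0))
  expect_equal(mp$distances["0", "1"], 5.1)
})

test_that("cysteines aligned into gaps or onto CA-less residues are unmapped", {
  st <- make_chain_structure(line_coords(10), cys_at = c(3, 7), structure_id = "GAP1")
  ch <- get_chain(st, "A")
  # query has an insertion relative to the chain: extra stretch incl. a cysteine
  qseq <- paste0(substr(ch$sequence, 1, 5), "WWCWW", substr(ch$sequence, 6, 10))
  aln <- global_realign(qseq, ch$sequence, query_id = "ins")
  mp <- map_cysteines(aln, ch, eligible_cys = c(2L, 7L, 11L))
  expect_true(7L %in% mp$unmapped)       # the inserted cysteine has no target
  expect_setequal(mp$mapped$qpos, c(2L, 11L))

  # residue without CA
  st2 <- st
  st2$residues$x[7] <- NA_real_
  ch2 <- get_chain(st2, "A")
  aln2 <- global_realign(ch$sequence, ch2$sequence)
  mp2 <- map_cysteines(aln2, ch2, eligible_cys = c(2L, 6L))
  expect_equal(mp2$unmapped, 6L)
})

test_that("mapping requires alignment and chain to agree on target length", {
  st <- make_chain_structure(line_coords(10), cys_at = 3, structure_id = "LEN1")
  ch <- get_chain(st, "A")
  aln <- global_realign("MKVL", "MKVL")
  expect_error(map_cysteines(aln, ch, 0L), "does not match")
})

test_that("the target residue need not be a cysteine", {
  st <- make_chain_structure(line_coords(10), cys_at = integer(), structure_id = "NC1")
  ch <- get_chain(st, "A")
  aln <- global_realign(ch$sequence, ch$sequence)
  mp <- map_cysteines(aln, ch, eligible_cys = c(2L, 3L))  # ALA targets
  expect_equal(nrow(mp$mapped), 2L)
})

test_that("three mutually close cysteines count as 3 hits and 3 pairs", {
  coords <- rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 4.3, 0), c(100, 0, 0))
  st <- make_chain_structure(coords, cys_at = 1:3, structure_id = "CLQ1")
  ch <- get_chain(st, "A")
  mp <- map_cysteines(self_alignment(st), ch, eligible_cys = 0:2)
  ph <- proximity_hits(mp, cutoff = 8)
  expect_equal(ph$n_hits, 3L)                 # counted once each, not 6
  expect_equal(nrow(ph$predicted_pairs), 3L)  # the 3-clique edges
})

test_that("the cutoff is strict: 9 A apart at cutoff 8 is no hit", {
  st <- make_chain_structure(rbind(c(0, 0, 0), c(9, 0, 0)), cys_at = 1:2,
                             structure_id = "B9")
  mp <- map_cysteines(self_alignment(st), get_chain(st), eligible_cys = 0:1)
  expect_equal(proximity_hits(mp, 8)$n_hits, 0L)
  st2 <- make_chain_structure(rbind(c(0, 0, 0), c(8, 0, 0)), cys_at = 1:2,
                              structure_id = "B8")
  mp2 <- map_cysteines(self_alignment(st2), get_chain(st2), eligible_cys = 0:1)
  expect_equal(proximity_hits(mp2, 8)$n_hits, 0L)   # exactly 8 is not < 8
  expect_equal(proximity_hits(mp2, 8.01)$n_hits, 2L)
})

test_that("hit counting equals brute-force neighbour scanning on random point sets", {
  set.seed(107)
  for (k in 1:80) {
    n <- sample(2:12, 1)
    xyz <- matrix(stats::runif(3 * n, 0, 25), n, 3)
    st <- make_chain_structure(xyz, cys_at = seq_len(n),
                               structure_id = "RND1")
    mp <- map_cysteines(self_alignment(st), get_chain(st), eligible_cys = 0:(n - 1))
    cutoff <- stats::runif(1, 4, 12)
    ph <- proximity_hits(mp, cutoff)
    bf <- brute_force_hits(xyz, cutoff)
    expect_equal(ph$n_hits, bf$n_hits)
    expect_equal(nrow(ph$predicted_pairs), bf$pairs)
    expect_true(all(ph$predicted_pairs$distance < cutoff))
    expect_true(all(ph$hits %in% mp$mapped$qpos))
  }
})

test_that("hit count is permutation-symmetric and monotone in the cutoff", {
  set.seed(109)
  n <- 10
  xyz <- matrix(stats::runif(3 * n, 0, 20), n, 3)
  st <- make_chain_structure(xyz, cys_at = 1:n, structure_id = "PRM1")
  mp <- map_cysteines(self_alignment(st), get_chain(st), eligible_cys = 0:(n - 1))
  perm <- sample(n)
  st2 <- make_chain_structure(xyz[perm, , drop = FALSE], cys_at = 1:n,
                              structure_id = "PRM2")
  mp2 <- map_cysteines(self_alignment(st2), get_chain(st2), eligible_cys = 0:(n - 1))
  counts <- vapply(c(3, 5, 8, 12, 20), function(cu) proximity_hits(mp, cu)$n_hits, integer(1))
  counts2 <- vapply(c(3, 5, 8, 12, 20), function(cu) proximity_hits(mp2, cu)$n_hits, integer(1))
  expect_identical(counts, counts2)
  expect_true(all(diff(counts) >= 0))
})

test_that("self-mapping reproduces a direct coordinate scan of the structure", {
  set.seed(113)
  st <- generate_structure(90, cys_pairs = list(c(10L, 30L), c(50L, 75L)),
                           cys_free = 85L, structure_id = "SLF1")
  ch <- get_chain(st)
  cys_res <- ch$residues[ch$residues$resname == "CYS", ]
  mp <- map_cysteines(self_alignment(st), ch, eligible_cys = cys_res$resno - 1L)
  ph <- proximity_hits(mp, 8)
  bf <- brute_force_hits(as.matrix(cys_res[, c("x", "y", "z")]), 8)
  expect_equal(ph$n_hits, bf$n_hits)
  expect_equal(ph$n_hits, 4L)  # the two planted pairs; the free one is distant
})

test_that("odd-case annotation distinguishes metal, surface and buried cysteines", {
  # lone pairless cysteine 4 A from a Zn
  st <- make_chain_structure(line_coords(6, 10), cys_at = 1L, structure_id = "MT1",
                             metals = tibble::tibble(element = "ZN", x = 4, y = 0, z = 0))
  mp <- map_cysteines(self_alignment(st), get_chain(st), eligible_cys = 0L)
  ann <- annotate_odd_case(mp, get_chain(st))
  expect_equal(ann$annotation, "metal_proximal")

  # chain end of an extended trace: few neighbours -> surface candidate
  st2 <- make_chain_structure(line_coords(40), cys_at = 1L, structure_id = "SF1")
  mp2 <- map_cysteines(self_alignment(st2), get_chain(st2), eligible_cys = 0L)
  ann2 <- annotate_odd_case(mp2, get_chain(st2))
  expect_equal(ann2$annotation, "surface_candidate")

  # dense cluster around the cysteine, no metal -> buried
  cl <- rbind(c(0, 0, 0),
              as.matrix(expand.grid(x = c(-4, 0, 4), y = c(-4, 0, 4), z = c(-4, 4))))
  st3 <- make_chain_structure(cl, cys_at = 1L, structure_id = "BR1")
  mp3 <- map_cysteines(self_alignment(st3), get_chain(st3), eligible_cys = 0L)
  ann3 <- annotate_odd_case(mp3, get_chain(st3))
  expect_equal(ann3$annotation, "buried_unpaired")

  # neighbour counting matches a brute-force scan
  ca <- rbind(c(0, 0, 0), line_coords(30)[-1, ] + 2)
  st4 <- make_chain_structure(ca, cys_at = 1L, structure_id = "NB1")
  n_close <- sum(sqrt(rowSums((ca[-1, , drop = FALSE] -
                                 matrix(ca[1, ], 29, 3, byrow = TRUE))^2)) < 10)
  mp4 <- map_cysteines(self_alignment(st4), get_chain(st4), eligible_cys = 0L)
  ann4 <- annotate_odd_case(mp4, get_chain(st4))
  expect_equal(ann4$annotation, if (n_close < 12) "surface_candidate" else "buried_unpaired")
})
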
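test_that("minimal hand-written PDB entry parses correctly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_text(), f)
  st <- read_structure(f)
  expect_equal(st$structure_id, "1ABC")
  expect_equal(nrow(st$residues), 3L)
  expect_equal(st$residues$resname, c("CYS", "GLY", "CYS"))
  expect_equal(st$residues$x, c(0, 3.8, 5.5))
  expect_equal(st$ssbond$resno1, 1L)
  expect_equal(st$ssbond$resno2, 3L)
  expect_equal(nrow(st$metals), 0L)
})

test_that("parser errors are informative", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    X", "END"), f)
  expect_error(read_structure(f), "no ATOM records")

  writeLines(c("ATOM      1  CA  CYS A   1       0.000"), f)
  expect_error(read_structure(f), "malformed fixed-column line 1")

  writeLines(c(minimal_pdb_text()[3],
               "ATOM      2  CA  GLY A   2       xxx.xxx   0.000   0.000  1.00  0.00           C"),
             f)
  expect_error(read_structure(f), "malformed fixed-column line 2")
})

test_that("coordinate parsing agrees with bio3d on a generated entry", {
  skip_if_not_installed("bio3d")
  st <- generate_structure(40, cys_pairs = list(c(5L, 25L)), cys_free = 35L,
                           structure_id = "XCHK", seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, f)
  ours <- read_structure(f)
  ref <- bio3d::read.pdb(f)
  ca <- ref$atom[ref$atom$elety == "CA" & ref$atom$type == "ATOM", ]
  expect_equal(nrow(ours$residues), nrow(ca))
  expect_equal(ours$residues$x, ca$x)
  expect_equal(ours$residues$y, ca$y)
  expect_equal(ours$residues$z, ca$z)
  expect_equal(ours$residues$resno, ca$resno)
  expect_equal(ours$residues$resname, ca$resid)
})

test_that("altloc duplicates keep the first occurrence", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA ACYS A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BCYS A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C"), f)
  st <- read_structure(f)
  expect_equal(nrow(st$residues), 2L)
  expect_equal(st$residues$x[1], 0)
})

test_that("f' follows the SSBOND/LINK/metal rules", {
  # 10 CYS on a line, spread far apart; 4 in SSBOND, 2 in LINK
  st <- make_chain_structure(line_coords(10, step = 20), cys_at = 1:10,
                             structure_id = "F1",
                             ssbond = tibble::tibble(chain1 = "A", resno1 = c(1L, 3L),
                                                     chain2 = "A", resno2 = c(2L, 4L)),
                             link_cys = tibble::tibble(chain = "A", resno = c(5L, 6L)))
  s <- structure_disulfide_fraction(list(st), dedup_identity = NULL)
  expect_equal(s$n_cys_considered, 8L)
  expect_equal(s$n_cys_disulfide, 4L)
  expect_equal(s$f_prime, 0.5)

  # every cysteine bonded -> f' = 1
  st2 <- make_chain_structure(line_coords(4, 20), cys_at = 1:4, structure_id = "F2",
                              ssbond = tibble::tibble(chain1 = "A", resno1 = c(1L, 3L),
                                                      chain2 = "A", resno2 = c(2L, 4L)))
  expect_equal(structure_disulfide_fraction(list(st2), dedup_identity = NULL)$f_prime, 1)
})

test_that("Zn/Fe entries are excluded wholesale and never shift f'", {
  plain <- make_chain_structure(line_coords(6, 20), cys_at = 1:4, structure_id = "P1",
                                ssbond = tibble::tibble(chain1 = "A", resno1 = 1L,
                                                        chain2 = "A", resno2 = 2L))
  zn <- make_chain_structure(line_coords(6, 20), cys_at = 1:6, structure_id = "Z1",
                             ssbond = tibble::tibble(chain1 = "A", resno1 = c(1L, 3L, 5L),
                                                     chain2 = "A", resno2 = c(2L, 4L, 6L)),
                             metals = tibble::tibble(element = "ZN", x = 0, y = 0, z = 5))
  base <- structure_disulfide_fraction(list(plain), dedup_identity = NULL)
  with_zn <- structure_disulfide_fraction(list(plain, zn), dedup_identity = NULL)
  expect_equal(with_zn$n_cys_considered, base$n_cys_considered)
  expect_equal(with_zn$n_cys_disulfide, base$n_cys_disulfide)
  expect_equal(with_zn$n_excluded_metal, 1L)

  # exclusion is configurable: not excluding Zn changes the tallies
  keep_zn <- structure_disulfide_fraction(list(plain, zn), exclude_metals = "FE",
                                          dedup_identity = NULL)
  expect_equal(keep_zn$n_cys_considered, base$n_cys_considered + 6L)

  # all entries metal-bound -> error
  expect_error(structure_disulfide_fraction(list(zn)), "no eligible cysteines")
})

test_that("f' is invariant under entry reordering", {
  set.seed(7)
  structs <- lapply(1:6, function(i) {
    generate_structure(50, cys_pairs = list(c(10L, 30L)), cys_free = 42L,
                       structure_id = sprintf("R%02d", i))
  })
  a <- structure_disulfide_fraction(structs)
  b <- structure_disulfide_fraction(rev(structs))
  expect_equal(a$f_prime, b$f_prime)
  expect_equal(a$n_cys_considered, b$n_cys_considered)
})

test_that("f' on generated fixtures equals the hand-computed truth ratio", {
  set.seed(31)
  n_ss <- 0L; n_free <- 0L
  structs <- list()
  for (i in 1:12) {
    npair <- sample(0:2, 1); nfree <- sample(0:2, 1)
    if (npair + nfree == 0) npair <- 1
    pairs <- list(); taken <- integer(0)
    starts <- c(5L, 55L)
    for (p in seq_len(npair)) pairs[[p]] <- c(starts[p], starts[p] + 20L)
    frees <- if (nfree > 0) seq(100L, by = 12L, length.out = nfree) else integer(0)
    structs[[i]] <- generate_structure(130, cys_pairs = pairs, cys_free = frees,
                                       structure_id = sprintf("T%02d", i))
    n_ss <- n_ss + 2L * npair
    n_free <- n_free + nfree
  }
  s <- structure_disulfide_fraction(structs, dedup_identity = NULL)
  expect_equal(s$n_cys_disulfide, n_ss)
  expect_equal(s$n_cys_considered, n_ss + n_free)
  expect_equal(s$f_prime, n_ss / (n_ss + n_free))
})

test_that("near-duplicate chains collapse to the first representative", {
  st <- generate_structure(60, cys_pairs = list(c(10L, 30L)), structure_id = "D1",
                           seed = 77)
  # identical copy under a different id: must not double-count
  st2 <- st
  st2$structure_id <- "D2"
  one <- structure_disulfide_fraction(list(st))
  two <- structure_disulfide_fraction(list(st, st2))
  expect_equal(two$n_cys_considered, one$n_cys_considered)
  expect_equal(two$f_prime, one$f_prime)
})
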
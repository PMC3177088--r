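test_that("generated structures satisfy the planted geometry", {
  for (seed in c(1, 2, 3)) {
    st <- generate_structure(70, cys_pairs = list(c(10L, 40L)), cys_free = 60L,
                             structure_id = "G001", seed = seed)
    r <- st$residues
    xyz <- as.matrix(r[, c("x", "y", "z")])
    d_pair <- sqrt(sum((xyz[10, ] - xyz[40, ])^2))
    expect_gte(d_pair, 4.0)
    expect_lte(d_pair, 6.5)
    d_free <- sqrt(rowSums((xyz[c(10, 40), , drop = FALSE] -
                              matrix(xyz[60, ], 2, 3, byrow = TRUE))^2))
    expect_true(all(d_free >= 10))
    # consecutive CA spacing is the canonical 3.8 A (coordinates are written
    # at PDB precision, 3 decimals)
    steps <- sqrt(rowSums(diff(xyz)^2))
    expect_true(all(abs(steps - 3.8) < 0.01))
    expect_equal(st$ssbond$resno1, 10L)
    expect_equal(st$ssbond$resno2, 40L)
  }
})

test_that("no planted cysteines means no SSBOND records", {
  st <- generate_structure(30, structure_id = "G002", seed = 5)
  expect_equal(nrow(st$ssbond), 0L)
  expect_false(any(st$residues$resname == "CYS"))
})

test_that("generation is deterministic: same seed gives byte-identical files", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(generate_structure(50, cys_pairs = list(c(8L, 30L)),
                                     structure_id = "G003", seed = 9), f1)
  write_structure(generate_structure(50, cys_pairs = list(c(8L, 30L)),
                                     structure_id = "G003", seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))

  b1 <- generate_proteome(generator_params(n_proteins = 8, seed = 15))
  b2 <- generate_proteome(generator_params(n_proteins = 8, seed = 15))
  expect_identical(b1$proteome, b2$proteome)
  expect_identical(b1$truth$proteins, b2$truth$proteins)
})

test_that("impossible geometry fails with advice rather than looping forever", {
  # two free cysteines 2 residues apart can never be 10 A apart on a
  # 3.8 A-step trace
  expect_error(generate_structure(20, cys_free = c(5L, 7L), seed = 1,
                                  max_retries = 5),
               "larger chain|constraints")
})

test_that("infeasible parameter combinations are rejected", {
  expect_error(generator_params(true_f = 1, odd_cys_fraction = 0.2), "infeasible")
  expect_error(generator_params(true_f = -0.1), "fractions")
})

test_that("generated structures re-parse through the structure reader unchanged", {
  bundle <- generate_proteome(generator_params(n_proteins = 10, seed = 33))
  dir <- withr::local_tempdir()
  write_bundle(bundle, dir)
  for (sid in names(bundle$structures)) {
    back <- read_structure(file.path(dir, "structures", paste0(sid, ".pdb")))
    orig <- bundle$structures[[sid]]
    expect_equal(back$residues$resname, orig$residues$resname)
    expect_equal(back$residues$x, orig$residues$x)
    expect_equal(back$ssbond, orig$ssbond)
    expect_equal(back$link_cys[order(back$link_cys$resno), ],
                 orig$link_cys[order(orig$link_cys$resno), ],
                 ignore_attr = TRUE)
    expect_equal(sort(bound_metals(back)), sort(bound_metals(orig)))
  }
})

test_that("realized true_f is self-consistent with the per-protein plantings", {
  bundle <- generate_proteome(generator_params(n_proteins = 60, true_f = 0.4,
                                               seed = 51))
  tr <- bundle$truth$proteins
  elig <- !tr$secreted
  recount <- 2 * sum(tr$n_pairs[elig]) / (2 * sum(tr$n_pairs[elig]) + sum(tr$n_free[elig]))
  expect_equal(bundle$truth$true_f, recount)

  # positions recorded in truth are cysteines in the emitted sequences
  for (i in sample(nrow(tr), 10)) {
    ch <- strsplit(bundle$proteome$sequence[bundle$proteome$id == tr$id[i]], "")[[1]]
    pos <- c(unlist(tr$pair_qpos[[i]]), tr$free_qpos[[i]])
    if (length(pos) > 0) expect_true(all(ch[pos + 1] == "C"))
  }
})

test_that("divergence preserves planted cysteines and hits the requested rate", {
  p <- generator_params(n_proteins = 25, divergence = 0.2, secreted_fraction = 0,
                        seed = 61)
  bundle <- generate_proteome(p)
  tr <- bundle$truth$proteins
  rates <- vapply(seq_len(nrow(tr)), function(i) {
    src <- get_chain(bundle$structures[[sub("_A$", "", tr$source[i])]])$sequence
    q <- bundle$proteome$sequence[i]
    mean(strsplit(src, "")[[1]] != strsplit(q, "")[[1]])
  }, numeric(1))
  expect_gt(mean(rates), 0.1)
  expect_lt(mean(rates), 0.3)
})

test_that("sequence-only generator controls cysteine statistics", {
  ind <- simulate_random_proteome(300, mode = "independent", cys_rate = 0.03,
                                  seed = 71)
  expect_equal(nrow(ind), 300L)
  rate <- sum(ind$n_cys) / sum(ind$length)
  expect_gt(rate, 0.02); expect_lt(rate, 0.04)

  par <- simulate_random_proteome(300, mode = "paired", seed = 73)
  expect_true(all(par$n_cys %% 2 == 0))
})
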
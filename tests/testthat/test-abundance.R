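test_that("per-protein fraction follows hits/mapped with degenerate cases", {
  st <- make_chain_structure(rbind(c(0, 0, 0), c(5, 0, 0)), cys_at = 1:2,
                             structure_id = "PF1")
  mp <- map_cysteines(self_alignment(st), get_chain(st), eligible_cys = 0:1)
  pf <- protein_f(mp)
  expect_equal(pf$n_hits, 2L)
  expect_equal(pf$fraction, 1)

  # a single mapped cysteine can never be a hit: enumerate all 1-point cases
  for (d in c(1, 5, 50)) {
    st1 <- make_chain_structure(matrix(c(d, 0, 0), 1, 3), cys_at = 1L,
                                structure_id = "PF2")
    mp1 <- map_cysteines(self_alignment(st1), get_chain(st1), eligible_cys = 0L)
    pf1 <- protein_f(mp1)
    expect_equal(pf1$n_hits, 0L)
    expect_equal(pf1$fraction, 0)
  }

  # nothing mapped -> undefined fraction, zero contribution
  st0 <- make_chain_structure(line_coords(5), cys_at = 2L, structure_id = "PF0")
  mp0 <- map_cysteines(self_alignment(st0), get_chain(st0), eligible_cys = integer(0))
  pf0 <- protein_f(mp0)
  expect_equal(pf0$n_mapped, 0L)
  expect_true(is.na(pf0$fraction))
})

test_that("proteome f is the pooled ratio, not the mean of per-protein fractions", {
  per <- tibble::tibble(n_hits = c(4L, 0L, 20L), n_mapped = c(4L, 8L, 35L))
  s <- proteome_f(per, label = "pool")
  expect_equal(s$f, 24 / 47)
  expect_false(isTRUE(all.equal(s$f, mean(c(1, 0, 20 / 35)))))

  # published worked examples are arithmetic checks of the same ratio
  expect_equal(proteome_f(tibble::tibble(n_hits = 4L, n_mapped = 4L), "v1")$f, 1)
  expect_equal(round(proteome_f(tibble::tibble(n_hits = 20L, n_mapped = 35L), "v2")$f, 2),
               0.57)

  expect_error(proteome_f(tibble::tibble(n_hits = 0L, n_mapped = 0L)),
               "no mapped cysteines")
})

test_that("pooled f is invariant to how proteins are batched", {
  set.seed(127)
  per <- tibble::tibble(n_mapped = sample(0:6, 40, TRUE))
  per$n_hits <- vapply(per$n_mapped, function(m) if (m < 2) 0L else as.integer(sample(0:m, 1)),
                       integer(1))
  whole <- proteome_f(per, "all")$f
  split1 <- proteome_f(per[1:13, ], "a")
  split2 <- proteome_f(per[14:40, ], "b")
  pooled <- (split1$n_hits + split2$n_hits) / (split1$m + split2$m)
  expect_equal(whole, pooled)
  expect_equal(whole, sum(per$n_hits) / sum(per$n_mapped))
})

test_that("abundance tiers use strict thresholds at 0.15/0.25/0.35", {
  expect_equal(classify_abundance(c(0, 0.15, 0.16, 0.25, 0.26, 0.35, 0.36, 1)),
               c("background", "background", "significant", "significant",
                 "high", "high", "very_high", "very_high"))
})

test_that("strain dedup removes within-tolerance strains against the parent", {
  sm <- tibble::tibble(label = c("sp1 parent", "sp1 strainA", "sp1 strainB",
                                 "sp2 parent"),
                       n_proteins_mapped = c(1000L, 1050L, 1200L, 500L))
  species <- c("sp1", "sp1", "sp1", "sp2")
  kept <- dedup_strains(sm, species)
  expect_equal(kept$label, c("sp1 parent", "sp1 strainB", "sp2 parent"))

  # brute-force application of the rule on random strain sets
  set.seed(131)
  for (k in 1:25) {
    n <- sample(2:12, 1)
    sp <- sample(c("a", "b", "c"), n, TRUE)
    cnt <- sample(100:2000, n, TRUE)
    sm2 <- tibble::tibble(label = sprintf("s%02d", 1:n), n_proteins_mapped = cnt)
    tol <- stats::runif(1, 0, 0.3)
    kept2 <- dedup_strains(sm2, sp, tol)
    keep_bf <- logical(n)
    for (s in unique(sp)) {
      idx <- which(sp == s)
      keep_bf[idx[1]] <- TRUE
      for (i in idx[-1]) keep_bf[i] <- abs(cnt[i] - cnt[idx[1]]) > tol * cnt[idx[1]]
    }
    expect_identical(kept2$label, sm2$label[keep_bf])
  }
})

test_that("f/f' comparison reproduces the textbook correlation", {
  ident <- tibble::tibble(f = c(0.1, 0.4, 0.8), f_prime = c(0.1, 0.4, 0.8))
  expect_equal(compare_f_fprime(ident)$r, 1)

  anti <- tibble::tibble(f = c(0.1, 0.5, 0.3), f_prime = c(0.5, 0.1, 0.3))
  expect_equal(compare_f_fprime(anti)$r, -1)

  set.seed(137)
  rnd <- tibble::tibble(f = stats::runif(20), f_prime = stats::runif(20))
  # direct covariance-formula oracle
  cov_xy <- mean(rnd$f * rnd$f_prime) - mean(rnd$f) * mean(rnd$f_prime)
  r_direct <- cov_xy / sqrt((mean(rnd$f^2) - mean(rnd$f)^2) *
                              (mean(rnd$f_prime^2) - mean(rnd$f_prime)^2))
  expect_equal(compare_f_fprime(rnd)$r, r_direct, tolerance = 1e-12)

  expect_error(compare_f_fprime(ident[1:2, ]), "at least 3")
})
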
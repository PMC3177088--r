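# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: alignment scores come from exhaustive
# enumeration, neighbour counts from O(n^2) scans, p-values from direct
# summation of the binomial mass function.

# ---- alignment --------------------------------------------------------------

# Exhaustive optimal alignment score with affine gaps (gap of length L costs
# open + L*ext), by plain recursive enumeration of alignment columns (no
# dynamic-programming tables). free_ends = TRUE is overlap alignment: a
# prefix of ONE sequence may be skipped free (enumerated as the start
# point), and a suffix of ONE sequence is free (recursion may terminate as
# soon as either sequence is exhausted).
brute_force_align_score <- function(a, b, sub, open = 11, ext = 1,
                                    free_ends = TRUE) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)

  # prev: 0 = match column, 1 = gap-in-b run, 2 = gap-in-a run
  rec <- function(i, j, prev) {
    if (free_ends) {
      if (i > n || j > m) return(0)  # remaining tail of the other seq free
    } else {
      if (i > n && j > m) return(0)
    }
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= n) {
      best <- max(best, -(ext + if (prev == 1L) 0 else open) + rec(i + 1L, j, 1L))
    }
    if (j <= m) {
      best <- max(best, -(ext + if (prev == 2L) 0 else open) + rec(i, j + 1L, 2L))
    }
    best
  }

  if (!free_ends) return(rec(1L, 1L, 0L))
  # free prefix of one sequence: enumerate every start point
  best <- -Inf
  for (i1 in 1:(n + 1L)) best <- max(best, rec(i1, 1L, 0L))
  for (j1 in 1:(m + 1L)) best <- max(best, rec(1L, j1, 0L))
  best
}

# ---- geometry ---------------------------------------------------------------

# O(n^2) count of points having at least one other point strictly closer
# than cutoff, plus the list of close pairs.
brute_force_hits <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(list(n_hits = 0L, pairs = 0L))
  hit <- logical(n); npairs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < cutoff) { hit[i] <- TRUE; hit[j] <- TRUE; npairs <- npairs + 1L }
    }
  }
  list(n_hits = sum(hit), pairs = npairs)
}

# ---- filters ----------------------------------------------------------------

# All-pairs masking oracle: drop every position with a partner at |i-j| <= s.
brute_force_mask <- function(pos, s) {
  keep <- vapply(seq_along(pos), function(k) {
    all(abs(pos[-k] - pos[k]) > s)
  }, logical(1))
  pos[keep]
}

# ---- statistics -------------------------------------------------------------

# Two-sided exact binomial p-value at p = 0.5 by direct PMF summation:
# sum of all outcome probabilities not exceeding that of the observed count.
binom_p_direct <- function(k, n, p = 0.5) {
  pm <- vapply(0:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x), numeric(1))
  sum(pm[pm <= pm[k + 1] * (1 + 1e-7)])
}

# ---- signal peptide ---------------------------------------------------------

# Independent checker for the three-part signal heuristic (1-based logic,
# written without reference to the package implementation).
signal_oracle <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  c1 <- any(s[1:min(7, n)] %in% c("K", "R"))
  c2 <- FALSE
  if (n >= 11) {
    for (st in 2:min(25, n - 9)) {
      if (sum(s[st:(st + 9)] %in% c("A", "I", "L", "M", "F", "V", "W", "C")) >= 8) c2 <- TRUE
    }
  }
  c3 <- FALSE
  if (n >= 15) {
    for (p in 15:min(40, n)) {
      if (s[p - 3] %in% c("A", "G", "S", "C", "T", "V") &&
          s[p - 1] %in% c("A", "G", "S", "C", "T", "V")) c3 <- TRUE
    }
  }
  n >= 15 && c1 && c2 && c3
}

# ---- misc -------------------------------------------------------------------

random_aa <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E", "G",
                                      "H", "I", "L", "K", "M", "F", "P", "S",
                                      "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

blosum62_test <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})
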
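# Pure-R reference implementations, independent of the package's C++
# kernels, used as oracles.

# LCS length by dynamic programming in plain R, with a pluggable
# equality predicate (for the property-recoded variants).
oracle_lcs_len <- function(a, b, eq = `==`) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- if (eq(a[i], b[j])) d[i, j] + 1L
                         else max(d[i, j + 1], d[i + 1, j])
    }
  }
  d[n + 1, m + 1]
}

# LCS length by exhaustive enumeration of all subsequences of the
# shorter string (feasible for 7-mers: 2^7 subsets).
oracle_lcs_enum <- function(a, b) {
  if (nchar(b) < nchar(a)) { tmp <- a; a <- b; b <- tmp }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  is_subseq <- function(s, t) {
    if (length(s) == 0) return(TRUE)
    j <- 1
    for (ch in t) {
      if (ch == s[j]) {
        j <- j + 1
        if (j > length(s)) return(TRUE)
      }
    }
    FALSE
  }
  best <- 0
  for (mask in 0:(2^length(av) - 1)) {
    s <- av[bitwAnd(mask, 2^(seq_along(av) - 1)) > 0]
    if (length(s) > best && is_subseq(s, bv)) best <- length(s)
  }
  best
}

# Indel-only edit distance (substitutions forbidden) by DP.
oracle_indel_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- if (a[i] == b[j]) d[i, j]
                         else min(d[i, j + 1], d[i + 1, j]) + 1L
    }
  }
  d[n + 1, m + 1]
}

# Brute-force adjacency under plain LCS distance.
oracle_adjacency <- function(seqs, max_distance = 4) {
  n <- length(seqs)
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      d <- nchar(seqs[i]) + nchar(seqs[j]) -
        2 * oracle_lcs_len(seqs[i], seqs[j])
      if (d <= max_distance) { ei <- c(ei, i); ej <- c(ej, j) }
    }
  }
  data.frame(i = ei, j = ej)
}

# Exact two-sided binomial p-value by enumeration of point
# probabilities no larger than the observed one.
oracle_binom_p <- function(k, n, p) {
  probs <- stats::dbinom(0:n, n, p)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Miller-Madow entropy from an integer composition of 7.
oracle_mm_entropy <- function(counts) {
  p <- counts / 7
  -sum(p * log(p)) + (length(counts) - 1) / 14
}

# A peptide realizing a given residue-count composition.
peptide_from_counts <- function(counts) {
  paste(rep(igomeNet::AA_ALPHABET[seq_along(counts)], counts),
        collapse = "")
}

# All 15 integer partitions of 7.
partitions_of_7 <- list(
  c(7), c(6, 1), c(5, 2), c(5, 1, 1), c(4, 3), c(4, 2, 1),
  c(4, 1, 1, 1), c(3, 3, 1), c(3, 2, 2), c(3, 2, 1, 1),
  c(3, 1, 1, 1, 1), c(2, 2, 2, 1), c(2, 2, 1, 1, 1),
  c(2, 1, 1, 1, 1, 1), rep(1, 7))

# Random peptides (uniform over the standard alphabet).
random_peptides <- function(n, len = 7) {
  apply(matrix(sample(igomeNet::AA_ALPHABET, n * len, replace = TRUE),
               nrow = n), 1, paste, collapse = "")
}

# Property-equivalence predicate mirroring the published residue groups,
# built independently of the package's matrix.
oracle_prop_eq <- local({
  groups <- list(c("M", "I", "L", "V"), c("F", "W", "Y"), c("Y", "H"),
                 c("D", "E"), c("D", "N"), c("H", "N"), c("S", "N"),
                 c("E", "Q"), c("E", "K"), c("R", "K", "Q"), c("S", "A"),
                 c("T", "S"), "G", "C", "P")
  function(a, b) {
    a == b || any(vapply(groups, function(g) a %in% g && b %in% g,
                         logical(1)))
  }
})

# Small desk-scale synthetic bundle shared across tests (built once).
desk_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- igomeNet::synthetic_config(rng_seed = 42)
      fams <- igomeNet::generate_families(cfg)
      libs <- igomeNet::generate_libraries(fams, cfg)
      pooled <- igomeNet::pool_libraries(libs[c("A", "C")])
      g <- igomeNet::build_graph(pooled)
      cache <<- list(cfg = cfg, fams = fams, libs = libs,
                     truth = attr(libs, "truth"), pooled = pooled, g = g)
    }
    cache
  }
})
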
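test_that("external neighbor counts equal the all-pairs oracle", {
  set.seed(61)
  vs <- unique(random_peptides(150))
  ext <- unique(random_peptides(400))
  fast <- external_neighbor_counts(vs, ext)
  slow <- vapply(vs, function(v)
    sum(vapply(ext, function(e)
      nchar(v) + nchar(e) - 2 * oracle_lcs_len(v, e) <= 4, logical(1))),
    integer(1))
  expect_equal(fast, unname(slow))
  expect_equal(external_neighbor_counts(vs, character(0)),
               integer(length(vs)))
})

test_that("counting a vertex set against itself recovers degree + 1", {
  b <- desk_bundle()
  vs <- igraph::V(b$g)$name[1:200]
  sub <- igraph::induced_subgraph(b$g, 1:200)
  counts <- external_neighbor_counts(vs, vs)
  expect_equal(counts, unname(igraph::degree(sub)) + 1L)
})

test_that("background neighbor counts track degree on bias-driven graphs", {
  # when the graph's connectivity is driven by residue bias alone (no
  # planted families), vertices rich in common residues gain both graph
  # degree and background neighbors, so the two correlate positively
  set.seed(25)
  bias <- nnk_residue_bias()^2
  bias <- bias / sum(bias)
  draw <- function(n) unique(apply(
    matrix(sample(AA_ALPHABET, 7 * n, replace = TRUE, prob = bias),
           ncol = 7), 1, paste, collapse = ""))
  vs <- draw(900)
  ext <- draw(1200)
  g <- build_graph(vs, keep_singletons = TRUE)
  nB <- external_neighbor_counts(igraph::V(g)$name, ext)
  expect_gt(stats::cor(log1p(nB), log1p(igraph::degree(g))), 0.2)
})

test_that("J-region 7-mer extraction windows, uniques and indexes", {
  out <- extract_jregion_7mers(c(J1 = "ACDEFGH"))
  expect_equal(out$kmers, "ACDEFGH")
  out16 <- extract_jregion_7mers(c(J1 = paste(rep("ACDEFGHKLMNPQRST", 1),
                                              collapse = "")))
  expect_length(out16$kmers, 10L)  # L - 6 windows, all distinct here
  # shared windows across J regions are uniqued and indexed
  js <- c(J1 = "AACDEFGHA", J2 = "CACDEFGHC", J3 = "ACDEF")
  res <- extract_jregion_7mers(js)
  expect_equal(res$n_skipped, 1L)
  oracle <- unique(unlist(lapply(js[1:2], function(s)
    substring(s, 1:(nchar(s) - 6), 7:nchar(s)))))
  expect_setequal(res$kmers, oracle)
  expect_setequal(res$index[["ACDEFGH"]], c("J1", "J2"))
})

test_that("capture-recapture estimates and intervals behave", {
  # complete recapture
  cr <- capture_recapture(100, 100, 100, bootstrap_reps = 200, seed = 1)
  expect_equal(cr$estimate, 100)
  # scale equivariance
  a <- capture_recapture(200, 300, 30, seed = 2)
  b <- capture_recapture(2000, 3000, 300, seed = 2)
  expect_equal(b$estimate, 10 * a$estimate)
  expect_true(a$interval_5_95[1] <= a$estimate &&
                a$estimate <= a$interval_5_95[2])
  expect_gte(a$estimate, 300)
  expect_error(capture_recapture(10, 10, 0), "unbounded")
  # Chapman variant is finite and close for moderate overlap
  ch <- capture_recapture(200, 300, 30, seed = 2, method = "chapman")
  expect_lt(abs(ch$estimate - a$estimate) / a$estimate, 0.05)
})

test_that("capture-recapture recovers a known population in simulation", {
  set.seed(62)
  N <- 50000
  ok <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    s1 <- sample.int(N, 5000)
    s2 <- sample.int(N, 8000)
    ov <- length(intersect(s1, s2))
    cr <- capture_recapture(5000, 8000, ov, bootstrap_reps = 300,
                            seed = r)
    if (abs(cr$estimate - N) <= 2 * cr$boot_sd) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.9)
})

test_that("overlap enrichment reproduces the printed fold and the null", {
  oe <- overlap_enrichment(297028, 109617, 15223, 0.88e8)
  expect_equal(oe$fold, 41.2, tolerance = 0.005)
  expect_lt(oe$p_value, 0.001)
  flat <- overlap_enrichment(1000, 2000, 2, 1e6)
  expect_equal(flat$fold, 1)
  # hypergeometric null: fold ~ 1
  set.seed(63)
  folds <- replicate(50, {
    ov <- stats::rhyper(1, m = 5000, n = 95000, k = 8000)
    overlap_enrichment(5000, 8000, ov, 1e5)$fold
  })
  expect_lt(abs(mean(folds) - 1), 0.05)
})

test_that("Miller-Madow entropy matches the closed form on all 15 patterns", {
  for (counts in partitions_of_7) {
    pep <- peptide_from_counts(counts)
    expect_equal(mm_entropy(pep), oracle_mm_entropy(counts), info = pep)
  }
  # published reference values (printed to 2 and 1 decimals)
  expect_equal(mm_entropy("ACDEFGH"), 2.37, tolerance = 0.005)
  expect_equal(mm_entropy("AACDEFG"), 2.1, tolerance = 0.005)
  expect_lt(mm_entropy("AACCDDE"), 1.57)
})

test_that("entropy classification is constant on composition patterns", {
  expect_equal(as.character(classify_entropy("AACCDDE")), "very_low")
  expect_equal(as.character(classify_entropy("AAACDEF")), "low")
  expect_equal(as.character(classify_entropy("AACCDEF")), "low")
  expect_equal(as.character(classify_entropy("AACDEFG")), "high")
  expect_equal(as.character(classify_entropy("ACDEFGH")), "very_high")
  # permuting the residues never changes the class
  set.seed(64)
  for (r in 1:20) {
    pep <- peptide_from_counts(partitions_of_7[[sample(15, 1)]])
    ch <- strsplit(pep, "")[[1]]
    perm <- paste(sample(ch), collapse = "")
    expect_equal(classify_entropy(pep), classify_entropy(perm))
  }
})

test_that("entropy distributions discriminate planted low-complexity sets", {
  set.seed(65)
  uniformish <- random_peptides(400)
  lowc <- vapply(1:400, function(i) {
    res <- sample(AA_ALPHABET, 3)
    paste(sample(c(rep(res[1], 3), rep(res[2], 2), rep(res[3], 2))),
          collapse = "")
  }, character(1))
  same <- suppressWarnings(entropy_distribution_comparison(uniformish,
                                                           uniformish))
  expect_equal(same$p_value, 1)
  diff <- suppressWarnings(entropy_distribution_comparison(uniformish, lowc))
  expect_lt(diff$p_value, 1e-7)
  expect_equal(unname(rowSums(diff$table)), c(400, 400))
})

test_that("partial correlation matches analytic expectations", {
  set.seed(66)
  x <- rnorm(200)
  y <- rnorm(200)
  plain <- partial_correlation(x, y)
  expect_equal(plain$estimate, stats::cor(x, y))
  z <- rnorm(200)
  same <- partial_correlation(x, x + 1e-8 * rnorm(200), controls = z)
  expect_gt(same$estimate, 0.999)
  # trivariate Gaussian with known precision structure:
  # x = z + ex, y = z + ey with unit noise => partial cor ~ 0, plain
  # cor ~ 0.5
  n <- 40000
  z2 <- rnorm(n)
  x2 <- z2 + rnorm(n)
  y2 <- z2 + rnorm(n)
  expect_equal(stats::cor(x2, y2), 0.5, tolerance = 0.03)
  pc <- partial_correlation(x2, y2, controls = z2)
  expect_lt(abs(pc$estimate), 0.02)
  expect_error(partial_correlation(rep(1, 10), rnorm(10)), "constant")
})
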
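#' Neighbor counts from an external library
#'
#' For every graph vertex, the number of sequences of an external library
#' within the LCS edge criterion (one-vs-many scan; no pooled giant graph
#' is built). The accelerated C++ scan returns output identical to the
#' all-pairs dynamic-programming reference.
#'
#' @param vertex_sequences character vector of graph vertex sequences.
#' @param external_library character vector of external peptides.
#' @param max_distance LCS-distance cutoff (default 4).
#' @return integer vector of counts over the vertices.
#' @export
external_neighbor_counts <- function(vertex_sequences, external_library,
                                     max_distance = 4) {
  if (length(external_library) == 0)
    return(integer(length(vertex_sequences)))
  as.integer(.cpp_neighbor_counts(vertex_sequences, external_library,
                                  as.integer(max_distance)))
}

#' Extract all 7-mer windows from J-region sequences
#'
#' Slides a 7-residue window over each immunoglobulin J-region sequence,
#' pools the unique 7-mers and keeps a reverse index from each 7-mer to
#' the J regions containing it. Sequences shorter than 7 residues are
#' skipped and counted.
#'
#' @param j_sequences character vector (or `AAStringSet`) of J-region
#'   amino-acid sequences; names are used as ids when present.
#' @return list: `kmers` (unique 7-mers), `index` (7-mer -> J ids),
#'   `lengths` (per-J-region length), `n_skipped`.
#' @export
extract_jregion_7mers <- function(j_sequences) {
  if (inherits(j_sequences, "AAStringSet"))
    j_sequences <- stats::setNames(as.character(j_sequences),
                                   names(j_sequences))
  if (is.null(names(j_sequences)))
    names(j_sequences) <- sprintf("J%06d", seq_along(j_sequences))
  len <- nchar(j_sequences)
  skip <- len < 7
  usable <- j_sequences[!skip]
  win <- lapply(usable, function(s)
    substring(s, 1:(nchar(s) - 6), 7:nchar(s)))
  kmer <- unlist(win, use.names = FALSE)
  jid <- rep(names(usable), lengths(win))
  index <- split(jid, kmer)
  index <- lapply(index, unique)
  list(kmers = sort(unique(kmer)), index = index,
       lengths = len, n_skipped = sum(skip))
}

#' Capture-recapture estimate of an unseen sequence diversity
#'
#' Lincoln-Petersen estimator `N = n1 * n2 / overlap` (Chapman
#' bias-corrected variant optional) of the size of the sampled sequence
#' space from two samples and their shared unique sequences, with a 5-95%
#' percentile interval from parametric (hypergeometric) bootstrap of the
#' overlap.
#'
#' @param n1,n2 unique-sequence sample sizes.
#' @param overlap shared unique sequences (must be >= 1).
#' @param bootstrap_reps bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param method `"lincoln"` (default) or `"chapman"`.
#' @return list of class `diversity_estimate`: `estimate`,
#'   `interval_5_95`, `n1`, `n2`, `overlap`, `method`, `boot_sd`.
#' @export
capture_recapture <- function(n1, n2, overlap, bootstrap_reps = 1000,
                              seed = 1, method = c("lincoln", "chapman")) {
  method <- match.arg(method)
  if (overlap < 1)
    stop("overlap of 0 leaves the diversity unbounded")
  stopifnot(overlap <= min(n1, n2))
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  overlap <- as.numeric(overlap)
  est <- function(m) switch(method,
    lincoln = n1 * n2 / m,
    chapman = (n1 + 1) * (n2 + 1) / (m + 1) - 1)
  N <- est(overlap)
  set.seed(seed)
  # hypergeometric resampling of the overlap; binomial limit for spaces
  # too large for the exact sampler
  m_star <- if (N > 1e7) {
    stats::rbinom(bootstrap_reps, size = round(n2), prob = n1 / N)
  } else {
    stats::rhyper(bootstrap_reps, m = round(n1),
                  n = max(round(N - n1), 0), k = round(min(n2, N)))
  }
  m_star <- pmax(m_star, 1)
  boot <- vapply(m_star, est, numeric(1))
  ci <- stats::quantile(boot, c(0.05, 0.95), names = FALSE)
  structure(list(estimate = N, interval_5_95 = ci, n1 = n1, n2 = n2,
                 overlap = overlap, method = method,
                 boot_sd = stats::sd(boot)),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf(
    "Diversity estimate (%s): %.3g (5-95%%: %.3g-%.3g) from n1=%d, n2=%d, overlap=%d\n",
    x$method, x$estimate, x$interval_5_95[1], x$interval_5_95[2],
    x$n1, x$n2, x$overlap))
  invisible(x)
}

#' Fold enrichment of an observed library overlap
#'
#' Compares an observed overlap between two libraries with the overlap
#' expected under uniform sampling from an estimated sequence space of
#' size `N_hat`; significance by the z-test of the overlap proportion.
#'
#' @param lib1_size,lib2_size unique-sequence library sizes.
#' @param observed_overlap shared unique sequences.
#' @param N_hat estimated size of the sampled space.
#' @return list: `expected`, `fold`, `p_value`.
#' @export
overlap_enrichment <- function(lib1_size, lib2_size, observed_overlap,
                               N_hat) {
  stopifnot(N_hat >= max(lib1_size, lib2_size))
  expected <- lib1_size * lib2_size / N_hat
  p0 <- lib1_size / N_hat
  list(expected = expected,
       fold = observed_overlap / expected,
       p_value = proportion_z_test(observed_overlap, lib2_size, p0))
}

#' Miller-Madow corrected Shannon entropy of a 7-mer
#'
#' Natural-log Shannon entropy of the peptide's residue-frequency vector
#' plus the Miller-Madow bias correction `(m - 1) / (2 n)` with `m` the
#' number of distinct residues and `n = 7`. On 7-mers this estimator
#' takes exactly one value per integer partition of 7 (15 values), from
#' 0 (a homopolymer) to 2.37 nats (7 distinct residues).
#'
#' @param peptides character vector of 7-mers.
#' @return numeric vector of entropies in nats.
#' @export
mm_entropy <- function(peptides) {
  stopifnot(all(nchar(peptides) == 7))
  vapply(peptides, function(s) {
    cnt <- table(strsplit(s, "")[[1]])
    p <- as.numeric(cnt) / 7
    -sum(p * log(p)) + (length(cnt) - 1) / 14
  }, numeric(1), USE.NAMES = FALSE)
}

#' Entropy complexity class of 7-mers
#'
#' Bins Miller-Madow entropies into the four discrete complexity levels
#' of 7-mers: `very_low` (< 1.57 nats; three or more repeated pairs or
#' stronger repetition), `low` (1.57-2 nats; two pairs or a triplet),
#' `high` (2.1 nats; one pair), `very_high` (2.37 nats; all seven
#' residues distinct).
#'
#' @param entropy_nats numeric vector from [mm_entropy()] (or peptides,
#'   which are converted first).
#' @return factor with levels `very_low`, `low`, `high`, `very_high`.
#' @export
classify_entropy <- function(entropy_nats) {
  if (is.character(entropy_nats)) entropy_nats <- mm_entropy(entropy_nats)
  cut(entropy_nats, breaks = c(-Inf, 1.57, 2.0, 2.2, Inf),
      labels = c("very_low", "low", "high", "very_high"), right = FALSE)
}

#' Compare two peptide sets by entropy-class distribution
#'
#' Chi-square test on the 2 x 4 contingency table of complexity classes.
#'
#' @param set1,set2 character vectors of 7-mers (or entropy vectors).
#' @return list: `table` (2 x 4 counts), `chi_square`, `p_value`.
#' @export
entropy_distribution_comparison <- function(set1, set2) {
  stopifnot(length(set1) > 0, length(set2) > 0)
  b1 <- table(classify_entropy(set1))
  b2 <- table(classify_entropy(set2))
  tab <- rbind(set1 = b1, set2 = b2)
  nonzero <- colSums(tab) > 0
  test <- suppressWarnings(stats::chisq.test(tab[, nonzero, drop = FALSE]))
  if (any(test$expected < 5))
    warning("expected cell count < 5; consider an exact test")
  list(table = tab, chi_square = unname(test$statistic),
       p_value = test$p.value)
}

#' First-order (or higher) partial Pearson correlation
#'
#' Correlation of `x` and `y` after residualizing both on the control
#' variables by least squares; p-value from the t distribution with
#' `n - 2 - k` degrees of freedom. Counts should be log-transformed
#' upstream (`log1p`) to stabilize the variance.
#'
#' @param x,y numeric vectors.
#' @param controls numeric vector, matrix or data.frame of control
#'   variables (NULL for the plain correlation).
#' @return list: `estimate`, `p_value`, `df`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector")
  k <- 0
  if (!is.null(controls)) {
    z <- as.matrix(controls)
    if (any(apply(z, 2, stats::sd) == 0)) stop("constant control variable")
    k <- ncol(z)
    x <- stats::resid(stats::lm(x ~ z))
    y <- stats::resid(stats::lm(y ~ z))
  }
  r <- stats::cor(x, y)
  df <- length(x) - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  list(estimate = r, p_value = 2 * stats::pt(-abs(t), df), df = df)
}
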
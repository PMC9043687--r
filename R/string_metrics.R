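#' @useDynLib igomeNet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The 20-letter amino-acid alphabet used throughout the package
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Biophysical property groups of amino-acid residues
#'
#' Fifteen partially overlapping residue groups capturing approximate
#' physicochemical and evolutionary equivalence (pairs with positive
#' substitution scores). Two residues are considered equivalent if any
#' group contains both, which makes the relation reflexive and symmetric
#' but deliberately *not* transitive (F~Y and Y~H, yet F and H are not
#' equivalent).
#'
#' @return Named list of 15 character vectors of residues.
#' @export
property_groups <- function() {
  list(
    M = c("M", "I", "L", "V"),
    F = c("F", "W", "Y"),
    Y = c("Y", "H"),
    D = c("D", "E"),
    N = c("D", "N"),
    H = c("H", "N"),
    S = c("S", "N"),
    E = c("E", "Q"),
    K = c("E", "K"),
    R = c("R", "K", "Q"),
    A = c("S", "A"),
    T = c("T", "S"),
    G = "G",
    C = "C",
    P = "P"
  )
}

#' Residue equivalence matrix under the property groups
#'
#' @param groups list of residue groups, by default [property_groups()].
#' @return 20 x 20 logical matrix over [AA_ALPHABET]; `TRUE` where the two
#'   residues share at least one group or are identical.
#' @export
property_equivalence_matrix <- function(groups = property_groups()) {
  m <- diag(length(AA_ALPHABET)) > 0
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  for (g in groups) {
    m[g, g] <- TRUE
  }
  m
}

.identity_matrix <- function() {
  m <- diag(length(AA_ALPHABET)) > 0
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}

.check_residues <- function(...) {
  ch <- unique(unlist(strsplit(c(...), "")))
  bad <- setdiff(ch, AA_ALPHABET)
  if (length(bad) > 0)
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Are two residues property-equivalent?
#'
#' @param a,b single residue characters.
#' @return `TRUE` iff some property group contains both residues.
#' @examples
#' property_equivalent("M", "V")  # TRUE, same aliphatic group
#' property_equivalent("F", "H")  # FALSE, despite F~Y and Y~H
#' @export
property_equivalent <- function(a, b) {
  .check_residues(a, b)
  m <- property_equivalence_matrix()
  unname(m[a, b])
}

#' Longest common subsequence length
#'
#' Length of a longest (not necessarily contiguous) common subsequence of
#' two peptides, by dynamic programming. With `recoded = TRUE` the
#' character-equality test is replaced by residue property equivalence.
#'
#' @param s1,s2 character vectors of peptides (recycled pairwise).
#' @param recoded use the property-group equivalence relation.
#' @return integer vector of LCS lengths.
#' @export
lcs_length <- function(s1, s2, recoded = FALSE) {
  n <- max(length(s1), length(s2))
  s1 <- rep_len(s1, n); s2 <- rep_len(s2, n)
  eq <- if (recoded) property_equivalence_matrix() else .identity_matrix()
  as.integer(.cpp_pair_metric(s1, s2, "lcs_length", AA_ALPHABET, eq))
}

#' Longest common subsequence (indel) distance
#'
#' The indel-only edit distance `|s1| + |s2| - 2 * LCS(s1, s2)`. For two
#' 7-mers, distance <= 4 is equivalent to a shared subsequence of at least
#' 5 residues -- the edge criterion of the mimotope graph.
#'
#' @inheritParams lcs_length
#' @return integer vector of distances.
#' @export
lcs_distance <- function(s1, s2, recoded = FALSE) {
  n <- max(length(s1), length(s2))
  s1 <- rep_len(s1, n); s2 <- rep_len(s2, n)
  eq <- if (recoded) property_equivalence_matrix() else .identity_matrix()
  as.integer(.cpp_pair_metric(s1, s2, "lcs", AA_ALPHABET, eq))
}

.EDIT_METRICS <- c("hamming", "lcs", "lv", "dl", "osa")
.PROFILE_METRICS <- c("qgram", "cosine", "jaccard")

.qgram_profile <- function(s, q) {
  n <- nchar(s)
  if (n < q) return(table(character(0)))
  grams <- substring(s, seq_len(n - q + 1), seq_len(n - q + 1) + q - 1)
  table(grams)
}

.profile_metric <- function(metric, s1, s2, q) {
  p1 <- .qgram_profile(s1, q)
  p2 <- .qgram_profile(s2, q)
  keys <- union(names(p1), names(p2))
  x <- as.numeric(p1[keys]); x[is.na(x)] <- 0
  y <- as.numeric(p2[keys]); y[is.na(y)] <- 0
  switch(metric,
    qgram = sum(abs(x - y)),
    cosine = {
      if (sum(x) == 0 || sum(y) == 0) return(1)
      1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    },
    jaccard = {
      a <- x > 0; b <- y > 0
      if (!any(a | b)) return(0)
      1 - sum(a & b) / sum(a | b)
    }
  )
}

#' Pairwise sequence comparison under a named metric
#'
#' One entry point for all metrics benchmarked for isospecific-mimotope
#' detection: the edit-distance family (`hamming`, `lcs`, `lv`, `dl`,
#' `osa`), the q-gram profile family (`qgram`, `cosine`, `jaccard`) and
#' global pairwise alignment (`pwa`, BLOSUM62). Edit metrics support a
#' property-recoded variant via `recoded = TRUE`; the profile metrics do
#' not (the overlapping groups make profile recoding ill-defined) and
#' `pwa` already encodes residue similarity through its substitution
#' matrix.
#'
#' All metrics except `pwa` return distances (lower = more similar); `pwa`
#' returns an alignment score (higher = more similar).
#'
#' @param metric metric id.
#' @param s1,s2 character vectors of peptides, compared pairwise.
#' @param recoded use property-group equivalence (edit metrics only).
#' @param q q-gram length for the profile family.
#' @param gap_open,gap_ext gap penalties for `pwa`.
#' @return numeric vector of distances (or scores for `pwa`).
#' @export
seq_metric <- function(metric, s1, s2, recoded = FALSE, q = 2,
                       gap_open = 10, gap_ext = 4) {
  metric <- match.arg(metric, c(.EDIT_METRICS, .PROFILE_METRICS, "pwa"))
  n <- max(length(s1), length(s2))
  s1 <- rep_len(s1, n); s2 <- rep_len(s2, n)
  if (metric %in% .EDIT_METRICS) {
    eq <- if (recoded) property_equivalence_matrix() else .identity_matrix()
    return(as.numeric(.cpp_pair_metric(s1, s2, metric, AA_ALPHABET, eq)))
  }
  if (recoded)
    stop("property recoding is not supported for metric '", metric, "'")
  if (metric == "pwa") {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    sm <- get("BLOSUM62", envir = environment())
    return(vapply(seq_len(n), function(i) {
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(s1[i]), Biostrings::AAString(s2[i]),
        substitutionMatrix = sm, gapOpening = gap_open,
        gapExtension = gap_ext, type = "global", scoreOnly = TRUE)
    }, numeric(1)))
  }
  vapply(seq_len(n), function(i) .profile_metric(metric, s1[i], s2[i], q),
         numeric(1))
}

#' All metric ids available to [seq_metric()]
#' @param recoded if `TRUE`, only the ids supporting property recoding.
#' @export
metric_ids <- function(recoded = FALSE) {
  if (recoded) setdiff(.EDIT_METRICS, character(0))
  else c(.EDIT_METRICS, .PROFILE_METRICS, "pwa")
}

#' All-pairs distance matrix
#'
#' Computes the full symmetric distance matrix for a set of peptides with
#' the guarantee of exact equality with the pairwise [seq_metric()] calls.
#'
#' @inheritParams seq_metric
#' @param seqs character vector of peptides.
#' @return numeric matrix with `seqs` as dimnames.
#' @export
all_pairs_distances <- function(seqs, metric = "lcs", recoded = FALSE,
                                q = 2) {
  n <- length(seqs)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- seq_metric(metric, seqs[idx[, 1]], seqs[idx[, 2]],
                  recoded = recoded, q = q)
  m <- matrix(0, n, n, dimnames = list(seqs, seqs))
  m[idx] <- d
  m[idx[, c(2, 1), drop = FALSE]] <- d
  m
}
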
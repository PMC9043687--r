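#' Default residue bias of a 7-mer phage-display library
#'
#' NNK-degenerate codon libraries encode each residue with 1-3 of the 32
#' NNK codons, so the expected residue frequency is proportional to its
#' NNK codon multiplicity -- a skewed, realistic default for the
#' unselected background.
#'
#' @return named numeric vector over [AA_ALPHABET] summing to 1.
#' @export
nnk_residue_bias <- function() {
  tab <- nnk_codon_table()
  mult <- vapply(AA_ALPHABET, function(a) length(tab[[a]]), numeric(1))
  mult / sum(mult)
}

#' NNK codon table
#'
#' All 32 codons of the form NNK (N = A/C/G/T, K = G/T) grouped by the
#' residue they encode under the standard genetic code. The amber stop
#' codon TAG is excluded (suppressed to Gln in the production strain, but
#' peptide encoding never needs it since CAG is available).
#'
#' @return named list: residue -> character vector of codons.
#' @export
nnk_codon_table <- function() {
  n <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(n, n, paste0), c("G", "T"), paste0))
  aa <- vapply(codons, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE)), character(1))
  keep <- aa != "*"
  split(codons[keep], aa[keep])
}

#' Configuration for the synthetic mimotope generator
#'
#' Defines the study conditions the generator emulates: a set of planted
#' cross-reactivity ("footprint") families, two cohort libraries `A` and
#' `C` whose family abundances differ for a fraction of families, a larger
#' public library `G` overlapping the planted families, and a background
#' library `B` drawn purely from the residue bias.
#'
#' @param n_families number of planted footprint families.
#' @param family_size_range inclusive (min, max) of family sizes.
#' @param residue_bias 20-vector of residue probabilities (sums to 1);
#'   default [nnk_residue_bias()].
#' @param n_A,n_C,n_G,n_B unique-sequence library sizes.
#' @param fraction_differential share of families with a shifted A/C
#'   abundance.
#' @param shift_magnitude fold-change (>= 1) between the A and C weights
#'   of a shifted family.
#' @param fraction_up among shifted families, the share shifted *up* in A
#'   (the rest are shifted up in C).
#' @param public_fraction probability that a family is also seeded into G.
#' @param inclusion_probability probability that a family member enters a
#'   cohort library when the family carries full weight there; a shifted
#'   family's members enter the down-shifted cohort with this probability
#'   divided by `shift_magnitude`.
#' @param copy_number_model list with `mu`, `size`, `max`: zero-truncated
#'   negative binomial, truncated above at `max`.
#' @param rng_seed integer seed; every generator call is deterministic
#'   given the config.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_families = 40,
                             family_size_range = c(20, 45),
                             residue_bias = nnk_residue_bias(),
                             n_A = 1500, n_C = 1200, n_G = 2500, n_B = 1500,
                             fraction_differential = 0.2,
                             shift_magnitude = 8,
                             fraction_up = 0.25,
                             public_fraction = 0.6,
                             inclusion_probability = 0.7,
                             copy_number_model = list(mu = 4, size = 1.2,
                                                      max = 50),
                             rng_seed = 42) {
  stopifnot(n_families >= 1,
            length(family_size_range) == 2,
            family_size_range[1] >= 1,
            family_size_range[1] <= family_size_range[2],
            length(residue_bias) == 20,
            abs(sum(residue_bias) - 1) < 1e-8,
            all(residue_bias >= 0),
            n_A > 0, n_C > 0, n_G > 0, n_B > 0,
            fraction_differential >= 0, fraction_differential <= 1,
            shift_magnitude >= 1,
            fraction_up >= 0, fraction_up <= 1,
            inclusion_probability > 0, inclusion_probability <= 1)
  names(residue_bias) <- AA_ALPHABET
  structure(list(n_families = n_families,
                 family_size_range = as.integer(family_size_range),
                 residue_bias = residue_bias,
                 n_A = n_A, n_C = n_C, n_G = n_G, n_B = n_B,
                 fraction_differential = fraction_differential,
                 shift_magnitude = shift_magnitude,
                 fraction_up = fraction_up,
                 public_fraction = public_fraction,
                 inclusion_probability = inclusion_probability,
                 copy_number_model = copy_number_model,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

.random_peptide <- function(n, bias) {
  m <- matrix(sample(AA_ALPHABET, 7 * n, replace = TRUE, prob = bias),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}

.perturb <- function(seq, bias, p_single = 0.8) {
  ch <- strsplit(seq, "")[[1]]
  # mostly single-edit members: two 1-edit variants of the same seed are
  # themselves within the edge criterion, giving the near-clique interior
  # real footprint families show
  n_ops <- if (stats::runif(1) < p_single) 1L else 2L
  for (k in seq_len(n_ops)) {
    if (stats::runif(1) < 0.5) {
      pos <- sample(7, 1)
      ch[pos] <- sample(AA_ALPHABET, 1, prob = bias)
    } else {
      # single indel with re-padding: delete one residue, insert a fresh
      # one at a random position, keeping length 7
      del <- sample(7, 1)
      ch <- ch[-del]
      ins <- sample(7, 1)
      ch <- append(ch, sample(AA_ALPHABET, 1, prob = bias), after = ins - 1)
    }
  }
  paste(ch, collapse = "")
}

#' Generate planted footprint families
#'
#' Each family models the cluster of related mimotopes a single antibody
#' paratope can select: a seed 7-mer plus members obtained by
#' substitution/indel perturbation constrained to share a common
#' subsequence of at least 5 residues with the seed (LCS distance <= 4).
#' Since every member is adjacent to the seed under the graph's edge
#' criterion, the family is connected by construction.
#'
#' @param config a [synthetic_config()].
#' @param max_retries retry budget per member before declaring the size
#'   infeasible.
#' @return list of `footprint_family` objects with fields `id`, `seed`,
#'   `members`, `abundance_A`, `abundance_C`, `is_public`.
#' @export
generate_families <- function(config, max_retries = 500) {
  set.seed(config$rng_seed)
  bias <- config$residue_bias
  n_diff <- round(config$fraction_differential * config$n_families)
  n_up <- round(config$fraction_up * n_diff)
  fams <- vector("list", config$n_families)
  pick1 <- function(v) v[sample.int(length(v), 1)]
  for (f in seq_len(config$n_families)) {
    size <- pick1(seq(config$family_size_range[1],
                      config$family_size_range[2]))
    seed_seq <- .random_peptide(1, bias)
    members <- seed_seq
    tries <- 0
    while (length(members) < size) {
      tries <- tries + 1
      if (tries > max_retries * size)
        stop("family size ", size, " infeasible under the LCS constraint")
      cand <- .perturb(seed_seq, bias)
      if (cand %in% members) next
      if (lcs_distance(seed_seq, cand) <= 4)
        members <- c(members, cand)
    }
    shifted <- f <= n_diff
    up <- shifted && f <= n_up
    fams[[f]] <- structure(list(
      id = f,
      seed = seed_seq,
      members = members,
      abundance_A = if (shifted && up) config$shift_magnitude else 1,
      abundance_C = if (shifted && !up) config$shift_magnitude else 1,
      is_public = stats::runif(1) < config$public_fraction
    ), class = "footprint_family")
  }
  fams
}

.rztnb <- function(n, model) {
  out <- integer(0)
  while (length(out) < n) {
    x <- stats::rnbinom(n, mu = model$mu, size = model$size)
    out <- c(out, x[x >= 1])
  }
  pmin(out[seq_len(n)], model$max)
}

.include_members <- function(families, weights, p_incl) {
  out <- character(0)
  for (k in seq_along(families)) {
    m <- families[[k]]$members
    out <- c(out, m[stats::runif(length(m)) < p_incl * weights[k]])
  }
  out
}

.background_seqs <- function(n, bias, exclude, what = "background") {
  if (n <= 0) return(character(0))
  seqs <- character(0)
  tries <- 0
  while (length(seqs) < n) {
    tries <- tries + 1
    if (tries > 60)
      stop("requested ", n, " unique ", what, " sequences exceeds the ",
           "reachable diversity")
    new <- .random_peptide(max(n - length(seqs), 50), bias)
    seqs <- unique(c(seqs, setdiff(new, exclude)))
  }
  seqs[seq_len(n)]
}

#' Generate the synthetic library set {A, C, G, B}
#'
#' Each family member enters cohort `A` with probability
#' `inclusion_probability * abundance_A / max(abundance_A, abundance_C)`
#' and likewise for `C`, so a shifted family's members are mostly private
#' to the up-shifted cohort while balanced families produce the common
#' (A-and-C) sequences. The remainder of each library, up to its
#' requested unique size, is background noise from the residue bias. `G`
#' oversamples the public families; `B` is drawn purely from the residue
#' bias. Every sequence receives a copy number from the zero-truncated
#' negative-binomial model.
#'
#' @param families output of [generate_families()].
#' @param config the same [synthetic_config()].
#' @return named list of `mimotope_library` objects (`A`, `C`, `G`, `B`)
#'   with attribute `truth`: a data.frame mapping member sequences to
#'   family ids and shift status.
#' @export
generate_libraries <- function(families, config) {
  if (length(families) == 0) stop("families must be non-empty")
  set.seed(config$rng_seed + 1L)
  bias <- config$residue_bias
  wA <- vapply(families, `[[`, numeric(1), "abundance_A")
  wC <- vapply(families, `[[`, numeric(1), "abundance_C")
  wmax <- pmax(wA, wC)
  pub <- vapply(families, `[[`, logical(1), "is_public")
  p <- config$inclusion_probability
  mA <- .include_members(families, wA / wmax, p)
  mC <- .include_members(families, wC / wmax, p)
  mG <- .include_members(families[pub], rep(1, sum(pub)), p)
  all_members <- unlist(lapply(families, `[[`, "members"))
  if (length(mA) > config$n_A || length(mC) > config$n_C ||
      length(mG) > config$n_G)
    stop("library size smaller than the included family members; ",
         "increase n_A/n_C/n_G or reduce the families")
  sA <- c(mA, .background_seqs(config$n_A - length(mA), bias,
                               all_members, "A"))
  sC <- c(mC, .background_seqs(config$n_C - length(mC), bias,
                               all_members, "C"))
  sG <- c(mG, .background_seqs(config$n_G - length(mG), bias,
                               all_members, "G"))
  sB <- .background_seqs(config$n_B, bias, character(0), "B")
  libs <- list(
    A = mimotope_library(sA, .rztnb(length(sA), config$copy_number_model), "A"),
    C = mimotope_library(sC, .rztnb(length(sC), config$copy_number_model), "C"),
    G = mimotope_library(sG, .rztnb(length(sG), config$copy_number_model), "G"),
    B = mimotope_library(sB, .rztnb(length(sB), config$copy_number_model), "B")
  )
  truth <- do.call(rbind, lapply(families, function(f)
    data.frame(sequence = f$members, family = f$id,
               shifted = f$abundance_A != f$abundance_C,
               direction = if (f$abundance_A > f$abundance_C) "A"
                           else if (f$abundance_C > f$abundance_A) "C"
                           else "ns",
               is_public = f$is_public, stringsAsFactors = FALSE)))
  truth <- truth[!duplicated(truth$sequence), , drop = FALSE]
  attr(libs, "truth") <- truth
  libs
}

#' Generate synthetic sequencer reads for a library
#'
#' Encodes each peptide with NNK-degenerate codons, flanks the 21-nt
#' insert with the two primers and emits one FASTQ record per copy. A
#' configurable fraction of records carries a single insert base with a
#' quality below the ingestion threshold, emulating sequencing errors the
#' quality filter must remove.
#'
#' @param lib a `mimotope_library`.
#' @param primer_5,primer_3 flanking primer DNA sequences.
#' @param low_quality_fraction share of records given one low-quality
#'   insert base.
#' @param q_high,q_low Phred qualities of normal and degraded bases.
#' @param seed integer seed.
#' @return `Biostrings::QualityScaledDNAStringSet` (Phred+33).
#' @export
generate_reads <- function(lib, primer_5 = "TCCTTTAGTGGTACCTTTCTATTCTCACTCT",
                           primer_3 = "GGTGGAGGTTCGGCCGAAACTGTTGAA",
                           low_quality_fraction = 0, q_high = 37, q_low = 20,
                           seed = 1) {
  stopifnot(nchar(primer_5) > 0, nchar(primer_3) > 0,
            all(nchar(lib$sequence) == 7))
  set.seed(seed)
  tab <- nnk_codon_table()
  seqs <- rep(lib$sequence, lib$count)
  inserts <- vapply(seqs, function(p) {
    ch <- strsplit(p, "")[[1]]
    paste(vapply(ch, function(a) sample(tab[[a]], 1), character(1)),
          collapse = "")
  }, character(1))
  reads <- paste0(primer_5, inserts, primer_3)
  len <- nchar(reads[1])
  qmat <- matrix(q_high, length(reads), len)
  degrade <- stats::runif(length(reads)) < low_quality_fraction
  if (any(degrade)) {
    pos <- nchar(primer_5) + sample(21, sum(degrade), replace = TRUE)
    qmat[cbind(which(degrade), pos)] <- q_low
  }
  qual_strings <- apply(qmat, 1, function(q) intToUtf8(q + 33L))
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads),
    Biostrings::PhredQuality(qual_strings))
  names(out) <- sprintf("read_%06d", seq_along(reads))
  out
}

#' Write/read FASTQ (Phred+33)
#' @param reads a `QualityScaledDNAStringSet`.
#' @param path output path (gzip transparent on read).
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Uniform sample of the 7-mer sequence space
#'
#' Draws distinct peptides uniformly from the full \eqn{20^7} space,
#' returned as integer codes (bijective with sequences via
#' [decode_peptides()]). Used for capture-recapture control experiments.
#'
#' @param n number of distinct draws.
#' @param seed integer seed (NULL = leave RNG alone).
#' @export
sample_peptide_space <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(20L^7L, n, replace = FALSE, useHash = TRUE)
}

#' @rdname sample_peptide_space
#' @param codes integer codes in 1..20^7.
#' @export
decode_peptides <- function(codes) {
  x <- codes - 1
  out <- matrix("", length(codes), 7)
  for (p in 1:7) {
    out[, p] <- AA_ALPHABET[(x %% 20) + 1]
    x <- x %/% 20
  }
  apply(out, 1, paste, collapse = "")
}
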
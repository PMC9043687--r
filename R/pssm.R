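#' Build a position-specific scoring matrix from a cluster
#'
#' The simplest statistical model of a mimotope cluster: per-position
#' residue probabilities (with a pseudocount keeping every cell finite),
#' scored as the negative log probability. A peptide's score is the sum
#' of its seven positional scores, so *lower* scores mean better fits;
#' reported `goodness` values are the negated score so that thresholds
#' read "higher is better".
#'
#' The default membership threshold is the worst (largest) score among
#' the cluster's own members, i.e. every training member is recalled.
#'
#' @param cluster_sequences at least 4 unique 7-mer peptides.
#' @param pseudocount per-cell pseudocount (default 1/20).
#' @param cluster_id identifier stored in the model.
#' @return object of class `igome_pssm`: `cluster_id`, `prob` (20 x 7),
#'   `score` (20 x 7, -log prob), `threshold` (max member score),
#'   `pseudocount`, `n_train`.
#' @export
build_pssm <- function(cluster_sequences, pseudocount = 1 / 20,
                       cluster_id = "cluster") {
  if (length(cluster_sequences) < 4)
    stop("a PSSM needs at least 4 cluster sequences")
  if (any(nchar(cluster_sequences) != 7))
    stop("cluster sequences must be 7-mers")
  stopifnot(pseudocount > 0)
  ch <- do.call(rbind, strsplit(cluster_sequences, ""))
  prob <- vapply(seq_len(7), function(p) {
    cnt <- table(factor(ch[, p], levels = AA_ALPHABET))
    (as.numeric(cnt) + pseudocount) /
      (length(cluster_sequences) + 20 * pseudocount)
  }, numeric(20))
  dimnames(prob) <- list(AA_ALPHABET, paste0("p", 1:7))
  score <- -log(prob)
  model <- structure(list(cluster_id = cluster_id, prob = prob,
                          score = score, threshold = NA_real_,
                          pseudocount = pseudocount,
                          n_train = length(cluster_sequences)),
                     class = "igome_pssm")
  model$threshold <- max(score_sequence(model, cluster_sequences))
  model
}

#' @export
print.igome_pssm <- function(x, ...) {
  cat(sprintf("PSSM '%s': 7 x 20, trained on %d sequences, threshold %.3f\n",
              x$cluster_id, x$n_train, x$threshold))
  invisible(x)
}

#' Score peptides against a PSSM
#'
#' Sum of the seven positional `-log` probability scores (lower =
#' better fit to the cluster).
#'
#' @param model an `igome_pssm`.
#' @param peptides character vector of 7-mers.
#' @param on_nonstandard `"fail"` (default) or `"skip"` (returns `NA`).
#' @return numeric vector of scores.
#' @export
score_sequence <- function(model, peptides, on_nonstandard = c("fail",
                                                               "skip")) {
  on_nonstandard <- match.arg(on_nonstandard)
  stopifnot(all(nchar(peptides) == 7))
  ch <- do.call(rbind, strsplit(peptides, ""))
  bad <- !ch %in% AA_ALPHABET
  if (any(bad)) {
    if (on_nonstandard == "fail")
      stop("non-standard residue(s) in query peptides")
    ch[bad] <- NA
  }
  vapply(seq_len(nrow(ch)), function(i) {
    idx <- cbind(match(ch[i, ], AA_ALPHABET), 1:7)
    sum(model$score[idx])
  }, numeric(1))
}

#' Membership call of peptides under a PSSM
#' @param model an `igome_pssm`.
#' @param peptides 7-mers.
#' @return logical: score within the model threshold.
#' @export
pssm_member <- function(model, peptides) {
  score_sequence(model, peptides) <= model$threshold
}

#' Scan epitope sequences with PSSM models
#'
#' Slides a 7-residue window over every epitope of at least `min_length`
#' residues, scores every frame against every model and keeps the best
#' frame per (model, epitope). A hit is a best frame scoring within the
#' model threshold. Shorter epitopes are skipped and counted.
#'
#' @param models list of `igome_pssm` models (or a single model).
#' @param epitopes data.frame with columns `id`, `sequence` (optionally
#'   `annotation`), or a named character vector.
#' @param min_length minimal epitope length (default 7).
#' @return data.frame: `cluster_id`, `target_id`, `offset` (0-based),
#'   `frame`, `score`, `goodness`, `hit`; attribute `n_skipped`.
#' @export
scan_epitopes <- function(models, epitopes, min_length = 7) {
  if (inherits(models, "igome_pssm")) models <- list(models)
  if (is.character(epitopes))
    epitopes <- data.frame(id = if (is.null(names(epitopes)))
                             sprintf("epi%04d", seq_along(epitopes))
                           else names(epitopes),
                           sequence = unname(epitopes),
                           stringsAsFactors = FALSE)
  keep <- nchar(epitopes$sequence) >= max(min_length, 7)
  n_skipped <- sum(!keep)
  epitopes <- epitopes[keep, , drop = FALSE]
  rows <- lapply(models, function(m) {
    do.call(rbind, lapply(seq_len(nrow(epitopes)), function(e) {
      s <- epitopes$sequence[e]
      n_frames <- nchar(s) - 6
      frames <- substring(s, 1:n_frames, 7:nchar(s))
      sc <- score_sequence(m, frames)
      b <- which.min(sc)
      data.frame(cluster_id = m$cluster_id, target_id = epitopes$id[e],
                 offset = b - 1L, frame = frames[b], score = sc[b],
                 goodness = -sc[b], hit = sc[b] <= m$threshold,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Exact substring matches of peptides in a proteome
#'
#' Case-insensitive exact search of each 7-mer in every protein sequence.
#' Reports every occurrence with its 0-based position, plus per-peptide
#' and per-protein summaries and an optional isoform collapsing by the
#' gene token of the FASTA header (`GN=...` when present, else the
#' second `|`-separated field).
#'
#' @param peptides character vector of 7-mers.
#' @param proteome `Biostrings::AAStringSet` or named character vector of
#'   protein sequences.
#' @param collapse_isoforms also report protein counts collapsed by gene.
#' @return list: `hits` (data.frame `peptide`, `protein_id`, `position`),
#'   `n_peptides_hit`, `n_proteins_hit`, `n_genes_hit` (when collapsed).
#' @export
exact_proteome_match <- function(peptides, proteome,
                                 collapse_isoforms = TRUE) {
  if (inherits(proteome, "AAStringSet"))
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  if (is.null(names(proteome)) || anyDuplicated(names(proteome)))
    stop("proteome needs unique sequence ids")
  prot_up <- toupper(proteome)
  rows <- lapply(unique(toupper(peptides)), function(p) {
    m <- gregexpr(p, prot_up, fixed = TRUE)
    found <- which(vapply(m, function(x) x[1] > 0, logical(1)))
    if (length(found) == 0) return(NULL)
    do.call(rbind, lapply(found, function(k)
      data.frame(peptide = p, protein_id = names(proteome)[k],
                 position = as.integer(m[[k]]) - 1L,
                 stringsAsFactors = FALSE)))
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits))
    hits <- data.frame(peptide = character(0), protein_id = character(0),
                       position = integer(0))
  out <- list(hits = hits,
              n_peptides_hit = length(unique(hits$peptide)),
              n_proteins_hit = length(unique(hits$protein_id)))
  if (collapse_isoforms && nrow(hits) > 0) {
    gene <- function(id) {
      gn <- regmatches(id, regexpr("GN=[^ ]+", id))
      if (length(gn)) return(sub("^GN=", "", gn))
      parts <- strsplit(id, "|", fixed = TRUE)[[1]]
      if (length(parts) >= 2) parts[2] else id
    }
    out$n_genes_hit <-
      length(unique(vapply(unique(hits$protein_id), gene, character(1))))
  }
  out
}

#' Serialize PSSM models to JSON
#' @param models list of `igome_pssm` (or one model).
#' @param path output path.
#' @export
write_pssm_json <- function(models, path) {
  if (inherits(models, "igome_pssm")) models <- list(models)
  payload <- lapply(models, function(m)
    list(cluster_id = m$cluster_id, pseudocount = m$pseudocount,
         n_train = m$n_train, threshold = m$threshold,
         positions = paste0("p", 1:7), residues = AA_ALPHABET,
         score = t(m$score)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
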
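#' Construct a mimotope library
#'
#' A labeled multiset of 7-mer peptides with copy numbers and library
#' membership flags. Libraries are labeled `A`/`C` for the two compared
#' cohorts, `G` (public repertoire), `B` (unselected background), `I`
#' (immunoglobulin J-region 7-mers) or `pooled`.
#'
#' @param sequences character vector of unique 7-mer peptides.
#' @param counts positive integer copy numbers (default 1).
#' @param label library label.
#' @param members optional character vector of comma-separated membership
#'   flags per sequence; defaults to `label` for every entry.
#' @return object of class `mimotope_library`: a data.frame with columns
#'   `sequence`, `count`, `libs` and attributes `label`.
#' @export
mimotope_library <- function(sequences, counts = 1L,
                             label = "pooled", members = NULL) {
  if (anyDuplicated(sequences))
    stop("sequences must be unique within a library")
  if (length(sequences) > 0) {
    if (any(nchar(sequences) != 7))
      stop("all sequences must be 7-mers")
    .check_residues(sequences)
  }
  counts <- rep_len(as.integer(counts), length(sequences))
  if (length(counts) && any(counts < 1)) stop("copy numbers must be >= 1")
  if (is.null(members)) members <- rep_len(label, length(sequences))
  x <- data.frame(sequence = as.character(sequences), count = counts,
                  libs = as.character(members), stringsAsFactors = FALSE)
  structure(x, label = label, class = c("mimotope_library", "data.frame"))
}

#' @export
print.mimotope_library <- function(x, ...) {
  cat(sprintf("Mimotope library '%s': %d unique sequences, %d total copies\n",
              attr(x, "label"), nrow(x), sum(x$count)))
  if (nrow(x) > 0) {
    flags <- sort(table(x$libs), decreasing = TRUE)
    cat("  membership:", paste(sprintf("%s=%d", names(flags), flags),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract peptide inserts from deep-panning reads
#'
#' Locates the 21-nt library insert between the two flanking primers,
#' applies a strict per-base quality rule (any insert base with Phred
#' quality <= `q_min` discards the read), translates in frame and counts
#' the resulting 7-mer peptides. Reads whose forward strand does not
#' contain the 5' primer are retried as reverse complements. Reads with a
#' stop codon or a translation of length != 7 are discarded and logged.
#'
#' @param reads a `Biostrings::QualityScaledDNAStringSet` or a path to a
#'   FASTQ file (Phred+33, gzip transparent).
#' @param primer_5,primer_3 flanking primer sequences (DNA strings).
#' @param q_min quality threshold; insert bases must have quality strictly
#'   above it (default 32, "high accuracy").
#' @return data.frame with columns `sequence`, `count`; attribute
#'   `rejects` holds counts of discarded reads by reason
#'   (`no_primer`, `low_quality`, `stop_codon`, `bad_length`).
#' @export
extract_inserts <- function(reads, primer_5, primer_3, q_min = 32) {
  if (is.character(reads) && length(reads) == 1)
    reads <- Biostrings::readQualityScaledDNAStringSet(reads)
  seqs <- as.character(reads)
  quals <- as(Biostrings::quality(reads), "IntegerList")
  ins_len <- 21L
  rejects <- c(no_primer = 0L, low_quality = 0L, stop_codon = 0L,
               bad_length = 0L)
  peptides <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    qv <- as.integer(quals[[i]])
    pos <- regexpr(primer_5, s, fixed = TRUE)[1]
    if (pos < 0) {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      qv <- rev(qv)
      pos <- regexpr(primer_5, s, fixed = TRUE)[1]
    }
    if (pos < 0) { rejects["no_primer"] <- rejects["no_primer"] + 1L; next }
    start <- pos + nchar(primer_5)
    end <- start + ins_len - 1L
    if (end + nchar(primer_3) - 1L > nchar(s) ||
        substr(s, end + 1L, end + nchar(primer_3)) != primer_3) {
      rejects["no_primer"] <- rejects["no_primer"] + 1L
      next
    }
    if (any(qv[start:end] <= q_min)) {
      rejects["low_quality"] <- rejects["low_quality"] + 1L
      next
    }
    insert <- substr(s, start, end)
    pep <- as.character(Biostrings::translate(Biostrings::DNAString(insert),
                                              no.init.codon = TRUE))
    if (grepl("*", pep, fixed = TRUE)) {
      rejects["stop_codon"] <- rejects["stop_codon"] + 1L
      next
    }
    if (nchar(pep) != 7) {
      rejects["bad_length"] <- rejects["bad_length"] + 1L
      next
    }
    peptides <- c(peptides, pep)
  }
  tab <- table(peptides)
  out <- data.frame(sequence = as.character(names(tab)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  if (nrow(out) > 0) out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Retain sequences by copy number
#'
#' Keeps sequences whose copy number lies in the closed interval
#' `[min_count, max_count]` (default 3..10), suppressing both likely
#' sequencing errors (singletons/doubletons) and overgrowing phage clones.
#'
#' @param lib a `mimotope_library` or a data.frame with `sequence`,`count`.
#' @param min_count,max_count inclusive copy-number bounds.
#' @export
filter_copy_number <- function(lib, min_count = 3, max_count = 10) {
  stopifnot(min_count <= max_count)
  keep <- lib$count >= min_count & lib$count <= max_count
  out <- lib[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("copy-number filter removed every sequence")
  out
}

#' Remove target-unrelated peptides via an exclusion list
#'
#' Set difference against a user-supplied list of known selection
#' artifacts (e.g. plastic or streptavidin binders). Removed sequences are
#' logged in the `removed` attribute with reason `"TUP"`.
#'
#' @param lib a `mimotope_library`.
#' @param exclusion_sequences character vector of peptides to discard.
#' @export
apply_exclusion_list <- function(lib, exclusion_sequences) {
  drop <- lib$sequence %in% exclusion_sequences
  out <- lib[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(sequence = lib$sequence[drop],
                                     reason = rep("TUP", sum(drop)),
                                     stringsAsFactors = FALSE)
  if (nrow(out) == 0 && nrow(lib) > 0)
    warning("exclusion list removed every sequence")
  out
}

#' Pool libraries into a labeled union
#'
#' Unique-sequence union of several libraries. Each pooled entry carries
#' comma-separated flags of every source library containing it; copy
#' numbers are summed. Pairwise overlap counts are reported in the
#' `overlaps` attribute.
#'
#' @param libraries named list of `mimotope_library` objects (names are
#'   used as membership flags; unnamed lists fall back to each library's
#'   own label).
#' @return pooled `mimotope_library` with attribute `overlaps` (matrix).
#' @export
pool_libraries <- function(libraries) {
  if (length(libraries) < 2) stop("need at least 2 libraries to pool")
  labs <- names(libraries)
  if (is.null(labs) || any(labs == ""))
    labs <- vapply(libraries, function(l) attr(l, "label"), character(1))
  all_seq <- sort(unique(unlist(lapply(libraries, `[[`, "sequence"))))
  counts <- integer(length(all_seq))
  flags <- vector("list", length(all_seq))
  memb <- matrix(FALSE, length(all_seq), length(libraries),
                 dimnames = list(all_seq, labs))
  for (k in seq_along(libraries)) {
    l <- libraries[[k]]
    i <- match(l$sequence, all_seq)
    counts[i] <- counts[i] + l$count
    memb[i, k] <- TRUE
  }
  members <- apply(memb, 1, function(r) paste(labs[r], collapse = ","))
  overlaps <- crossprod(memb)
  out <- mimotope_library(all_seq, counts, label = "pooled",
                          members = unname(members))
  attr(out, "overlaps") <- overlaps
  out
}

#' Project a pooled library back onto one source library
#'
#' @param pooled a pooled `mimotope_library`.
#' @param label source flag to extract.
#' @return `mimotope_library` of the entries flagged with `label`.
#' @export
project_library <- function(pooled, label) {
  keep <- vapply(strsplit(pooled$libs, ","), function(f) label %in% f,
                 logical(1))
  mimotope_library(pooled$sequence[keep], pooled$count[keep], label = label)
}

#' Read/write the TSV library format
#'
#' Tab-separated columns `sequence`, `count`, `libs` (comma-separated
#' membership flags). Gzip transparent.
#'
#' @param path file path.
#' @param label label for the returned library.
#' @export
read_library_tsv <- function(path, label = "pooled") {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "count") %in% names(x)))
    stop("library TSV must have columns 'sequence' and 'count'")
  if (is.null(x$libs)) x$libs <- label
  mimotope_library(x$sequence, x$count, label = label, members = x$libs)
}

#' @rdname read_library_tsv
#' @param lib library to write.
#' @export
write_library_tsv <- function(lib, path) {
  utils::write.table(as.data.frame(lib)[, c("sequence", "count", "libs")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export library sequences as FASTA
#' @param lib library to export.
#' @param path output path.
#' @export
write_library_fasta <- function(lib, path) {
  ss <- Biostrings::AAStringSet(lib$sequence)
  names(ss) <- sprintf("%s|count=%d", lib$sequence, lib$count)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a plain peptide list (one sequence per line or FASTA)
#' @param path file path.
#' @export
read_peptide_list <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) && startsWith(first, ">"))
    return(as.character(Biostrings::readAAStringSet(path)))
  readLines(path)
}
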
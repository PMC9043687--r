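p5 <- "TCCTTTAGTGGTACCTTTCTATTCTCACTCT"
p3 <- "GGTGGAGGTTCGGCCGAAACTGTTGAA"

test_that("read generation and insert extraction are inverse operations", {
  lib <- mimotope_library(c("ACDEFGH", "MNPQRST", "WYKLHIV"),
                          c(3, 2, 5), "A")
  reads <- generate_reads(lib, p5, p3, seed = 4)
  expect_length(reads, 10L)
  tab <- extract_inserts(reads, p5, p3)
  expect_equal(tab$sequence, sort(lib$sequence))
  expect_equal(tab$count, lib$count[order(lib$sequence)])
  expect_true(all(attr(tab, "rejects") == 0))
})

test_that("insert extraction is order independent and handles reverse reads", {
  lib <- mimotope_library(c("ACDEFGH", "MNPQRST"), c(4, 3), "A")
  reads <- generate_reads(lib, p5, p3, seed = 9)
  set.seed(1)
  shuffled <- reads[sample(length(reads))]
  expect_equal(extract_inserts(reads, p5, p3),
               extract_inserts(shuffled, p5, p3),
               ignore_attr = TRUE)
  rc <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::reverseComplement(as(reads, "DNAStringSet")),
    Biostrings::PhredQuality(vapply(as.character(Biostrings::quality(reads)),
                                    function(q) paste(rev(strsplit(q, "")[[1]]),
                                                      collapse = ""),
                                    character(1))))
  expect_equal(extract_inserts(rc, p5, p3)$count, c(4, 3)[order(lib$sequence)])
})

test_that("quality rule discards reads with any insert base at Q <= 32", {
  lib <- mimotope_library("ACDEFGH", 1, "A")
  reads <- generate_reads(lib, p5, p3, seed = 2)
  qv <- rep(37L, nchar(as.character(reads)[1]))
  at_33 <- qv; at_33[nchar(p5) + 10] <- 33L
  at_32 <- qv; at_32[nchar(p5) + 10] <- 32L
  mk <- function(q) Biostrings::QualityScaledDNAStringSet(
    as(reads, "DNAStringSet"), Biostrings::PhredQuality(intToUtf8(q + 33L)))
  expect_equal(sum(extract_inserts(mk(at_33), p5, p3)$count), 1L)
  out <- extract_inserts(mk(at_32), p5, p3)
  expect_equal(nrow(out), 0L)
  expect_equal(unname(attr(out, "rejects")["low_quality"]), 1L)
  # a low-quality primer base does not discard the read
  primer_low <- qv; primer_low[3] <- 10L
  expect_equal(sum(extract_inserts(mk(primer_low), p5, p3)$count), 1L)
})

test_that("stop-codon inserts are discarded and logged", {
  insert <- paste0("TAG", "GCTGCTGCTGCTGCTGCT")  # amber + 6x Ala
  read <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(paste0(p5, insert, p3)),
    Biostrings::PhredQuality(strrep("H", nchar(p5) + 21 + nchar(p3))))
  out <- extract_inserts(read, p5, p3)
  expect_equal(nrow(out), 0L)
  expect_equal(unname(attr(out, "rejects")["stop_codon"]), 1L)
})

test_that("a configurable fraction of degraded reads is lost at ingestion", {
  lib <- mimotope_library(random_peptides(40), 10, "A")
  reads <- generate_reads(lib, p5, p3, low_quality_fraction = 0.1, seed = 6)
  tab <- extract_inserts(reads, p5, p3)
  retained <- sum(tab$count) / 400
  # binomial tolerance around 90%
  expect_gt(retained, 0.9 - 3 * sqrt(0.1 * 0.9 / 400))
  expect_lt(retained, 0.9 + 3 * sqrt(0.1 * 0.9 / 400))
})

test_that("copy-number filter keeps the closed interval [3, 10]", {
  lib <- mimotope_library(c("ACDEFGH", "CDEFGHA", "DEFGHAC", "EFGHACD"),
                          c(2, 3, 10, 11), "A")
  kept <- filter_copy_number(lib)
  expect_setequal(kept$sequence, c("CDEFGHA", "DEFGHAC"))
  expect_equal(filter_copy_number(lib, 1, Inf)$sequence, lib$sequence)
  # idempotence
  expect_equal(filter_copy_number(kept), kept)
  # retained fraction equals the histogram mass on [3, 10]
  set.seed(3)
  counts <- sample(1:20, 500, replace = TRUE)
  lib2 <- mimotope_library(random_peptides(500), counts, "A")
  expect_equal(nrow(filter_copy_number(lib2)),
               sum(counts >= 3 & counts <= 10))
  expect_warning(filter_copy_number(mimotope_library("ACDEFGH", 1, "A")),
                 "removed every")
})

test_that("exclusion list removal is an exact set difference", {
  lib <- mimotope_library(c("ACDEFGH", "CDEFGHA", "DEFGHAC"), 5, "A")
  expect_equal(apply_exclusion_list(lib, character(0))$sequence,
               lib$sequence)
  out <- apply_exclusion_list(lib, "CDEFGHA")
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "removed")$reason, "TUP")
  expect_warning(apply_exclusion_list(lib, lib$sequence), "every sequence")
  # idempotence
  expect_equal(apply_exclusion_list(out, "CDEFGHA")$sequence, out$sequence)
})

test_that("pooling unions sequences, flags membership and counts overlaps", {
  a <- mimotope_library(c("ACDEFGH", "CDEFGHA"), c(3, 4), "A")
  c_ <- mimotope_library(c("CDEFGHA", "DEFGHAC"), c(5, 6), "C")
  pooled <- pool_libraries(list(A = a, C = c_))
  expect_equal(nrow(pooled), 3L)
  ov <- attr(pooled, "overlaps")
  expect_equal(ov["A", "C"], 1)
  common <- pooled[pooled$sequence == "CDEFGHA", ]
  expect_equal(common$libs, "A,C")
  expect_equal(common$count, 9L)
  # disjoint toy libraries
  d <- pool_libraries(list(P = mimotope_library("ACDEFGH", 1, "P"),
                           Q = mimotope_library("MNPQRST", 1, "Q")))
  expect_equal(nrow(d), 2L)
  expect_equal(attr(d, "overlaps")["P", "Q"], 0)
  # pooling a library with itself
  s <- pool_libraries(list(X = a, Y = a))
  expect_equal(nrow(s), nrow(a))
  expect_equal(attr(s, "overlaps")["X", "Y"], nrow(a))
  # projection recovers the originals
  expect_setequal(project_library(pooled, "A")$sequence, a$sequence)
  expect_setequal(project_library(pooled, "C")$sequence, c_$sequence)
})

test_that("TSV and FASTA round trips preserve the library", {
  lib <- mimotope_library(random_peptides(20), sample(1:9, 20, TRUE), "A")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_library_tsv(lib, tsv)
  back <- read_library_tsv(tsv, label = "A")
  expect_equal(back$sequence, lib$sequence)
  expect_equal(back$count, lib$count)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_library_fasta(lib, fa)
  expect_setequal(read_peptide_list(fa), lib$sequence)
})

test_that("library constructor enforces its invariants", {
  expect_error(mimotope_library(c("ACDEFGH", "ACDEFGH")), "unique")
  expect_error(mimotope_library("ACDEF"), "7-mers")
  expect_error(mimotope_library("ACDEFGB"), "non-standard")
  expect_error(mimotope_library("ACDEFGH", 0), ">= 1")
})
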
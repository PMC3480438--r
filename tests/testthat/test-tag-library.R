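test_that("constructed single-site transcript yields exactly one sense tag", {
  lib <- build_tag_library(c(g1 = paste0("AAA", "CATG", strrep("A", 17))))
  sense <- lib$occurrences[strand == "sense"]
  expect_equal(nrow(sense), 1)
  expect_equal(sense$tag, paste0("CATG", strrep("A", 17)))
  expect_equal(sense$offset, 3)   # 0-based position of the C
  expect_equal(sense$gene_id, "g1")
})

test_that("genes without any CATG site are absent from the tag-bearing set", {
  lib <- build_tag_library(tiny_reference())
  expect_false("g2" %in% lib$occurrences$gene_id)
  expect_equal(lib$report$n_tag_bearing_genes, 2)
  expect_equal(lib$report$n_genes, 3)
})

test_that("library construction rejects bad input and skips non-ACGT sites", {
  expect_error(build_tag_library(character(0)), "empty")
  expect_error(build_tag_library(c(g = "ACGT", g = "ACGT")), "duplicate")
  with_n <- c(g1 = paste0("CATG", strrep("A", 8), "N", strrep("A", 8),
                          "TT", "CATG", strrep("C", 17)))
  lib <- build_tag_library(with_n)
  ## the N falls inside one candidate window on each strand
  expect_equal(lib$report$n_skipped_sites, 2)
  expect_equal(nrow(lib$occurrences[strand == "sense"]), 1)
  expect_false(any(grepl("N", lib$occurrences$tag, fixed = TRUE)))
})

test_that("library matches the brute-force scanner on a synthetic reference", {
  ex <- small_experiment(n_genes = 200, seed = 31)
  seqs <- ex$tr$sequence
  names(seqs) <- ex$tr$gene_id
  lib <- build_tag_library(ex$tr)
  oracle <- oracle_scan_tags(seqs)
  got <- data.table::as.data.table(lib$occurrences)
  data.table::setkey(oracle, tag, gene_id, strand, offset)
  data.table::setkey(got, tag, gene_id, strand, offset)
  expect_equal(nrow(got), nrow(oracle))
  expect_identical(as.data.frame(got), as.data.frame(oracle))
  ## per-strand occurrence counts agree too
  expect_equal(table(got$strand), table(oracle$strand))
})

test_that("reverse-complementing the reference swaps the strand labels", {
  ex <- small_experiment(n_genes = 60, seed = 37)
  seqs <- ex$tr$sequence
  names(seqs) <- ex$tr$gene_id
  fwd <- build_tag_library(seqs)
  rev <- build_tag_library(oracle_revcomp(seqs))
  tf <- table(fwd$occurrences$strand)
  tr <- table(rev$occurrences$strand)
  expect_equal(unname(tf[["sense"]]), unname(tr[["antisense"]]))
  expect_equal(unname(tf[["antisense"]]), unname(tr[["sense"]]))
  ## and the tag sets are identical
  expect_setequal(fwd$occurrences$tag, rev$occurrences$tag)
})

test_that("rebuilding from the same FASTA is bit-identical", {
  ex <- small_experiment(n_genes = 40, seed = 41)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(ex$tr, fa)
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_tag_library(build_tag_library(fa), t1)
  write_tag_library(build_tag_library(fa), t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("lookup separates perfect, one-mismatch and unknown tags", {
  ref <- c(g1 = paste0("AAA", "CATG", strrep("A", 17)),
           g2 = paste0("CC", "CATG", strrep("C", 17)))
  lib <- build_tag_library(ref)
  t1 <- paste0("CATG", strrep("A", 17))
  hit <- lookup_tags(t1, lib)
  expect_equal(nrow(hit[match_class == "PM-sense"]), 1)
  expect_equal(hit$gene_id[hit$match_class == "PM-sense"], "g1")

  ## mismatch at variable-region position 9 (tag position 13)
  t2 <- t1
  substr(t2, 13, 13) <- "G"
  hit2 <- lookup_tags(t2, lib)
  expect_equal(nrow(hit2), 1)
  expect_equal(hit2$match_class, "1MM-sense")
  expect_equal(hit2$gene_id, "g1")

  ## two mismatches: unknown
  t3 <- t2
  substr(t3, 14, 14) <- "G"
  expect_equal(nrow(lookup_tags(t3, lib)), 0)

  ## anchor mismatches never count toward the allowance
  t4 <- t1
  substr(t4, 2, 2) <- "C"   # CATG -> CCTG
  expect_equal(nrow(lookup_tags(t4, lib)), 0)

  expect_error(lookup_tags("CATG", lib), "length")
})

test_that("1-mismatch lookup agrees with an exhaustive Hamming scan", {
  ex <- small_experiment(n_genes = 60, seed = 43)
  lib <- build_tag_library(ex$tr)
  occ <- lib$occurrences
  set.seed(43)
  ## queries: real tags, mutated tags, and random tags
  real <- sample(occ$tag, 40)
  mut <- vapply(sample(occ$tag, 40), function(t) {
    p <- sample(5:21, 1)
    substr(t, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(t, p, p)), 1)
    t
  }, character(1), USE.NAMES = FALSE)
  rand <- paste0("CATG", vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = ""),
    character(1)))
  qry <- unique(c(real, mut, rand))
  got <- lookup_tags(qry, lib)
  for (tg in qry) {
    expected <- oracle_lookup(tg, occ)
    g <- got[tag == tg]
    if (is.null(expected)) {
      expect_equal(nrow(g), 0)
    } else {
      expect_setequal(paste(g$gene_id, g$strand),
                      paste(expected$gene_id, expected$strand))
      expect_true(all(startsWith(g$match_class,
                                 if (expected$pm[1]) "PM" else "1MM")))
    }
  }
})
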
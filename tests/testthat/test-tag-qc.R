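adapter28 <- "TCGTATGCCGTCTTCTGCTTGAAAAAAA"

## build a 49 nt read from a 21 nt tag
mk_read <- function(tag) paste0(tag, substr(adapter28, 1, 49 - nchar(tag)))

test_that("the five filters classify a constructed batch exactly", {
  good <- paste0("CATG", strrep("A", 17))
  lone <- paste0("CATG", strrep("C", 17))
  withn <- paste0("CATG", "N", strrep("G", 16))
  adapter_only <- substr(strrep(adapter28, 2), 1, 49)
  reads <- c(rep(mk_read(good), 10), mk_read(lone), mk_read(withn),
             adapter_only)
  tcs <- filter_raw_tags(reads, adapter28)
  expect_equal(tcs$totals$raw_total, 13)
  expect_equal(tcs$totals$clean_total, 10)
  expect_equal(tcs$totals$clean_distinct, 1)
  expect_equal(tcs$counts$tag, good)
  expect_equal(tcs$counts$count, 10)
  expect_equal(tcs$discards$singleton[["total"]], 1)
  expect_equal(tcs$discards$n_containing[["total"]], 1)
  expect_equal(tcs$discards$adapter_only[["total"]], 1)
  expect_equal(tcs$discards$bad_length[["total"]], 0)
})

test_that("a batch of only valid repeated tags passes through unchanged", {
  tags <- paste0("CATG", c(strrep("A", 17), strrep("G", 17)))
  reads <- rep(vapply(tags, mk_read, character(1)), times = c(3, 2))
  tcs <- filter_raw_tags(reads, adapter28)
  expect_equal(tcs$totals$clean_total, tcs$totals$raw_total)
  expect_equal(sort(tcs$counts$count), c(2, 3))
})

test_that("filters reject invalid inputs", {
  expect_error(filter_raw_tags(character(0), adapter28), "zero reads")
  expect_error(filter_raw_tags("ACGT", "CATGN"), "N")
  expect_error(filter_raw_tags("ACGT", ""), "adapter")
})

test_that("QC discard accounting matches simulator truth labels", {
  ex <- small_experiment(n_genes = 150, depth = 3e4, seed = 53, error = 0)
  reads <- suppressWarnings(
    simulate_tag_reads(ex$tr, ex$truth, ex$cfg, "A"))
  tcs <- filter_raw_tags(reads)
  truth_n <- table(reads$truth$category)
  expect_equal(tcs$discards$adapter_only[["total"]],
               unname(truth_n[["adapter_only"]]))
  expect_equal(tcs$discards$n_containing[["total"]],
               unname(truth_n[["n_read"]]))
  ## noise tags are singletons by construction; at error 0 every biological
  ## tag collides with its gene-mates, so the singleton discard is exactly
  ## the noise category (plus any true singleton biological draw)
  bio_tags <- table(substr(reads$reads, 1, 21)[
    reads$truth$category == "biological"])
  bio_singletons <- sum(bio_tags == 1)
  expect_equal(tcs$discards$singleton[["total"]],
               unname(truth_n[["singleton"]]) + bio_singletons)
  expect_equal(tcs$discards$bad_length[["total"]], 0)
  ## conservation ledger
  expect_equal(tcs$totals$raw_total,
               tcs$totals$clean_total +
                 sum(vapply(tcs$discards, `[[`, numeric(1), "total")))
})

test_that("every clean tag is CATG plus 17 ACGT bases and re-running is identical", {
  ex <- small_experiment(n_genes = 100, depth = 2e4, seed = 59,
                         error = 0.01)
  reads <- suppressWarnings(
    simulate_tag_reads(ex$tr, ex$truth, ex$cfg, "A"))
  t1 <- filter_raw_tags(reads)
  t2 <- filter_raw_tags(reads)
  expect_true(all(grepl("^CATG[ACGT]{17}$", t1$counts$tag)))
  expect_true(all(t1$counts$count >= 2))
  expect_identical(t1$counts, t2$counts)
})

test_that("copy-number bins follow the documented edges", {
  tcs <- structure(list(
    counts = data.table::data.table(
      tag = paste0("CATG", strrep("A", 17), 1:5),
      count = c(2L, 5L, 6L, 100L, 101L)),
    params = list(min_copies = 2L)), class = "tag_count_set")
  d <- copy_number_distribution(tcs)
  expect_equal(d$n_distinct[d$bin == "[2,5]"], 2)
  expect_equal(d$n_distinct[d$bin == "[6,10]"], 1)
  expect_equal(d$n_distinct[d$bin == "[11,20]"], 0)
  expect_equal(d$n_distinct[d$bin == "[51,100]"], 1)
  expect_equal(d$n_distinct[d$bin == ">100"], 1)
  expect_equal(sum(d$share_distinct), 1)
  expect_equal(sum(d$share_total), 1)

  all3 <- structure(list(
    counts = data.table::data.table(tag = c("a", "b"), count = c(3L, 3L)),
    params = list(min_copies = 2L)), class = "tag_count_set")
  d3 <- copy_number_distribution(all3)
  expect_equal(d3$share_distinct[d3$bin == "[2,5]"], 1)
  expect_equal(d3$share_total[d3$bin == "[2,5]"], 1)
})

test_that("clean-tag fraction tracks the configured contaminant load", {
  ## with per-base errors off, the only losses are the injected contaminants
  ## (~1.6% here), so the clean fraction must sit within 2 points of target
  ex <- small_experiment(n_genes = 200, depth = 5e4, seed = 107, error = 0,
                         adapter_only_rate = 0.005, n_read_rate = 0.005,
                         singleton_rate = 0.006)
  reads <- suppressWarnings(
    simulate_tag_reads(ex$tr, ex$truth, ex$cfg, "A"))
  tcs <- filter_raw_tags(reads)
  target <- 1 - (0.005 + 0.005 + 0.006)
  got <- tcs$totals$clean_total / tcs$totals$raw_total
  expect_lt(abs(got - target), 0.02)
})

test_that("saturation curve starts at zero, ends at the mapped gene count, and is stable across seeds", {
  ex <- small_experiment(n_genes = 150, depth = 5e4, seed = 61)
  reads <- suppressWarnings(
    simulate_tag_reads(ex$tr, ex$truth, ex$cfg, "A"))
  tcs <- filter_raw_tags(reads)
  lib <- build_tag_library(ex$tr)
  sat <- saturation_curve(tcs, lib, n_points = 10, seed = 1)
  expect_equal(sat$depth[1], 0)
  expect_equal(sat$genes_detected[1], 0)
  m <- map_tags(tcs, lib)
  expect_equal(sat$genes_detected[nrow(sat)],
               m$totals$genes_unambiguous_mapped)
  expect_true(all(diff(sat$genes_detected) >= 0))
  ## half-depth detection varies little between subsampling seeds
  s1 <- saturation_curve(tcs, lib, n_points = 2, seed = 1)
  s2 <- saturation_curve(tcs, lib, n_points = 2, seed = 2)
  half1 <- s1$genes_detected[2]
  half2 <- s2$genes_detected[2]
  expect_lt(abs(half1 - half2) / max(half1, half2), 0.05)
  expect_error(saturation_curve(tcs, lib, n_points = 1), "n_points")
})
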
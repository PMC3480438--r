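mk_tcs <- function(tags, counts, clean_total = sum(counts)) {
  data.table::data.table(tag = tags, count = as.integer(counts))
}

test_that("a unique perfect match credits its gene with the copy number", {
  ref <- c(g1 = paste0("AAA", "CATG", strrep("A", 17)))
  lib <- build_tag_library(ref)
  m <- map_tags(mk_tcs(paste0("CATG", strrep("A", 17)), 50), lib)
  expect_equal(m$totals$all_mapped_total, 50)
  expect_equal(m$totals$unambiguous_total, 50)
  expect_equal(m$totals$unknown_total, 0)
  expect_equal(m$expression[gene_id == "g1", count], 50L)
  expect_equal(m$expression[gene_id == "g1", tpm], 1e6)
})

test_that("a tag shared by two genes maps but is not quantified", {
  shared <- paste0("CATG", strrep("A", 17))
  ref <- c(g1 = paste0("AAA", shared), g2 = paste0("TT", shared, "GG"))
  lib <- build_tag_library(ref)
  expect_equal(lib$report$n_ambiguous_tags, 1)
  m <- map_tags(mk_tcs(shared, 10), lib)
  expect_equal(m$totals$all_mapped_total, 10)
  expect_equal(m$totals$unambiguous_total, 0)
  expect_equal(sum(m$expression$count), 0)
  expect_equal(m$totals$genes_all_mapped, 2)
  expect_equal(m$totals$genes_unambiguous_mapped, 0)
})

test_that("a tag hitting one gene at several sites stays unambiguous", {
  tagA <- paste0("CATG", strrep("A", 17))
  ref <- c(g1 = paste0(tagA, "CC", tagA))
  lib <- build_tag_library(ref)
  expect_equal(lib$tags[tag == tagA, n_genes], 1L)
  m <- map_tags(mk_tcs(tagA, 7), lib)
  expect_equal(m$expression[gene_id == "g1", count], 7L)
})

test_that("exact-match priority keeps a PM-unique tag unambiguous despite 1MM hits elsewhere", {
  tagA <- paste0("CATG", strrep("A", 17))
  tagB <- paste0("CATG", strrep("A", 16), "G")   # 1 mismatch from tagA
  ref <- c(g1 = paste0("TT", tagA), g2 = paste0("CC", tagB))
  lib <- build_tag_library(ref)
  m <- map_tags(mk_tcs(tagA, 5), lib)
  expect_equal(m$tags$match_class, "PM-sense")
  expect_equal(m$tags$n_genes, 1L)
  expect_equal(m$expression[gene_id == "g1", count], 5L)
  expect_equal(m$expression[gene_id == "g2", count], 0L)
})

test_that("per-gene counts equal a brute-force mapper on noisy simulated data", {
  ex <- small_experiment(n_genes = 80, depth = 2e4, seed = 67,
                         error = 0.005)
  reads <- suppressWarnings(
    simulate_tag_reads(ex$tr, ex$truth, ex$cfg, "A"))
  tcs <- filter_raw_tags(reads)
  lib <- build_tag_library(ex$tr)
  m <- map_tags(tcs, lib)

  ## brute force: exhaustive Hamming classification of every clean tag
  occ <- lib$occurrences
  expected <- new.env()
  for (i in seq_len(nrow(tcs$counts))) {
    hits <- oracle_lookup(tcs$counts$tag[i], occ)
    if (is.null(hits)) next
    genes <- unique(hits$gene_id)
    if (length(genes) == 1L) {
      cur <- mget(genes, expected, ifnotfound = 0L)[[1]]
      assign(genes, cur + tcs$counts$count[i], expected)
    }
  }
  got <- m$expression[count > 0]
  exp_counts <- unlist(as.list(expected))
  expect_setequal(got$gene_id, names(exp_counts))
  expect_equal(got$count[match(names(exp_counts), got$gene_id)],
               unname(exp_counts))
})

test_that("error-free simulation with unique tags recovers truth draws exactly", {
  ex <- small_experiment(n_genes = 80, depth = 2e4, seed = 71, error = 0,
                         adapter_only_rate = 0, n_read_rate = 0,
                         singleton_rate = 0)
  reads <- suppressWarnings(
    simulate_tag_reads(ex$tr, ex$truth, ex$cfg, "A"))
  tcs <- filter_raw_tags(reads)
  lib <- build_tag_library(ex$tr)
  m <- map_tags(tcs, lib)
  truth_counts <- table(reads$truth$gene_id)
  ## compare over genes whose 3'-most tag is unambiguous and kept (copies>=2)
  for (g in names(truth_counts)) {
    tc <- truth_counts[[g]]
    if (tc < 2) next
    got <- m$expression[gene_id == g, count]
    expect_equal(got, tc)
  }
})

test_that("TPM normalisation is the documented linear scale", {
  expect_equal(tpm_normalize(50, 1e6), 50)
  expect_equal(tpm_normalize(0, 123), 0)
  expect_error(tpm_normalize(1, 0), "positive")
  expect_error(tpm_normalize(-1, 10), "non-negative")
})

test_that("mapping accounting identities hold on simulated data", {
  ex <- small_experiment(n_genes = 120, depth = 3e4, seed = 73,
                         error = 0.01)
  reads <- suppressWarnings(
    simulate_tag_reads(ex$tr, ex$truth, ex$cfg, "A"))
  tcs <- filter_raw_tags(reads)
  lib <- build_tag_library(ex$tr)
  m <- map_tags(tcs, lib)
  t <- m$totals
  expect_equal(t$all_mapped_total + t$unknown_total, t$clean_total)
  expect_equal(t$all_mapped_distinct + t$unknown_distinct, t$clean_distinct)
  expect_lte(t$unambiguous_total, t$all_mapped_total)
  expect_equal(sum(m$expression$count), t$unambiguous_total)
  expect_equal(m$expression$count,
               m$expression$count_sense + m$expression$count_antisense)
  ## sum of TPM = (unambiguous total / clean total) * 1e6
  expect_equal(sum(m$expression$tpm),
               t$unambiguous_total / t$clean_total * 1e6)
})

test_that("raising the error rate shifts mass from PM to 1MM and unknown", {
  shares <- lapply(c(0, 0.01, 0.03), function(e) {
    ex <- small_experiment(n_genes = 100, depth = 2e4, seed = 79, error = e,
                           adapter_only_rate = 0, n_read_rate = 0,
                           singleton_rate = 0)
    reads <- suppressWarnings(
      simulate_tag_reads(ex$tr, ex$truth, ex$cfg, "A"))
    tcs <- filter_raw_tags(reads)
    m <- map_tags(tcs, build_tag_library(ex$tr))
    pm <- m$tags[startsWith(match_class, "PM"), sum(count)]
    c(pm = pm / m$totals$clean_total,
      rest = 1 - pm / m$totals$clean_total)
  })
  pm_share <- vapply(shares, `[[`, numeric(1), "pm")
  expect_true(all(diff(pm_share) < 0))
})
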
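## Independent oracles used across the suite. These deliberately share no
## code with the package internals they check.

suppressMessages(library(data.table))

oracle_revcomp <- function(x) {
  out <- vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA",
                     strsplit(s, "", fixed = TRUE)[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(x)
  out
}

## brute-force virtual tag scan: slide a 21 nt window over both strands of
## every sequence and keep windows with prefix CATG
oracle_scan_tags <- function(seqs) {
  stopifnot(!is.null(names(seqs)))
  recs <- list()
  for (g in names(seqs)) {
    for (strand in c("sense", "antisense")) {
      s <- if (strand == "sense") seqs[[g]] else oracle_revcomp(seqs[[g]])
      n <- nchar(s)
      if (n < 21) next
      for (i in seq_len(n - 20)) {
        w <- substr(s, i, i + 20)
        if (startsWith(w, "CATG") && grepl("^[ACGT]+$", w))
          recs[[length(recs) + 1L]] <-
            data.table(tag = w, gene_id = g, strand = strand,
                       offset = i - 1L)
      }
    }
  }
  rbindlist(recs)
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## exhaustive <=1-mismatch lookup over a reference occurrence table, with
## exact-match priority and the CATG anchor held fixed
oracle_lookup <- function(tag, occ) {
  d <- vapply(occ$tag, oracle_hamming, numeric(1), a = tag)
  anchor_ok <- substr(occ$tag, 1, 4) == substr(tag, 1, 4)
  exact <- which(d == 0)
  if (length(exact)) {
    hits <- occ[exact]
    hits$pm <- TRUE
  } else {
    near <- which(d == 1 & anchor_ok)
    if (!length(near)) return(NULL)
    hits <- occ[near]
    hits$pm <- FALSE
  }
  unique(hits[, .(gene_id, strand, pm)])
}

## AC conditional pmf is negative binomial: p(y | x) = dnbinom(y, x + 1, q)
## with q = N1 / (N1 + N2)
oracle_ac_pmf <- function(y, x, n1, n2) {
  dnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
}

## doubled-tail two-sided p in the canonical orientation (condition on the
## higher-rate library), via the negative-binomial tail functions
oracle_ac_two_sided <- function(x, y, n1, n2) {
  if (!(x / n1 > y / n2 || (x / n1 == y / n2 && x >= y))) {
    tmp <- x; x <- y; y <- tmp
    tmp <- n1; n1 <- n2; n2 <- tmp
  }
  q <- n1 / (n1 + n2)
  lower <- pnbinom(y, size = x + 1, prob = q)
  upper <- pnbinom(y - 1, size = x + 1, prob = q, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

## direct summation of the hypergeometric upper tail with choose()
oracle_hyper_upper <- function(N, M, n, m) {
  i <- m:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

## small fixed reference set used by several construction tests
tiny_reference <- function() {
  c(g1 = paste0("AAA", "CATG", strrep("A", 17)),          # one sense site
    g2 = strrep("T", 40),                                  # no CATG anywhere
    g3 = paste0("GG", "CATG", strrep("C", 17), "TTTT",
                "CATG", strrep("G", 17)))                  # two sense sites
}

## bare expression vector for driving the DE caller with arbitrary counts
mk_expr <- function(counts, clean_total) {
  d <- data.table::data.table(gene_id = names(counts),
                              count = as.integer(counts),
                              tpm = counts * 1e6 / clean_total)
  data.table::setattr(d, "clean_total", clean_total)
  data.table::setattr(d, "class", c("expression_vector", class(d)))
  d
}

## deterministic synthetic experiment shared by heavier tests
small_experiment <- function(n_genes = 200, depth = 2e4, seed = 101,
                             error = 0, ...) {
  cfg <- sim_config(n_genes = n_genes, depth = depth, seed = seed,
                    base_error_rate = error, ...)
  tr <- simulate_transcriptome(cfg)
  truth <- suppressWarnings(simulate_truth(tr, n_de = 20, seed = seed))
  list(cfg = cfg, tr = tr, truth = truth)
}
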
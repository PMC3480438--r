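#' Simulation settings for synthetic DGE experiments
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object: the size and length distribution of the reference transcript set,
#' the sequencing depth of each tag library, and the rates of the error and
#' contaminant processes observed in real tag sequencing runs (per-base
#' substitution errors, adapter-only reads, reads containing \code{N}, and
#' spurious tags seen exactly once).
#'
#' @param n_genes Number of reference transcripts to simulate.
#' @param mean_length Mean transcript length in bases (log-normal model).
#' @param length_sdlog Standard deviation of log length.
#' @param min_length Minimum transcript length in bases (>= 100).
#' @param gc_mean,gc_sd Per-transcript GC content is drawn from a normal
#'   distribution with these parameters, truncated to \[0.25, 0.60\].
#' @param catg_fraction Fraction of transcripts guaranteed to carry at least
#'   one sense-strand CATG site with 17 bases downstream (a usable tag site).
#' @param depth Number of raw reads per simulated library.
#' @param base_error_rate Per-base substitution error probability applied to
#'   the 21 nt tag portion of each biological read.
#' @param adapter_only_rate Probability that a read is an empty-insert,
#'   adapter-only read.
#' @param n_read_rate Probability that a read carries an undetermined base
#'   (\code{N}) in its tag.
#' @param singleton_rate Probability that a read is a spurious random tag
#'   emitted exactly once in the library.
#' @param adapter 3' adapter sequence used to pad tags to the read length.
#' @param read_length Raw read length in nt (default 49).
#' @param seed Integer seed; identical configurations give bit-identical
#'   output files.
#'
#' @return An object of class \code{"sim_config"} (a named list).
#' @export
sim_config <- function(n_genes = 1000L,
                       mean_length = 676,
                       length_sdlog = 0.7,
                       min_length = 100L,
                       gc_mean = 0.42,
                       gc_sd = 0.05,
                       catg_fraction = 0.95,
                       depth = 2e5,
                       base_error_rate = 0.005,
                       adapter_only_rate = 0.005,
                       n_read_rate = 0.005,
                       singleton_rate = 0.005,
                       adapter = "TCGTATGCCGTCTTCTGCTTGAAAAAAA",
                       read_length = 49L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), mean_length = mean_length,
    length_sdlog = length_sdlog, min_length = as.integer(min_length),
    gc_mean = gc_mean, gc_sd = gc_sd, catg_fraction = catg_fraction,
    depth = as.integer(depth), base_error_rate = base_error_rate,
    adapter_only_rate = adapter_only_rate, n_read_rate = n_read_rate,
    singleton_rate = singleton_rate, adapter = toupper(adapter),
    read_length = as.integer(read_length), seed = as.integer(seed)
  )
  chk_count <- function(field, min) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < min)
      stop(sprintf("invalid '%s': must be a single value >= %s", field, min),
           call. = FALSE)
  }
  chk_rate <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("invalid '%s': must lie in [0, 1]", field), call. = FALSE)
  }
  chk_count("n_genes", 1L)
  chk_count("depth", 1L)
  chk_count("min_length", 100L)
  chk_count("read_length", 21L)
  chk_count("mean_length", 100)
  for (f in c("catg_fraction", "base_error_rate", "adapter_only_rate",
              "n_read_rate", "singleton_rate"))
    chk_rate(f)
  if (cfg$adapter_only_rate + cfg$n_read_rate + cfg$singleton_rate >= 1)
    stop("invalid contaminant rates: 'adapter_only_rate' + 'n_read_rate' + ",
         "'singleton_rate' must be < 1", call. = FALSE)
  if (!grepl("^[ACGT]+$", cfg$adapter))
    stop("invalid 'adapter': must contain only A/C/G/T", call. = FALSE)
  if (is.na(cfg$seed) || abs(cfg$seed) > 2^31 - 10)
    stop("invalid 'seed': must be a 32-bit integer", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic reference transcriptome
#'
#' Draws transcript lengths from a log-normal distribution and sequences as
#' i.i.d. bases at a per-transcript GC content. A configured fraction of
#' transcripts is guaranteed to carry at least one usable tag site (a sense
#' strand \code{CATG} with 17 bases downstream); the remainder is scrubbed of
#' all sense-strand \code{CATG} occurrences, emulating genes invisible to
#' tag profiling.
#'
#' @param config A [sim_config()] object.
#' @return A \code{data.table} of class \code{"synthetic_transcriptome"} with
#'   columns \code{gene_id}, \code{sequence}, \code{length}, and
#'   \code{has_tag_site}; the configuration is stored as an attribute.
#' @seealso [write_fasta()], [simulate_truth()], [simulate_tag_reads()]
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    len <- pmax(config$min_length,
                round(rlnorm(n,
                             meanlog = log(config$mean_length) -
                               config$length_sdlog^2 / 2,
                             sdlog = config$length_sdlog)))
    gc <- pmin(0.60, pmax(0.25, rnorm(n, config$gc_mean, config$gc_sd)))
    seqs <- random_dna(len, gc)
    bearing <- runif(n) < config$catg_fraction
    for (i in seq_len(n)) {
      if (bearing[i]) {
        if (length(sense_tag_sites(seqs[i])) == 0L) {
          pos <- sample.int(len[i] - 20L, 1L)
          substr(seqs[i], pos, pos + 3L) <- "CATG"
        }
      } else {
        ## remove every sense CATG; substitution can create new sites, so loop
        while (grepl("CATG", seqs[i], fixed = TRUE)) {
          pos <- regexpr("CATG", seqs[i], fixed = TRUE)
          substr(seqs[i], pos + 1L, pos + 1L) <-
            sample(c("C", "G", "T"), 1L)
        }
      }
    }
    out <- data.table(
      gene_id = sprintf("gene%04d", seq_len(n)),
      sequence = seqs,
      length = nchar(seqs),
      has_tag_site = vapply(seqs, function(s)
        length(sense_tag_sites(s)) > 0L, logical(1), USE.NAMES = FALSE)
    )
    setattr(out, "config", config)
    setattr(out, "class", c("synthetic_transcriptome", class(out)))
    out[]
  })
}

## 1-based start positions of sense-strand CATG sites with >= 17 nt downstream
sense_tag_sites <- function(seq) {
  m <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  m <- as.integer(m)
  m[m + 20L <= nchar(seq)]
}

## the 21 nt tag released at the 3'-most usable sense CATG site, or NA
tag_3prime <- function(seq) {
  sites <- sense_tag_sites(seq)
  if (length(sites) == 0L) return(NA_character_)
  p <- max(sites)
  substr(seq, p, p + 20L)
}

#' Simulate a ground-truth abundance table for two conditions
#'
#' Assigns each gene a relative abundance in conditions A and B. A chosen set
#' of genes is planted as differentially expressed with a fixed absolute
#' log2 fold change; all other genes keep the same relative abundance up to
#' the renormalisation induced by the planted changes. Planted genes are
#' drawn from transcripts that carry a usable tag site and have their
#' baseline abundance floored so they are comfortably detectable.
#'
#' @param transcriptome A [simulate_transcriptome()] result.
#' @param n_de Number of genes planted as differentially expressed.
#' @param log2fc Absolute log2 fold change of planted genes (sign is
#'   randomised per gene).
#' @param de_threshold Absolute log2 fold change above which a gene is
#'   labelled \code{is_de} (applied to the realised, post-normalisation fold
#'   change).
#' @param min_de_abundance Floor on the baseline relative abundance of
#'   planted genes.
#' @param abund_sdlog Spread (log scale) of the baseline abundance
#'   distribution.
#' @param seed Integer seed.
#' @return A \code{data.table} of class \code{"truth_table"} with columns
#'   \code{gene_id}, \code{abund_a}, \code{abund_b}, \code{log2fc},
#'   \code{is_de}. Abundances sum to 1 within each condition.
#' @export
simulate_truth <- function(transcriptome, n_de = 50L, log2fc = 3,
                           de_threshold = 1, min_de_abundance = 2e-4,
                           abund_sdlog = 1.2, seed = 1L) {
  stopifnot(inherits(transcriptome, "synthetic_transcriptome"))
  n <- nrow(transcriptome)
  if (n_de > sum(transcriptome$has_tag_site))
    stop("n_de exceeds the number of transcripts with a usable tag site")
  with_seed(seed, {
    base <- rlnorm(n, meanlog = 0, sdlog = abund_sdlog)
    base <- base / sum(base)
    de_idx <- sample(which(transcriptome$has_tag_site), n_de)
    base[de_idx] <- pmax(base[de_idx], min_de_abundance)
    a <- base / sum(base)
    fc <- rep(1, n)
    fc[de_idx] <- 2^(sample(c(-1, 1), n_de, replace = TRUE) * log2fc)
    b <- a * fc
    b <- b / sum(b)
    lfc <- log2(b / a)
    out <- data.table(
      gene_id = transcriptome$gene_id,
      abund_a = a, abund_b = b,
      log2fc = lfc,
      is_de = abs(lfc) >= de_threshold
    )
    setattr(out, "de_threshold", de_threshold)
    setattr(out, "class", c("truth_table", class(out)))
    out[]
  })
}

#' Simulate a raw DGE tag library
#'
#' Emulates one lane of tag sequencing against a known transcriptome.
#' Each biological read is the 21 nt tag released at the 3'-most usable
#' sense-strand \code{CATG} site of a gene drawn from the condition's
#' abundance vector, subjected to per-base substitution errors and padded to
#' the read length with the 3' adapter. Contaminant reads — adapter-only
#' reads, reads with an \code{N} in the tag, and spurious random tags each
#' seen exactly once — are injected at the configured rates. The true
#' category (and source gene, where applicable) of every read is recorded.
#'
#' Genes with nonzero abundance but no usable tag site cannot produce reads;
#' their probability mass is dropped with a warning and the remaining vector
#' renormalised.
#'
#' @param transcriptome A [simulate_transcriptome()] result.
#' @param truth A [simulate_truth()] result over the same genes.
#' @param config The [sim_config()] shared by both libraries.
#' @param condition \code{"A"} or \code{"B"}: which abundance column to use.
#' @return An object of class \code{"tag_reads"}: a list with elements
#'   \code{reads} (character vector of raw read sequences), \code{truth}
#'   (\code{data.table}: \code{read_id}, \code{category}, \code{gene_id}),
#'   \code{condition} and \code{config}.
#' @seealso [write_fastq()], [filter_raw_tags()]
#' @export
simulate_tag_reads <- function(transcriptome, truth, config,
                               condition = c("A", "B")) {
  stopifnot(inherits(transcriptome, "synthetic_transcriptome"),
            inherits(config, "sim_config"))
  condition <- match.arg(condition)
  if (!identical(truth$gene_id, transcriptome$gene_id))
    stop("truth table and transcriptome disagree on gene ids")

  abund <- if (condition == "A") truth$abund_a else truth$abund_b
  tags <- vapply(transcriptome$sequence, tag_3prime, character(1),
                 USE.NAMES = FALSE)
  no_site <- is.na(tags) & abund > 0
  if (any(no_site)) {
    warning(sprintf(
      "%d gene(s) with nonzero abundance lack a usable tag site; %.3g of probability mass reassigned",
      sum(no_site), sum(abund[no_site])))
    abund[no_site] <- 0
    abund <- abund / sum(abund)
  }

  pad <- function(x) {
    if (length(x) == 0L) return(character(0))
    need <- config$read_length - nchar(x[1])
    adapt <- substr(strrep(config$adapter,
                           ceiling(config$read_length / nchar(config$adapter))),
                    1L, need)
    paste0(x, adapt)
  }

  with_seed(config$seed + match(condition, c("A", "B")), {
    depth <- config$depth
    rates <- c(adapter_only = config$adapter_only_rate,
               n_read = config$n_read_rate,
               singleton = config$singleton_rate)
    ncat <- drop(rmultinom(1, depth, c(rates, biological = 1 - sum(rates))))
    n_bio <- ncat[["biological"]]

    ## biological reads: multinomial gene draws, per-base errors in the tag
    gi <- sample.int(nrow(transcriptome), n_bio, replace = TRUE, prob = abund)
    bio <- tags[gi]
    e <- config$base_error_rate
    if (e > 0 && n_bio > 0) {
      for (p in 1:21) {
        hit <- which(runif(n_bio) < e)
        if (length(hit)) {
          cur <- substr(bio[hit], p, p)
          new <- DNA_BASES[(match(cur, DNA_BASES) - 1L +
                              sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
          substr(bio[hit], p, p) <- new
        }
      }
    }

    ## N reads: biological draws with one tag base replaced by N
    n_n <- ncat[["n_read"]]
    gi_n <- if (n_n > 0)
      sample.int(nrow(transcriptome), n_n, replace = TRUE, prob = abund)
    else integer(0)
    nreads <- tags[gi_n]
    if (n_n > 0) {
      pos <- sample.int(21L, n_n, replace = TRUE)
      for (p in unique(pos)) substr(nreads[pos == p], p, p) <- "N"
    }

    ## adapter-only (empty insert) reads
    n_ad <- ncat[["adapter_only"]]
    ad_read <- substr(strrep(config$adapter,
                             ceiling(config$read_length / nchar(config$adapter))),
                      1L, config$read_length)

    ## singleton noise: distinct random CATG+17 tags, one copy each
    n_sg <- ncat[["singleton"]]
    sg <- character(0)
    if (n_sg > 0) {
      repeat {
        sg <- unique(paste0("CATG", vapply(seq_len(n_sg + 8L), function(i)
          paste(sample(DNA_BASES, 17L, replace = TRUE), collapse = ""),
          character(1))))
        if (length(sg) >= n_sg) { sg <- sg[seq_len(n_sg)]; break }
      }
    }

    reads <- c(pad(bio), pad(nreads), rep(ad_read, n_ad),
               if (n_sg > 0) pad(sg) else character(0))
    lab <- data.table(
      category = rep(c("biological", "n_read", "adapter_only", "singleton"),
                     times = c(n_bio, n_n, n_ad, n_sg)),
      gene_id = c(transcriptome$gene_id[gi], transcriptome$gene_id[gi_n],
                  rep(NA_character_, n_ad + n_sg))
    )
    ord <- sample.int(length(reads))
    reads <- reads[ord]
    lab <- lab[ord]
    lab[, read_id := sprintf("read%07d", .I)]
    setcolorder(lab, c("read_id", "category", "gene_id"))

    structure(list(reads = reads, truth = lab, condition = condition,
                   config = config),
              class = "tag_reads")
  })
}

#' Simulate a gene-to-term annotation map
#'
#' Draws term memberships at random from the gene set, optionally planting
#' one term whose members are preferentially taken from the truly
#' differentially expressed genes — a positive control for enrichment
#' power studies.
#'
#' @param truth A [simulate_truth()] result (supplies the gene universe and
#'   the DE labels used for the planted term).
#' @param n_terms Number of terms (>= 1).
#' @param size_range Integer range from which term sizes are drawn uniformly;
#'   a single value gives constant-size terms.
#' @param planted If \code{TRUE}, term \code{"T0001"} is enriched for DE
#'   genes.
#' @param planted_frac Fraction of the planted term's members drawn from DE
#'   genes.
#' @param planted_size Size of the planted term.
#' @param seed Integer seed.
#' @return A \code{data.table} of class \code{"annotation_map"} with columns
#'   \code{gene_id}, \code{term_id}, \code{term_name}.
#' @export
simulate_annotation <- function(truth, n_terms = 50L, size_range = c(5L, 50L),
                                planted = FALSE, planted_frac = 0.8,
                                planted_size = 25L, seed = 1L) {
  stopifnot(inherits(truth, "truth_table"))
  if (n_terms < 1L) stop("n_terms must be >= 1")
  genes <- truth$gene_id
  if (length(genes) == 0L) stop("empty gene list")
  size_range <- as.integer(rep(size_range, length.out = 2L))
  with_seed(seed, {
    recs <- vector("list", n_terms)
    for (t in seq_len(n_terms)) {
      id <- sprintf("T%04d", t)
      if (planted && t == 1L) {
        de <- genes[truth$is_de]
        nde <- min(length(de), round(planted_frac * planted_size))
        members <- c(sample(de, nde),
                     sample(setdiff(genes, de), planted_size - nde))
      } else {
        sz <- if (size_range[1] == size_range[2]) size_range[1]
              else sample(seq(size_range[1], size_range[2]), 1L)
        members <- sample(genes, min(sz, length(genes)))
      }
      recs[[t]] <- data.table(gene_id = members, term_id = id,
                              term_name = paste0("term ", id))
    }
    out <- rbindlist(recs)
    setattr(out, "class", c("annotation_map", class(out)))
    out[]
  })
}

#' Draw per-gene unambiguous tag counts directly from a truth table
#'
#' Bypasses read-level simulation: counts for each condition are one
#' multinomial draw of the given depth from the condition's abundance
#' vector. This is the count-level view of the generative model used by
#' [simulate_tag_reads()], convenient for studying the differential
#' expression caller at scale.
#'
#' @param truth A [simulate_truth()] result.
#' @param depth Library size (total tag count) per condition.
#' @param seed Integer seed.
#' @return A list with integer vectors \code{counts_a}, \code{counts_b}
#'   (named by gene) and the depths \code{n1}, \code{n2}.
#' @export
simulate_counts <- function(truth, depth = 5e5, seed = 1L) {
  stopifnot(inherits(truth, "truth_table"))
  with_seed(seed, {
    ca <- drop(rmultinom(1, depth, truth$abund_a))
    cb <- drop(rmultinom(1, depth, truth$abund_b))
    names(ca) <- names(cb) <- truth$gene_id
    list(counts_a = ca, counts_b = cb, n1 = as.integer(depth),
         n2 = as.integer(depth))
  })
}

#' @export
print.tag_reads <- function(x, ...) {
  cat(sprintf("Simulated tag library (condition %s): %d reads of %d nt\n",
              x$condition, length(x$reads), x$config$read_length))
  print(x$truth[, .N, by = category])
  invisible(x)
}
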
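#' Filter raw reads into clean tags with copy numbers
#'
#' Applies the five filtering steps of tag-library preprocessing, in order:
#' \enumerate{
#'   \item trim the 3' adapter (leftmost full occurrence, else the longest
#'     read suffix matching an adapter prefix of at least \code{min_overlap}
#'     bases);
#'   \item drop reads that are empty after trimming (adapter-only /
#'     empty-insert reads);
#'   \item drop reads whose trimmed tag contains \code{N};
#'   \item drop tags whose copy number in the post-trim, post-N multiset is
#'     exactly 1 (likely sequencing errors);
#'   \item keep only tags of exactly \code{tag_length} nt with the
#'     \code{anchor} prefix.
#' }
#' The result is the clean tag multiset together with a full accounting
#' ledger: raw and clean totals (copies and distinct sequences) and the
#' discard counts per category, which satisfy
#' \code{raw total = clean total + sum(discarded copies)} exactly.
#'
#' @param reads Character vector of raw read sequences, a
#'   [simulate_tag_reads()] result, or a FASTQ path.
#' @param adapter 3' adapter sequence (no \code{N}s).
#' @param min_overlap Minimum read-suffix/adapter-prefix overlap for
#'   end trimming.
#' @param tag_length Expected clean tag length (default 21).
#' @param anchor Required tag prefix (default \code{"CATG"}).
#' @param min_copies Minimum copy number for a clean tag (default 2).
#' @param label Library label carried through reports.
#' @return An object of class \code{"tag_count_set"}: list with
#'   \code{counts} (\code{data.table}: \code{tag}, \code{count}),
#'   \code{totals} (raw/clean, total/distinct) and \code{discards}
#'   (per category: copies and distinct sequences).
#' @export
filter_raw_tags <- function(reads, adapter, min_overlap = 5L,
                            tag_length = 21L, anchor = "CATG",
                            min_copies = 2L, label = "library") {
  if (inherits(reads, "tag_reads")) {
    if (missing(adapter)) adapter <- reads$config$adapter
    label <- if (label == "library") reads$condition else label
    reads <- reads$reads
  } else if (is.character(reads) && length(reads) == 1L &&
             file.exists(reads)) {
    reads <- unname(read_fastq(reads))
  }
  if (length(reads) == 0L) stop("zero reads supplied")
  if (missing(adapter) || !nzchar(adapter)) stop("adapter must be non-empty")
  adapter <- toupper(adapter)
  if (grepl("N", adapter, fixed = TRUE)) stop("adapter must not contain N")

  raw_total <- length(reads)
  raw_distinct <- uniqueN(reads)

  ## step 1: adapter trimming
  trimmed <- trim_adapter(reads, adapter, min_overlap)

  ## step 2: empty after trimming (adapter-only / empty insert)
  empty <- !nzchar(trimmed)
  adapter_only <- trimmed[empty]
  trimmed <- trimmed[!empty]

  ## step 3: N-containing tags
  has_n <- grepl("N", trimmed, fixed = TRUE)
  n_containing <- trimmed[has_n]
  trimmed <- trimmed[!has_n]

  ## step 4: copy number < min_copies on the surviving multiset
  cnt <- data.table(tag = trimmed)[, .(count = .N), by = tag]
  single <- cnt$count < min_copies
  singletons <- cnt[single]
  cnt <- cnt[!single]

  ## step 5: length and anchor
  ok <- nchar(cnt$tag) == tag_length & startsWith(cnt$tag, anchor)
  bad_length <- cnt[!ok]
  cnt <- cnt[ok]
  setkey(cnt, tag)

  discards <- list(
    adapter_only = c(total = length(adapter_only), distinct = 1L * (length(adapter_only) > 0L)),
    n_containing = c(total = length(n_containing),
                     distinct = uniqueN(n_containing)),
    singleton = c(total = sum(singletons$count),
                  distinct = nrow(singletons)),
    bad_length = c(total = sum(bad_length$count),
                   distinct = nrow(bad_length))
  )
  totals <- list(raw_total = raw_total, raw_distinct = raw_distinct,
                 clean_total = sum(cnt$count), clean_distinct = nrow(cnt))
  stopifnot(totals$raw_total == totals$clean_total +
              sum(vapply(discards, function(d) d[["total"]], numeric(1))))
  structure(list(counts = cnt, totals = totals, discards = discards,
                 label = label,
                 params = list(adapter = adapter, min_overlap = min_overlap,
                               tag_length = tag_length, anchor = anchor,
                               min_copies = min_copies)),
            class = "tag_count_set")
}

## trim at the leftmost full adapter occurrence; otherwise at the longest
## read suffix that equals an adapter prefix of >= min_overlap bases
trim_adapter <- function(reads, adapter, min_overlap) {
  pos <- regexpr(adapter, reads, fixed = TRUE)
  cut <- ifelse(pos > 0L, pos - 1L, nchar(reads))
  unresolved <- which(pos < 0L)
  if (length(unresolved)) {
    kmax <- min(nchar(adapter) - 1L, max(nchar(reads[unresolved])))
    for (k in if (kmax >= min_overlap) seq(kmax, min_overlap) else integer(0)) {
      if (length(unresolved) == 0L) break
      hit <- endsWith(reads[unresolved], substr(adapter, 1L, k))
      cut[unresolved[hit]] <- nchar(reads[unresolved[hit]]) - k
      unresolved <- unresolved[!hit]
    }
  }
  substr(reads, 1L, cut)
}

#' Copy-number distribution of clean tags
#'
#' Bins clean tags by copy number and reports, per bin, the share of total
#' tag copies and the share of distinct tag sequences — the two
#' complementary views of library composition (highly expressed tags
#' dominate copies; low-copy tags dominate diversity).
#'
#' @param tags A [filter_raw_tags()] result.
#' @param breaks Upper bin edges; the default gives bins
#'   \code{[2,5], [6,10], [11,20], [21,50], [51,100], >100}.
#' @return A \code{data.frame} with columns \code{bin}, \code{n_distinct},
#'   \code{n_total}, \code{share_distinct}, \code{share_total}.
#' @export
copy_number_distribution <- function(tags,
                                     breaks = c(5, 10, 20, 50, 100, Inf)) {
  stopifnot(inherits(tags, "tag_count_set"))
  if (nrow(tags$counts) == 0L) stop("empty tag count set")
  lo <- c(tags$params$min_copies, head(breaks, -1) + 1)
  fin <- is.finite(breaks)
  lab <- character(length(breaks))
  lab[fin] <- sprintf("[%d,%d]", as.integer(lo[fin]), as.integer(breaks[fin]))
  lab[!fin] <- sprintf(">%d", as.integer(lo[!fin] - 1))
  bin <- cut(tags$counts$count, breaks = c(lo[1] - 1, breaks), labels = lab)
  n_distinct <- as.vector(table(bin))
  n_total <- as.vector(tapply(tags$counts$count, bin, sum, default = 0))
  data.frame(bin = lab, n_distinct = n_distinct, n_total = n_total,
             share_distinct = n_distinct / sum(n_distinct),
             share_total = n_total / sum(n_total))
}

#' Sequencing saturation curve
#'
#' Subsamples the clean tag multiset without replacement on an even depth
#' grid and counts, at each depth, the genes detected by at least one
#' unambiguously mapping tag. A plateau indicates the library depth has
#' saturated gene discovery.
#'
#' @param tags A [filter_raw_tags()] result.
#' @param library A [build_tag_library()] result.
#' @param n_points Number of nonzero grid depths (>= 2).
#' @param seed Integer seed for the subsampling permutation.
#' @param max_mismatch Passed to the mapper.
#' @return A \code{data.frame} with columns \code{depth} and
#'   \code{genes_detected}, starting at depth 0.
#' @export
saturation_curve <- function(tags, library, n_points = 20L, seed = 1L,
                             max_mismatch = 1L) {
  stopifnot(inherits(tags, "tag_count_set"), inherits(library, "tag_library"))
  if (n_points < 2L) stop("n_points must be >= 2")
  clean_total <- tags$totals$clean_total
  depths <- unique(round(seq(0, clean_total, length.out = n_points + 1L)))

  ## unambiguous gene assignment per distinct tag (NA = not usable)
  m <- map_tags(tags, library, max_mismatch = max_mismatch)
  gene_of <- m$tags[n_genes == 1L, .(tag, gene_id)]
  tag2gene <- gene_of$gene_id
  names(tag2gene) <- gene_of$tag

  with_seed(seed, {
    stream <- sample(rep.int(tags$counts$tag, tags$counts$count))
    g <- tag2gene[stream]                      # NA where tag not unambiguous
    first <- tapply(seq_along(g)[!is.na(g)], g[!is.na(g)], min)
    detected <- vapply(depths, function(d) sum(first <= d), numeric(1))
    data.frame(depth = depths, genes_detected = as.integer(detected))
  })
}

#' @export
print.tag_count_set <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Clean tag set '%s'\n", x$label))
  cat(sprintf("  raw:   %d total, %d distinct\n", t$raw_total, t$raw_distinct))
  cat(sprintf("  clean: %d total, %d distinct\n", t$clean_total,
              t$clean_distinct))
  for (nm in names(x$discards))
    cat(sprintf("  discarded %-12s %d copies (%d distinct)\n", nm,
                x$discards[[nm]][["total"]], x$discards[[nm]][["distinct"]]))
  invisible(x)
}

#' Write clean tags and the QC ledger
#'
#' @param tags A [filter_raw_tags()] result.
#' @param path TSV output (tag, copy number).
#' @param report_path Optional JSON path for the QC accounting ledger.
#' @return \code{path}, invisibly.
#' @export
write_tag_counts <- function(tags, path, report_path = NULL) {
  stopifnot(inherits(tags, "tag_count_set"))
  fwrite(tags$counts, path, sep = "\t")
  if (!is.null(report_path)) {
    rep <- c(tags$totals,
             list(discards = lapply(tags$discards, as.list)))
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
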
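#' Map clean tags to the reference tag library
#'
#' Looks up every distinct clean tag (exact match first, then one
#' substitution mismatch in the variable region) and classifies it:
#' \itemize{
#'   \item \emph{unambiguous} — all hits in exactly one gene; the tag's copy
#'     number is credited to that gene;
#'   \item \emph{ambiguous} — hits in two or more genes; counted as mapped
#'     but excluded from quantification;
#'   \item \emph{unknown} — no hit within one mismatch.
#' }
#' Exact matches take priority: a tag with any perfect-match hit never
#' receives mismatch hits, so a unique perfect match plus mismatch hits to
#' other genes still yields an unambiguous assignment. When a tag hits one
#' gene on both strands, the sense assignment is reported. Antisense
#' unambiguous hits are counted toward gene expression (a per-strand
#' breakdown is kept so sense-only analyses remain possible).
#'
#' @param tags A [filter_raw_tags()] result (or a \code{data.table} with
#'   \code{tag} and \code{count} columns plus a known clean total).
#' @param library A [build_tag_library()] result.
#' @param max_mismatch 0 or 1.
#' @return An object of class \code{"mapping_result"}: list with
#'   \describe{
#'     \item{tags}{per distinct tag: \code{tag}, \code{count},
#'       \code{match_class}, \code{n_genes} (0 = unknown), \code{gene_id}
#'       (for unambiguous tags), \code{strand}.}
#'     \item{expression}{per-gene table over the full reference gene set:
#'       \code{gene_id}, \code{count}, \code{count_sense},
#'       \code{count_antisense}, \code{tpm} (class
#'       \code{"expression_vector"}).}
#'     \item{totals}{all-mapped / unambiguous / unknown totals and distinct
#'       counts; all- and unambiguous-tag-mapped gene counts.}
#'   }
#' @export
map_tags <- function(tags, library, max_mismatch = 1L) {
  stopifnot(inherits(library, "tag_library"))
  if (inherits(tags, "tag_count_set")) {
    cnt <- tags$counts
    clean_total <- tags$totals$clean_total
    label <- tags$label
  } else {
    cnt <- as.data.table(tags)
    stopifnot(all(c("tag", "count") %in% names(cnt)))
    clean_total <- sum(cnt$count)
    label <- "library"
  }
  if (nrow(cnt) && any(nchar(cnt$tag) != 21L))
    stop("tag length mismatch: library tags are 21 nt")

  hits <- lookup_tags(cnt$tag, library, max_mismatch = max_mismatch)

  ## per-tag classification
  per_tag <- hits[, {
    pm <- startsWith(match_class[1], "PM")
    genes <- unique(gene_id)
    st <- if ("sense" %in% strand) "sense" else "antisense"
    g1 <- if (length(genes) == 1L) genes else NA_character_
    st1 <- if (length(genes) == 1L) {
      s <- strand[gene_id == genes]
      if ("sense" %in% s) "sense" else "antisense"
    } else st
    .(match_class = paste0(if (pm) "PM" else "1MM", "-", st1),
      n_genes = length(genes), gene_id = g1, strand = st1)
  }, by = tag]

  res <- merge(cnt, per_tag, by = "tag", all.x = TRUE)
  res[is.na(n_genes), `:=`(n_genes = 0L, match_class = "unknown")]

  mapped <- res[n_genes >= 1L]
  unamb <- res[n_genes == 1L]
  unknown <- res[n_genes == 0L]

  ## gene sets: all-mapped uses every hit gene; unambiguous uses assignments
  genes_all <- uniqueN(hits$gene_id)
  genes_unamb <- uniqueN(unamb$gene_id)

  ## per-gene expression from unambiguous tag copy numbers
  expr <- data.table(gene_id = library$gene_ids)
  by_gene <- unamb[, .(count = sum(count),
                       count_sense = sum(count[strand == "sense"]),
                       count_antisense = sum(count[strand == "antisense"])),
                   by = gene_id]
  expr <- merge(expr, by_gene, by = "gene_id", all.x = TRUE)
  for (cl in c("count", "count_sense", "count_antisense"))
    expr[is.na(get(cl)), (cl) := 0L]
  expr[, tpm := tpm_normalize(count, clean_total)]
  setkey(expr, gene_id)
  setattr(expr, "clean_total", clean_total)
  setattr(expr, "label", label)
  setattr(expr, "class", c("expression_vector", class(expr)))

  totals <- list(
    clean_total = clean_total, clean_distinct = nrow(cnt),
    all_mapped_total = sum(mapped$count),
    all_mapped_distinct = nrow(mapped),
    unambiguous_total = sum(unamb$count),
    unambiguous_distinct = nrow(unamb),
    unknown_total = sum(unknown$count),
    unknown_distinct = nrow(unknown),
    genes_all_mapped = genes_all,
    genes_unambiguous_mapped = genes_unamb
  )
  stopifnot(totals$all_mapped_total + totals$unknown_total ==
              totals$clean_total,
            totals$all_mapped_distinct + totals$unknown_distinct ==
              totals$clean_distinct)
  structure(list(tags = res, expression = expr, totals = totals,
                 label = label, max_mismatch = max_mismatch),
            class = "mapping_result")
}

#' Tags-per-million normalisation
#'
#' Scales unambiguous per-gene tag counts by the library's total clean tag
#' count: \code{TPM = count * 1e6 / clean_total}. The denominator is the
#' total number of clean tags in the library, not the mapped subset.
#'
#' @param counts Numeric vector of per-gene unambiguous tag counts.
#' @param clean_total Total clean tags in the library (> 0).
#' @return Numeric vector of TPM values.
#' @export
tpm_normalize <- function(counts, clean_total) {
  if (length(clean_total) != 1L || is.na(clean_total) || clean_total <= 0)
    stop("clean_total must be a single positive count")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts * 1e6 / clean_total
}

#' @export
print.mapping_result <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Tag mapping ('%s', max mismatch %d)\n", x$label,
              x$max_mismatch))
  cat(sprintf("  clean:       %10d total  %8d distinct\n", t$clean_total,
              t$clean_distinct))
  cat(sprintf("  all mapped:  %10d total  %8d distinct\n",
              t$all_mapped_total, t$all_mapped_distinct))
  cat(sprintf("  unambiguous: %10d total  %8d distinct\n",
              t$unambiguous_total, t$unambiguous_distinct))
  cat(sprintf("  unknown:     %10d total  %8d distinct\n", t$unknown_total,
              t$unknown_distinct))
  cat(sprintf("  genes: %d all-mapped, %d unambiguously mapped\n",
              t$genes_all_mapped, t$genes_unambiguous_mapped))
  invisible(x)
}

#' Write a per-gene expression table
#'
#' @param mapping A [map_tags()] result (or its \code{expression} element).
#' @param path TSV output (gene_id, count, sense/antisense breakdown, TPM).
#' @param report_path Optional JSON path for the mapping totals.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(mapping, path, report_path = NULL) {
  expr <- if (inherits(mapping, "mapping_result")) mapping$expression
          else mapping
  fwrite(as.data.table(expr), path, sep = "\t")
  if (!is.null(report_path) && inherits(mapping, "mapping_result"))
    jsonlite::write_json(mapping$totals, report_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
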
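#' Percentage with half-up rounding to two decimals
#'
#' All published ratios in tag-profiling summary tables are percentages
#' rounded half-up at the second decimal; this helper reproduces that
#' arithmetic exactly from the underlying integers.
#'
#' @param numerator,denominator Counts; \code{denominator > 0}.
#' @return \code{numerator / denominator * 100} rounded half-up to 2
#'   decimals.
#' @export
percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0)) stop("numerator must be non-negative")
  x <- numerator / denominator * 100
  ## half-up, with a guard against representation error just below .xx5
  floor(x * 100 + 0.5 + 1e-9) / 100
}

#' Assemble a per-library sequencing report
#'
#' Combines the QC accounting of one library with its mapping result into
#' the standard summary table of a tag-profiling experiment: raw and clean
#' tag totals, mapped and unmapped fractions (copies and distinct tags
#' separately), and the number and fraction of reference genes identified.
#' Every percentage is recomputed from the integer fields via
#' [percentage()]; nothing is cached.
#'
#' @param qc A [filter_raw_tags()] result.
#' @param mapping The [map_tags()] result for the same library.
#' @param n_ref_genes Number of genes in the reference transcript set.
#' @return An object of class \code{"library_report"} (a named list of
#'   integers and percentages).
#' @export
build_library_report <- function(qc, mapping, n_ref_genes) {
  stopifnot(inherits(qc, "tag_count_set"),
            inherits(mapping, "mapping_result"))
  t <- mapping$totals
  if (qc$totals$clean_total != t$clean_total ||
      qc$totals$clean_distinct != t$clean_distinct)
    stop("inconsistent totals: qc and mapping come from different libraries")
  q <- qc$totals
  r <- list(
    label = qc$label,
    raw_total = q$raw_total,
    raw_distinct = q$raw_distinct,
    clean_total = q$clean_total,
    clean_distinct = q$clean_distinct,
    clean_total_pct_of_raw = percentage(q$clean_total, q$raw_total),
    all_mapped_total = t$all_mapped_total,
    all_mapped_total_pct = percentage(t$all_mapped_total, q$clean_total),
    all_mapped_distinct = t$all_mapped_distinct,
    all_mapped_distinct_pct = percentage(t$all_mapped_distinct,
                                         q$clean_distinct),
    unambiguous_total = t$unambiguous_total,
    unambiguous_total_pct = percentage(t$unambiguous_total, q$clean_total),
    unambiguous_distinct = t$unambiguous_distinct,
    unambiguous_distinct_pct = percentage(t$unambiguous_distinct,
                                          q$clean_distinct),
    genes_all_mapped = t$genes_all_mapped,
    genes_all_mapped_pct = percentage(t$genes_all_mapped, n_ref_genes),
    genes_unambiguous_mapped = t$genes_unambiguous_mapped,
    genes_unambiguous_mapped_pct = percentage(t$genes_unambiguous_mapped,
                                              n_ref_genes),
    unknown_total = t$unknown_total,
    unknown_total_pct = percentage(t$unknown_total, q$clean_total),
    unknown_distinct = t$unknown_distinct,
    unknown_distinct_pct = percentage(t$unknown_distinct, q$clean_distinct),
    n_ref_genes = n_ref_genes
  )
  class(r) <- "library_report"
  r
}

#' @export
print.library_report <- function(x, ...) {
  cat(sprintf("Library report '%s' (%d reference genes)\n", x$label,
              x$n_ref_genes))
  row <- function(name, total, pct = NA, distinct = NA, dpct = NA) {
    cat(sprintf("  %-28s %10s %8s %9s %8s\n", name,
                format(total, big.mark = ","),
                ifelse(is.na(pct), "", sprintf("%.2f%%", pct)),
                ifelse(is.na(distinct), "", format(distinct, big.mark = ",")),
                ifelse(is.na(dpct), "", sprintf("%.2f%%", dpct))))
  }
  cat(sprintf("  %-28s %10s %8s %9s %8s\n", "", "total", "%", "distinct",
              "%"))
  row("raw tags", x$raw_total, NA, x$raw_distinct)
  row("clean tags", x$clean_total, x$clean_total_pct_of_raw,
      x$clean_distinct)
  row("all mapped", x$all_mapped_total, x$all_mapped_total_pct,
      x$all_mapped_distinct, x$all_mapped_distinct_pct)
  row("unambiguous mapped", x$unambiguous_total, x$unambiguous_total_pct,
      x$unambiguous_distinct, x$unambiguous_distinct_pct)
  row("unknown", x$unknown_total, x$unknown_total_pct, x$unknown_distinct,
      x$unknown_distinct_pct)
  row("genes, all tags", x$genes_all_mapped, x$genes_all_mapped_pct)
  row("genes, unambiguous tags", x$genes_unambiguous_mapped,
      x$genes_unambiguous_mapped_pct)
  invisible(x)
}

#' Write a library report as JSON
#'
#' @param report A [build_library_report()] result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_library_report <- function(report, path) {
  stopifnot(inherits(report, "library_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
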
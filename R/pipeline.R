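#' Run the full tag-profiling pipeline on simulated data
#'
#' Convenience wrapper chaining every stage on one synthetic experiment:
#' transcriptome and truth generation, raw read simulation for two
#' conditions, QC filtering, reference tag library construction, mapping,
#' differential expression between the two libraries (condition B relative
#' to condition A), optional term enrichment of the called genes, and the
#' per-library summary reports.
#'
#' @param config A [sim_config()].
#' @param n_de,log2fc Passed to [simulate_truth()].
#' @param annotation_terms Number of simulated annotation terms (0 skips
#'   enrichment); the first term is planted as enriched in the true DE set.
#' @param fdr_cutoff,lfc_cutoff Passed to [call_degs()].
#' @param max_mismatch Passed to [map_tags()].
#' @return A list with elements \code{transcriptome}, \code{truth},
#'   \code{reads}, \code{qc}, \code{library}, \code{mapping}, \code{degs},
#'   \code{enrichment}, \code{reports} (the last three \code{NULL} where
#'   skipped), each per condition where applicable.
#' @export
run_dge_pipeline <- function(config = sim_config(), n_de = 50L, log2fc = 3,
                             annotation_terms = 50L, fdr_cutoff = 0.001,
                             lfc_cutoff = 1, max_mismatch = 1L) {
  tr <- simulate_transcriptome(config)
  truth <- simulate_truth(tr, n_de = n_de, log2fc = log2fc,
                          seed = config$seed)
  lib <- build_tag_library(tr)

  reads <- list(A = simulate_tag_reads(tr, truth, config, "A"),
                B = simulate_tag_reads(tr, truth, config, "B"))
  qc <- lapply(reads, filter_raw_tags)
  mapping <- lapply(qc, map_tags, library = lib, max_mismatch = max_mismatch)
  reports <- lapply(names(qc), function(cond)
    build_library_report(qc[[cond]], mapping[[cond]], config$n_genes))
  names(reports) <- names(qc)

  degs <- call_degs(mapping$A$expression, mapping$B$expression,
                    fdr_cutoff = fdr_cutoff, lfc_cutoff = lfc_cutoff)

  enr <- NULL
  if (annotation_terms > 0L) {
    ann <- simulate_annotation(truth, n_terms = annotation_terms,
                               planted = TRUE, seed = config$seed)
    de_genes <- degs$gene_id[degs$call != "not-DE"]
    enr <- enrich_terms(de_genes, ann, mode = "go")
  }

  list(transcriptome = tr, truth = truth, reads = reads, qc = qc,
       library = lib, mapping = mapping, degs = degs, enrichment = enr,
       reports = reports)
}
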
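#' Hypergeometric enrichment p-value for one term
#'
#' Upper-tail hypergeometric probability that at least \code{m} of the
#' \code{n} differentially expressed genes carry a term annotated to
#' \code{M} of the \code{N} background genes:
#' \deqn{P = \sum_{i=m}^{\min(n,M)}
#'   \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}
#'   = 1 - \sum_{i=0}^{m-1}
#'   \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}}
#' Binomial coefficients are evaluated through log-gamma and the tail is
#' summed directly, smallest terms first, so deeply significant terms keep
#' full relative precision. Out-of-support terms (\eqn{n-i > N-M})
#' contribute zero.
#'
#' @param N Background: number of genes with any annotation in the domain.
#' @param M Genes annotated to the term (vectorised in parallel with
#'   \code{m}).
#' @param n Differentially expressed genes within the background.
#' @param m Differentially expressed genes carrying the term.
#' @return Upper-tail probabilities in (0, 1].
#' @export
hypergeom_enrichment_p <- function(N, M, n, m) {
  len <- max(length(M), length(m))
  M <- rep_len(M, len); m <- rep_len(m, len)
  if (any(n > N) || any(M > N))
    stop("count constraints violated: need n <= N and M <= N")
  if (any(m > pmin(n, M)))
    stop("count constraints violated: need m <= min(n, M)")
  if (any(c(N, M, n, m) < 0)) stop("counts must be non-negative")
  vapply(seq_len(len), function(j) {
    if (m[j] == 0L) return(1)        # empty excluded sum: P(X >= 0) = 1
    i <- m[j]:min(n, M[j])
    terms <- exp(lchoose(M[j], i) + lchoose(N - M[j], n - i) -
                   lchoose(N, n))
    min(1, sum(sort(terms)))
  }, numeric(1))
}

#' Term enrichment of a differentially expressed gene set
#'
#' Tests every annotated term for over-representation in a DE gene set with
#' the upper-tail hypergeometric probability, against the background of all
#' genes carrying at least one annotation in the domain. Q-values are
#' Benjamini-Hochberg adjusted across the term family. Two significance
#' conventions are supported: GO-style terms are flagged on the raw
#' p-value, pathway-style terms on the q-value.
#'
#' @param deg_genes Character vector of DE gene ids.
#' @param annotation An annotation map (\code{gene_id}, \code{term_id},
#'   \code{term_name}), e.g. from [simulate_annotation()] or
#'   [read_annotation()].
#' @param mode \code{"go"} (significant if \code{p < p_cutoff}) or
#'   \code{"pathway"} (significant if \code{q < q_cutoff}).
#' @param p_cutoff,q_cutoff Significance thresholds (default 0.05).
#' @param background Optional character vector overriding the background
#'   universe; defaults to all annotated genes.
#' @return A \code{data.frame} of class \code{"enrichment_results"}:
#'   \code{term_id}, \code{term_name}, \code{N}, \code{n}, \code{M},
#'   \code{m}, \code{p_value}, \code{q_value}, \code{significant}, ordered
#'   by p-value.
#' @export
enrich_terms <- function(deg_genes, annotation, mode = c("go", "pathway"),
                         p_cutoff = 0.05, q_cutoff = 0.05,
                         background = NULL) {
  mode <- match.arg(mode)
  ann <- as.data.table(annotation)
  if (nrow(ann) == 0L) stop("empty annotation map")
  if (!is.null(background)) ann <- ann[gene_id %in% background]
  universe <- unique(ann$gene_id)
  N <- length(universe)
  de <- unique(deg_genes)
  de_in <- intersect(de, universe)
  if (length(de_in) == 0L)
    warning("no DE gene carries an annotation in this domain")
  n <- length(de_in)

  per_term <- ann[, .(term_name = term_name[1],
                      M = uniqueN(gene_id),
                      m = uniqueN(intersect(gene_id, de_in))),
                  by = term_id]
  per_term <- per_term[M >= 1L]
  per_term[, `:=`(N = N, n = n)]
  per_term[, p_value := hypergeom_enrichment_p(N[1], M, n[1], m)]
  per_term[, q_value := bh_fdr(p_value)]
  per_term[, significant := if (mode == "go") p_value < p_cutoff
           else q_value < q_cutoff]
  setorder(per_term, p_value)
  out <- as.data.frame(per_term[, .(term_id, term_name, N, n, M, m,
                                    p_value, q_value, significant)])
  attr(out, "mode") <- mode
  attr(out, "cutoffs") <- c(p = p_cutoff, q = q_cutoff)
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' @export
print.enrichment_results <- function(x, n = 10L, ...) {
  cat(sprintf(
    "Term enrichment (%s mode): %d terms tested, %d significant\n",
    attr(x, "mode"), nrow(x), sum(x$significant)))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' Write an enrichment table as TSV
#'
#' @param enrichment An [enrich_terms()] result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  fwrite(as.data.table(as.data.frame(enrichment)), path, sep = "\t")
  invisible(path)
}
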
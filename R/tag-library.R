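#' Build the virtual reference tag library
#'
#' Enumerates every possible 21 nt tag — the \code{CATG} anchor plus the 17
#' downstream bases — on both strands of every reference transcript. This is
#' the "virtual tag" view of the reference used in NlaIII/MmeI tag
#' profiling: a sequenced tag can only ever originate from one of these
#' sites, so the library is the complete search space for mapping.
#'
#' A tag whose occurrences all fall in a single gene (regardless of site
#' count or strand) is \emph{unambiguous}; a tag seen in two or more genes is
#' \emph{ambiguous} and is excluded from quantification downstream.
#' Candidate sites whose 21-mer contains a non-ACGT letter are skipped and
#' counted in the build report.
#'
#' @param transcripts One of: a named character vector of sequences, a path
#'   to a FASTA file, or a [simulate_transcriptome()] result.
#' @return An object of class \code{"tag_library"}: a list with
#'   \describe{
#'     \item{occurrences}{\code{data.table} (\code{tag}, \code{gene_id},
#'       \code{strand}, \code{offset}) keyed by tag. \code{offset} is the
#'       0-based position of the \code{C} of \code{CATG} on the scanned
#'       strand.}
#'     \item{tags}{per-tag summary (\code{tag}, \code{n_genes}).}
#'     \item{report}{counts: genes, tag-bearing genes, occurrences,
#'       distinct tags, unambiguous tags, skipped sites.}
#'   }
#' @export
build_tag_library <- function(transcripts) {
  seqs <- as_ref_seqs(transcripts)
  if (length(seqs) == 0L) stop("empty reference: no transcripts")
  if (anyDuplicated(names(seqs)))
    stop("duplicate gene ids in reference: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))

  scan_strand <- function(s, strand) {
    recs <- lapply(seq_along(s), function(i) {
      m <- gregexpr("CATG", s[i], fixed = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      m <- as.integer(m)
      m <- m[m + 20L <= nchar(s[i])]
      if (length(m) == 0L) return(NULL)
      data.table(tag = substring(s[i], m, m + 20L),
                 gene_id = names(s)[i],
                 strand = strand,
                 offset = m - 1L)
    })
    rbindlist(recs)
  }

  occ <- rbindlist(list(scan_strand(seqs, "sense"),
                        scan_strand(revcomp(seqs), "antisense")))
  n_skipped <- 0L
  if (nrow(occ)) {
    bad <- !grepl("^[ACGT]{21}$", occ$tag)
    n_skipped <- sum(bad)
    occ <- occ[!bad]
  }
  setkey(occ, tag)
  tags <- occ[, .(n_genes = uniqueN(gene_id)), by = tag]
  setkey(tags, tag)

  report <- list(
    n_genes = length(seqs),
    n_tag_bearing_genes = uniqueN(occ$gene_id),
    n_occurrences = nrow(occ),
    n_distinct_tags = nrow(tags),
    n_unambiguous_tags = sum(tags$n_genes == 1L),
    n_ambiguous_tags = sum(tags$n_genes > 1L),
    n_skipped_sites = n_skipped
  )
  structure(list(occurrences = occ, tags = tags, report = report,
                 gene_ids = names(seqs)),
            class = "tag_library")
}

as_ref_seqs <- function(transcripts) {
  if (inherits(transcripts, "synthetic_transcriptome")) {
    seqs <- transcripts$sequence
    names(seqs) <- transcripts$gene_id
    seqs
  } else if (is.character(transcripts) && length(transcripts) == 1L &&
             file.exists(transcripts)) {
    read_fasta(transcripts)
  } else if (is.character(transcripts)) {
    if (length(transcripts) == 0L) return(character(0))
    if (is.null(names(transcripts)))
      stop("a character vector of transcripts must be named by gene id")
    toupper(transcripts)
  } else stop("unsupported 'transcripts' input")
}

#' Look up tags in a reference tag library
#'
#' Implements the mapping rule of tag profiling: a tag is first sought as an
#' exact (perfect match, PM) hit; only if it has no exact occurrence is its
#' 1-mismatch neighbourhood searched. Substitution mismatches are restricted
#' to the 17 nt variable region — the \code{CATG} anchor is an enzymatic
#' recognition site present by construction in both tag and reference, so it
#' is held fixed (51 variants per tag). Tags with neither kind of hit are
#' \emph{unknown}.
#'
#' @param tags Character vector of 21 nt tag sequences (distinct or not).
#' @param library A [build_tag_library()] result.
#' @param max_mismatch 0 (exact only) or 1.
#' @return A \code{data.table} with one row per (tag, gene, strand) hit:
#'   columns \code{tag}, \code{gene_id}, \code{strand}, \code{match_class}
#'   (\code{"PM-sense"}, \code{"PM-antisense"}, \code{"1MM-sense"},
#'   \code{"1MM-antisense"}). Tags without hits are absent from the result.
#' @export
lookup_tags <- function(tags, library, max_mismatch = 1L) {
  stopifnot(inherits(library, "tag_library"))
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  if (length(tags) == 0L)
    return(data.table(tag = character(), gene_id = character(),
                      strand = character(), match_class = character()))
  if (any(nchar(tags) != 21L))
    stop("malformed tag length: all tags must be 21 nt")

  qry <- unique(tags)
  occ <- library$occurrences

  exact <- occ[data.table(tag = qry), nomatch = NULL,
               .(tag, gene_id, strand)]
  exact <- unique(exact)
  exact[, match_class := paste0("PM-", strand)]

  res <- exact
  if (max_mismatch == 1L) {
    miss <- setdiff(qry, exact$tag)
    if (length(miss)) {
      vr <- mm1_variants(miss)
      hits <- occ[data.table(tag = vr$variant), nomatch = NULL,
                  .(variant = tag, gene_id, strand)]
      if (nrow(hits)) {
        hits <- merge(hits, vr, by = "variant", allow.cartesian = TRUE)
        hits <- unique(hits[, .(tag = origin, gene_id, strand)])
        hits[, match_class := paste0("1MM-", strand)]
        res <- rbindlist(list(res, hits), use.names = TRUE)
      }
    }
  }
  setkey(res, tag)
  res[]
}

## all 51 variable-region substitution variants of each 21 nt tag
mm1_variants <- function(tags) {
  n <- length(tags)
  origin <- rep(tags, each = 51L)
  pos <- rep(rep(5:21, each = 3L), times = n)
  sub_i <- rep(rep(1:3, times = 17L), times = n)
  cur <- substr(origin, pos, pos)
  new <- DNA_BASES[(match(cur, DNA_BASES) - 1L + sub_i) %% 4L + 1L]
  variant <- origin
  variant <- str_sub_replace(variant, seq_along(variant), pos, new)
  unique(data.table(variant = variant, origin = origin))
}

#' @export
print.tag_library <- function(x, ...) {
  r <- x$report
  cat("Reference tag library\n")
  cat(sprintf("  genes: %d (%d tag-bearing)\n", r$n_genes,
              r$n_tag_bearing_genes))
  cat(sprintf("  occurrences: %d sites, %d distinct tags (%d unambiguous, %d ambiguous)\n",
              r$n_occurrences, r$n_distinct_tags, r$n_unambiguous_tags,
              r$n_ambiguous_tags))
  if (r$n_skipped_sites > 0)
    cat(sprintf("  skipped sites (non-ACGT): %d\n", r$n_skipped_sites))
  invisible(x)
}

#' Serialise a tag library to TSV (+ JSON build report)
#'
#' @param library A [build_tag_library()] result.
#' @param path Output TSV path (columns tag, gene_id, strand, offset).
#' @param report_path Optional JSON path for the build report.
#' @return \code{path}, invisibly.
#' @export
write_tag_library <- function(library, path, report_path = NULL) {
  stopifnot(inherits(library, "tag_library"))
  fwrite(library$occurrences, path, sep = "\t")
  if (!is.null(report_path))
    jsonlite::write_json(library$report, report_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
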
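#' Write a synthetic transcriptome to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param transcriptome A [simulate_transcriptome()] result, or any object
#'   with \code{gene_id} and \code{sequence} columns.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(transcriptome, path) {
  x <- Biostrings::DNAStringSet(transcriptome$sequence)
  names(x) <- transcriptome$gene_id
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read reference transcripts from FASTA
#'
#' @param path FASTA file path.
#' @return A named character vector of sequences (names = gene ids; the
#'   description line is truncated at the first whitespace).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write simulated raw reads to FASTQ
#'
#' Qualities are written as a constant \code{"I"} (Sanger Q40): the tag
#' filtering pipeline is sequence-based and does not consume qualities.
#'
#' @param reads A [simulate_tag_reads()] result.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "tag_reads"))
  x <- Biostrings::DNAStringSet(reads$reads)
  names(x) <- reads$truth$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$reads)))
  y <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(y, path)
  invisible(path)
}

#' Read raw read sequences from FASTQ
#'
#' @param path FASTQ file path.
#' @return Character vector of read sequences, named by read id.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a gene-to-term annotation map as TSV
#'
#' @param annotation An [simulate_annotation()] result or any table with
#'   columns \code{gene_id}, \code{term_id}, \code{term_name}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  fwrite(as.data.table(annotation), path, sep = "\t")
  invisible(path)
}

#' Read a gene-to-term annotation map from TSV
#'
#' @param path TSV with columns \code{gene_id}, \code{term_id} and
#'   optionally \code{term_name}.
#' @return A \code{data.table} of class \code{"annotation_map"}.
#' @export
read_annotation <- function(path) {
  out <- fread(path, sep = "\t", colClasses = "character")
  if (!all(c("gene_id", "term_id") %in% names(out)))
    stop("annotation file must have 'gene_id' and 'term_id' columns")
  if (!"term_name" %in% names(out)) out[, term_name := term_id]
  setattr(out, "class", c("annotation_map", class(out)))
  out[]
}
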
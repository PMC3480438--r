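## internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

## Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

## vectorised reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## random DNA strings, one per element of `len`, with per-sequence GC content
random_dna <- function(len, gc) {
  stopifnot(length(len) == length(gc))
  vapply(seq_along(len), function(i) {
    p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
    paste(sample(DNA_BASES, len[i], replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

## replace single characters at (string index, position) pairs
str_sub_replace <- function(x, idx, pos, value) {
  for (p in unique(pos)) {
    sel <- idx[pos == p]
    substr(x[sel], p, p) <- value[pos == p]
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
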
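#' @importFrom data.table data.table := setorder setorderv rbindlist as.data.table setDT setnames
#' @importFrom stats cor median quantile rnorm runif rlnorm setNames coef lm resid predict sd
#' @importFrom utils adist head
NULL

DNA_BASES <- c("A", "C", "G", "T")

## character matrix (one column per position) for equal-length sequences
.char_matrix <- function(seqs) {
  n <- nchar(seqs[1L])
  m <- vapply(seq_len(n), function(j) substring(seqs, j, j), character(length(seqs)))
  if (is.null(dim(m))) dim(m) <- c(length(seqs), n)
  m
}

.base_codes <- function(chars) {
  code <- match(chars, DNA_BASES)
  dim(code) <- dim(chars)
  code
}

.check_dna <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: record %d)",
                 what, which(bad)[1L]), call. = FALSE)
  }
  invisible(seqs)
}

## big-endian base-4 index over selected columns of a code matrix, 1-based
.kmer_index <- function(codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  w <- ncol(codes)
  idx <- rep(0, nrow(codes))
  for (j in seq_len(w)) idx <- idx * 4 + (codes[, j] - 1L)
  as.integer(idx + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
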
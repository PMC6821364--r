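## Gapped k-mer patterns: a left l-mer and a right n-mer separated by m
## wildcard positions (l + m + n = k), written with 'x' at wildcard slots,
## e.g. ACTACxxxACGC is the 5-3-4 pattern of span 12. l and n take values
## 4 or 5; m ranges from 0 up to N - l - n for a randomized region of
## length N. A pattern is counted once per read regardless of how many
## offsets it matches (first-occurrence rule).

.gapped_structures <- function(max_len, l_values, n_values) {
  out <- list()
  for (l in l_values) for (n in n_values) {
    for (m in 0:(max_len - l - n)) {
      if (m < 0) next
      out[[length(out) + 1L]] <- c(l = l, m = m, n = n)
    }
  }
  out
}

#' Enumerate the gapped k-mers present in a single read
#'
#' Every (l, m, n, offset) window of the read instantiates one pattern;
#' duplicate instantiations within the read collapse to a single entry.
#'
#' @param read one A/C/G/T string.
#' @param l_values,n_values allowed left/right word lengths.
#' @return character vector of distinct patterns (wildcards as `x`).
#' @export
enumerate_gapped_kmers <- function(read, l_values = c(4L, 5L), n_values = c(4L, 5L)) {
  stopifnot(length(read) == 1L)
  .check_dna(read, "read")
  N <- nchar(read)
  if (N < min(l_values) + min(n_values)) return(character(0))
  pats <- character(0)
  for (st in .gapped_structures(N, l_values, n_values)) {
    l <- st[["l"]]; m <- st[["m"]]; n <- st[["n"]]
    span <- l + m + n
    if (span > N) next
    gap <- strrep("x", m)
    for (o in seq_len(N - span + 1L)) {
      pats[length(pats) + 1L] <- paste0(
        substr(read, o, o + l - 1L), gap,
        substr(read, o + l + m, o + span - 1L))
    }
  }
  unique(pats)
}

#' Count gapped k-mers across a sample of reads
#'
#' Implements the per-read first-occurrence counting rule: the observed
#' count of a pattern is the number of reads containing it at least once.
#' Reads of different randomized-region lengths are pooled, and the count
#' filter is applied after pooling.
#'
#' @param reads character vector of A/C/G/T reads (one demultiplexed
#'   sample).
#' @param l_values,n_values allowed left/right word lengths.
#' @param count_threshold patterns observed in fewer reads than this are
#'   dropped (50 by default; pass 1 to keep everything).
#' @return `data.table` with columns pattern, l, m, n, observed.
#' @export
count_patterns <- function(reads, l_values = c(4L, 5L), n_values = c(4L, 5L),
                           count_threshold = 50L) {
  .check_dna(reads, "read")
  lens <- nchar(reads)
  max_len <- max(lens)
  if (max_len < min(l_values) + min(n_values)) {
    return(data.table(pattern = character(0), l = integer(0), m = integer(0),
                      n = integer(0), observed = integer(0)))
  }
  by_len <- split(seq_along(reads), lens)
  res <- vector("list", 0L)
  for (st in .gapped_structures(max_len, l_values, n_values)) {
    l <- st[["l"]]; m <- st[["m"]]; n <- st[["n"]]
    span <- l + m + n
    gap <- strrep("x", m)
    ids <- list(); ps <- list()
    for (Lc in names(by_len)) {
      L <- as.integer(Lc)
      if (span > L) next
      idx <- by_len[[Lc]]
      rd <- reads[idx]
      for (o in seq_len(L - span + 1L)) {
        ids[[length(ids) + 1L]] <- idx
        ps[[length(ps) + 1L]] <- paste0(
          substr(rd, o, o + l - 1L), gap,
          substr(rd, o + l + m, o + span - 1L))
      }
    }
    if (length(ps) == 0L) next
    dt <- data.table(id = unlist(ids), pattern = unlist(ps))
    cnt <- unique(dt)[, list(observed = .N), by = "pattern"]
    cnt <- cnt[cnt$observed >= count_threshold]
    if (nrow(cnt)) {
      cnt[, `:=`(l = l, m = m, n = n)]
      res[[length(res) + 1L]] <- cnt
    }
  }
  if (!length(res)) {
    return(data.table(pattern = character(0), l = integer(0), m = integer(0),
                      n = integer(0), observed = integer(0)))
  }
  out <- rbindlist(res)
  ## an ungapped pattern (m = 0) arises from more than one (l, n) split of
  ## the same string; keep one row per pattern string
  out <- unique(out, by = "pattern")
  data.table::setcolorder(out, c("pattern", "l", "m", "n", "observed"))
  out[]
}

#' Expected count of gapped k-mer patterns in a sample
#'
#' Two conventions are provided. `"single-position"` multiplies the pattern
#' probability by the total read count, treating each read as containing one
#' potential match site. `"per-read-any-offset"` accounts for every offset
#' at which the pattern can sit inside the randomized region and returns the
#' expected number of reads matching at one or more offsets, which is the
#' quantity the per-read first-occurrence counting rule estimates; use it
#' whenever expected counts are compared directly against
#' [count_patterns()] output.
#'
#' @param model a `markov_bg`.
#' @param patterns character vector of patterns.
#' @param total_reads number of reads in the sample being normalized.
#' @param region_lengths read lengths of the sample: a single length, an
#'   integer vector of per-read lengths, or a named vector of counts per
#'   length. Required for the per-read convention.
#' @param convention expected-count convention; see Details.
#' @export
expected_count <- function(model, patterns, total_reads,
                           region_lengths = NULL,
                           convention = c("single-position", "per-read-any-offset")) {
  convention <- match.arg(convention)
  stopifnot(total_reads >= 1)
  p <- pattern_probability(model, patterns)
  span <- nchar(patterns)
  if (!is.null(region_lengths) && any(span > max(.region_length_table(region_lengths, total_reads)$L)))
    stop("pattern span exceeds the randomized-region length")
  if (convention == "single-position") return(p * total_reads)
  if (is.null(region_lengths))
    stop("region_lengths is required for the per-read-any-offset convention")
  tab <- .region_length_table(region_lengths, total_reads)
  out <- numeric(length(patterns))
  for (i in seq_len(nrow(tab))) {
    offs <- pmax(0L, tab$L[i] - span + 1L)
    out <- out + tab$n[i] * (1 - (1 - p)^offs)
  }
  out
}

.region_length_table <- function(region_lengths, total_reads) {
  nm <- names(region_lengths)
  if (!is.null(nm) && !anyNA(suppressWarnings(as.integer(nm)))) {
    data.frame(L = as.integer(nm), n = as.numeric(region_lengths))
  } else if (length(region_lengths) == 1L) {
    data.frame(L = as.integer(region_lengths), n = total_reads)
  } else {
    tb <- table(region_lengths)
    data.frame(L = as.integer(names(tb)), n = as.numeric(tb))
  }
}

#' Per-pattern enrichment of a selected sample over the background model
#'
#' Enrichment is observed / expected; values well above 1 indicate
#' selection. Patterns whose expected count is zero even after smoothing
#' are excluded with a warning.
#'
#' @param sample_counts output of [count_patterns()] on the selected sample.
#' @param model `markov_bg` trained on the starting library.
#' @param total_reads reads in the selected sample.
#' @param region_lengths see [expected_count()].
#' @param convention see [expected_count()].
#' @return `data.table` with columns pattern, l, m, n, observed, expected,
#'   enrichment, sorted by decreasing enrichment.
#' @export
enrichment_table <- function(sample_counts, model, total_reads,
                             region_lengths = NULL,
                             convention = c("single-position", "per-read-any-offset")) {
  convention <- match.arg(convention)
  out <- data.table::copy(as.data.table(sample_counts))
  out[, expected := expected_count(model, out$pattern, total_reads,
                                   region_lengths, convention)]
  if (any(out$expected == 0)) {
    warning(sprintf("%d patterns with zero expected count excluded",
                    sum(out$expected == 0)))
    out <- out[out$expected > 0]
  }
  out[, enrichment := out$observed / out$expected]
  setorderv(out, c("enrichment", "observed", "pattern"), c(-1L, -1L, 1L))
  out[]
}
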
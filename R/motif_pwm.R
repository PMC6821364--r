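## Seeded PWM construction. The most enriched gapped k-mer is the seed;
## the enrichment of every single-mismatch variant of the seed, computed
## exactly as for the seed itself, weights the corresponding (position,
## base) cell of the PWM.

#' Construct a pwm object
#'
#' @param mat 4 x W probability matrix (rows A, C, G, T), non-wildcard
#'   columns summing to 1.
#' @param wildcard logical flag per column; wildcard (spacer) columns are
#'   stored as uniform.
#' @param seed_pattern the gapped k-mer the matrix was seeded from, if any.
#' @export
new_pwm <- function(mat, wildcard = rep(FALSE, ncol(mat)), seed_pattern = NULL) {
  stopifnot(nrow(mat) == 4L, length(wildcard) == ncol(mat))
  rownames(mat) <- DNA_BASES
  if (max(abs(colSums(mat) - 1)) > 1e-9)
    stop("PWM columns must sum to 1")
  structure(list(mat = mat, wildcard = wildcard, seed_pattern = seed_pattern),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- ifelse(x$wildcard, "x", DNA_BASES[apply(x$mat, 2L, which.max)])
  cat(sprintf("PWM of width %d, consensus %s\n", ncol(x$mat),
              paste(cons, collapse = "")))
  if (!is.null(x$seed_pattern)) cat("  seeded from", x$seed_pattern, "\n")
  invisible(x)
}

#' Per-position information content in bits
#'
#' 2 bits for a deterministic column, 0 for a uniform (or wildcard) column.
#' @param pwm a [pwm] object.
#' @export
pwm_info_content <- function(pwm) {
  apply(pwm$mat, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Select the seed pattern from an enrichment table
#'
#' The argmax-enrichment pattern; ties break toward the higher observed
#' count, then lexicographically.
#'
#' @param table an [enrichment_table()] result.
#' @return single-row `data.table` for the seed pattern.
#' @export
select_seed <- function(table) {
  if (nrow(table) == 0L) stop("empty enrichment table: no seed available")
  tab <- as.data.table(table)
  setorderv(tab, c("enrichment", "observed", "pattern"), c(-1L, -1L, 1L))
  tab[1L]
}

#' Enrichment of every single-mismatch variant of a seed pattern
#'
#' For each non-wildcard position of the seed and each base, the variant
#' with that base substituted is looked up in the sample counts and its
#' enrichment computed as observed / expected. Variants absent from the
#' counts (i.e. below the count filter) receive enrichment 0; the seed base
#' carries the seed's own enrichment.
#'
#' @param seed seed pattern string (wildcards as `x`).
#' @param sample_counts [count_patterns()] output for the sample.
#' @param model background `markov_bg`.
#' @param total_reads,region_lengths,convention as in [expected_count()].
#' @return list with `enrichment` (4 x W matrix, wildcard columns NA) and
#'   `wildcard` flags.
#' @export
mismatch_enrichments <- function(seed, sample_counts, model, total_reads,
                                 region_lengths = NULL,
                                 convention = c("single-position", "per-read-any-offset")) {
  convention <- match.arg(convention)
  chars <- strsplit(seed, "")[[1L]]
  W <- length(chars)
  wild <- chars == "x"
  variants <- character(0)
  vpos <- integer(0); vbase <- integer(0)
  for (i in which(!wild)) {
    for (b in seq_len(4L)) {
      v <- chars; v[i] <- DNA_BASES[b]
      variants <- c(variants, paste(v, collapse = ""))
      vpos <- c(vpos, i); vbase <- c(vbase, b)
    }
  }
  counts <- as.data.table(sample_counts)
  obs <- counts$observed[match(variants, counts$pattern)]
  obs[is.na(obs)] <- 0
  exp_ct <- expected_count(model, variants, total_reads, region_lengths,
                           convention)
  enr <- ifelse(obs > 0, obs / exp_ct, 0)
  mat <- matrix(NA_real_, 4L, W, dimnames = list(DNA_BASES, NULL))
  mat[cbind(vbase, vpos)] <- enr
  list(enrichment = mat, wildcard = wild, seed = seed)
}

#' Build a PWM from single-mismatch enrichments
#'
#' Each non-wildcard column is the enrichment vector normalized to sum 1
#' (linear enrichment-proportional weighting); with `scheme = "log"`, the
#' positive part of log2 enrichment is used instead. Wildcard columns are
#' emitted as uniform and flagged.
#'
#' @param me output of [mismatch_enrichments()].
#' @param scheme `"linear"` or `"log"` column weighting.
#' @return a [pwm] object.
#' @export
build_pwm <- function(me, scheme = c("linear", "log")) {
  scheme <- match.arg(scheme)
  W <- length(me$wildcard)
  mat <- matrix(0.25, 4L, W, dimnames = list(DNA_BASES, NULL))
  for (i in which(!me$wildcard)) {
    w <- me$enrichment[, i]
    if (scheme == "log") w <- ifelse(w > 1, log2(w), 0)
    if (sum(w) == 0) stop(sprintf("degenerate seed: all-zero enrichment column %d", i))
    mat[, i] <- w / sum(w)
  }
  new_pwm(mat, wildcard = me$wildcard, seed_pattern = me$seed)
}
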
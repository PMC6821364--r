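## Cluster rank-size analysis of selected pools. Unique sequences passing
## a coverage filter are clustered greedily at a sequence-identity
## threshold (most abundant / longest sequence first, as in the CD-HIT
## strategy), and the descending cluster-size curve is fitted with an
## exponential decay — the signature of successful enrichment.

#' Drop unique sequences below a coverage threshold
#'
#' @param seqs data.frame with columns `sequence` and `count`.
#' @param min_coverage minimum read count to retain (10 by default).
#' @export
coverage_filter <- function(seqs, min_coverage = 10L) {
  stopifnot(all(seqs$count >= 1))
  seqs[seqs$count >= min_coverage, , drop = FALSE]
}

#' Best ungapped-offset identity between two sequences
#'
#' Slides one sequence against the other over every ungapped offset, counts
#' matching positions in the overlap and divides by the longer length (a
#' conservative denominator for the 16-19 bp mixed-length libraries).
#'
#' @param a,b sequences.
#' @return identity fraction in [0, 1].
#' @export
seq_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  na <- length(ca); nb <- length(cb)
  best <- 0L
  for (off in (-(nb - 1L)):(na - 1L)) {
    ia <- max(1L, 1L + off):min(na, nb + off)
    if (length(ia) == 0L) next
    ib <- ia - off
    best <- max(best, sum(ca[ia] == cb[ib]))
  }
  best / max(na, nb)
}

#' Greedy identity clustering of unique sequences
#'
#' Sequences are sorted by count then length, descending; each joins the
#' first existing cluster whose representative it matches at or above the
#' identity threshold, otherwise it founds a new cluster. Clusters smaller
#' (in total member count) than `min_cluster_size` are dropped, and the
#' remainder returned in descending size order.
#'
#' @param seqs data.frame with columns `sequence` and `count`.
#' @param identity_threshold fractional identity required to join a cluster
#'   (0.90 by default).
#' @param min_cluster_size minimum total member count for a reported
#'   cluster (5 by default).
#' @return data.frame: rank, representative, size, n_members.
#' @export
greedy_cluster <- function(seqs, identity_threshold = 0.90,
                           min_cluster_size = 5L) {
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  if (nrow(seqs) == 0L) stop("no sequences to cluster")
  ord <- order(-seqs$count, -nchar(seqs$sequence), seqs$sequence)
  sq <- seqs$sequence[ord]; ct <- seqs$count[ord]
  reps <- character(0); size <- numeric(0); members <- integer(0)
  for (i in seq_along(sq)) {
    placed <- FALSE
    for (j in seq_along(reps)) {
      if (seq_identity(sq[i], reps[j]) >= identity_threshold) {
        size[j] <- size[j] + ct[i]
        members[j] <- members[j] + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, sq[i]); size <- c(size, ct[i]); members <- c(members, 1L)
    }
  }
  keep <- size >= min_cluster_size
  out <- data.frame(representative = reps[keep], size = size[keep],
                    n_members = members[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$size, out$representative), , drop = FALSE]
  if (nrow(out)) out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Exponential fit of the descending cluster-size curve
#'
#' Least-squares fit of `log(size) = log(a) - b * rank` on the
#' rank-ordered cluster sizes; a high R-squared with b > 0 is the
#' rank-size signature of an enriched (non-random) pool.
#'
#' @param sizes cluster sizes in descending order.
#' @return list: a (amplitude), b (decay per rank), r_squared, n_clusters.
#' @export
rank_size_fit <- function(sizes) {
  if (length(sizes) < 3L) stop("at least 3 clusters are required for the fit")
  stopifnot(all(sizes > 0))
  rank <- seq_along(sizes)
  fit <- lm(log(sizes) ~ rank)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((log(sizes) - mean(log(sizes)))^2)
  list(a = exp(unname(coef(fit)[1L])), b = -unname(coef(fit)[2L]),
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
       n_clusters = length(sizes))
}
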
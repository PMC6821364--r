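## Independent oracles used across the suite. These deliberately use naive
## algorithms (nested loops, plain recursion, power iteration) so they share
## no code path with the implementations they check.

## every (l, m, n, offset) window of a read, one pattern at a time
brute_force_gapped_kmers <- function(read, l_values = c(4L, 5L),
                                     n_values = c(4L, 5L)) {
  chars <- strsplit(read, "")[[1L]]
  N <- length(chars)
  out <- character(0)
  for (l in l_values) for (n in n_values) {
    if (l + n > N) next
    for (m in 0:(N - l - n)) {
      span <- l + m + n
      for (o in 1:(N - span + 1L)) {
        left <- paste(chars[o:(o + l - 1L)], collapse = "")
        right <- paste(chars[(o + l + m):(o + span - 1L)], collapse = "")
        out <- c(out, paste0(left, strrep("x", m), right))
      }
    }
  }
  unique(out)
}

## memo-free recursive Levenshtein (exponential; strings <= 8 only)
recursive_levenshtein <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- as.integer(substr(a, 1L, 1L) != substr(b, 1L, 1L))
  ta <- substr(a, 2L, nchar(a)); tb <- substr(b, 2L, nchar(b))
  min(recursive_levenshtein(ta, b) + 1L,
      recursive_levenshtein(a, tb) + 1L,
      recursive_levenshtein(ta, tb) + cost)
}

## order-respecting greedy clustering, written as plain loops over a
## pairwise-identity helper that tries every ungapped offset explicitly
oracle_greedy_cluster <- function(seqs, counts, threshold) {
  ident <- function(a, b) {
    ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
    best <- 0L
    for (sh in -(length(cb) - 1L):(length(ca) - 1L)) {
      matches <- 0L
      for (i in seq_along(ca)) {
        j <- i - sh
        if (j >= 1L && j <= length(cb) && ca[i] == cb[j]) matches <- matches + 1L
      }
      best <- max(best, matches)
    }
    best / max(length(ca), length(cb))
  }
  ord <- order(-counts, -nchar(seqs), seqs)
  reps <- character(0); size <- numeric(0)
  assign <- integer(length(seqs))
  for (i in ord) {
    placed <- FALSE
    for (j in seq_along(reps)) {
      if (ident(seqs[i], reps[j]) >= threshold) {
        size[j] <- size[j] + counts[i]; assign[i] <- j; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, seqs[i]); size <- c(size, counts[i])
      assign[i] <- length(reps)
    }
  }
  list(reps = reps, size = size, assign = assign)
}

## stationary 5-mer distribution of an order-5 chain by power iteration.
## state index is big-endian base 4: idx = sum (digit_j - 1) * 4^(5-j) + 1,
## so appending base b maps idx -> ((idx - 1) mod 4^4) * 4 + b.
power_iteration_stationary <- function(cond_probs, iters = 200L) {
  n_ctx <- nrow(cond_probs)
  tail_sz <- n_ctx / 4L
  v <- rep(1 / n_ctx, n_ctx)
  for (it in seq_len(iters)) {
    nv <- numeric(n_ctx)
    for (b in 1:4) {
      w <- v * cond_probs[, b]
      ## contexts sharing a tail r = ((idx-1) mod tail_sz) + 1 differ in the
      ## leading digit: idx = (d1-1)*tail_sz + r, column-major in a matrix
      rs <- rowSums(matrix(w, tail_sz, 4L))
      nv[(seq_len(tail_sz) - 1L) * 4L + b] <- rs
    }
    v <- nv / sum(nv)
  }
  v
}

## small uniform-random DNA helper
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}
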
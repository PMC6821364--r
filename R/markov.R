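## Fifth-order Markov background model of the unselected library.
##
## The model serves two purposes: (i) computing the probability of any gapped
## k-mer pattern, from which expected pattern counts in a sequenced sample are
## derived, and (ii) sampling synthetic background reads with the library's
## compositional bias. Conditional probabilities are stored as (context,
## base) counts; conditionals for contexts containing wildcard positions are
## obtained by marginalizing the counts over the wildcard slots, weighted by
## how often each concrete context occurs in the training corpus.

.CTX_W <- 5L
.N_CTX <- 4L^5L

## digits (1..4) of every context index, precomputed once per session
.ctx_digits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      idx <- 0:(.N_CTX - 1L)
      d <- matrix(0L, .N_CTX, .CTX_W)
      for (j in .CTX_W:1) {
        d[, j] <- idx %% 4L + 1L
        idx <- idx %/% 4L
      }
      cache <<- d
    }
    cache
  }
})

## one aggregate per wildcard mask: counts summed over wildcard context slots.
## mask bit j (1-based position j in the context) set => position specified.
.build_aggregates <- function(counts, init_counts) {
  digits <- .ctx_digits()
  agg_cond <- vector("list", 32L)
  agg_tot <- vector("list", 32L)
  agg_init <- vector("list", 32L)
  for (mask in 0:31) {
    spec <- which(bitwAnd(mask, 2L^(0:4)) > 0L)
    if (length(spec) == 0L) {
      red <- rep(1L, .N_CTX)
      nred <- 1L
    } else {
      red <- .kmer_index(digits[, spec, drop = FALSE])
      nred <- 4L^length(spec)
    }
    g <- factor(red, levels = seq_len(nred))
    agg_cond[[mask + 1L]] <- rowsum(counts, g)
    agg_tot[[mask + 1L]] <- rowSums(agg_cond[[mask + 1L]])
    agg_init[[mask + 1L]] <- as.numeric(rowsum(init_counts, g))
  }
  list(cond = agg_cond, tot = agg_tot, init = agg_init)
}

.new_markov_bg <- function(counts, init_counts, pseudocount) {
  structure(
    list(order = .CTX_W,
         counts = counts,
         init_counts = init_counts,
         pseudocount = pseudocount,
         n_init = sum(init_counts),
         agg = .build_aggregates(counts, init_counts)),
    class = "markov_bg")
}

#' Train a fifth-order Markov background model
#'
#' Estimates smoothed conditional probabilities P(base | previous 5 bases)
#' from every sliding window of the background (unselected library) reads,
#' together with marginal 5-mer frequencies taken over every read offset.
#' The marginal 5-mer table doubles as the initial-state distribution when a
#' pattern probability is evaluated, since patterns occur at arbitrary
#' offsets within the randomized region.
#'
#' @param reads character vector of A/C/G/T reads, each at least
#'   `order + 1` long.
#' @param order Markov order; only 5 is supported (the model of record for
#'   normalizing gapped k-mer counts).
#' @param pseudocount smoothing mass added per (context, base) cell.
#' @return an object of class `markov_bg`.
#' @export
train_markov <- function(reads, order = 5L, pseudocount = 1) {
  if (order != 5L) stop("only order-5 models are supported")
  if (length(reads) == 0L) stop("no background reads: model undefined")
  .check_dna(reads, "background read")
  if (any(nchar(reads) < order + 1L))
    stop("background reads must be at least order + 1 bases long")

  cond_tab <- numeric(.N_CTX * 4L)
  init_tab <- numeric(.N_CTX)
  for (L in sort(unique(nchar(reads)))) {
    sel <- reads[nchar(reads) == L]
    codes <- .base_codes(.char_matrix(sel))
    for (o in seq_len(L - .CTX_W)) {
      ctx <- .kmer_index(codes[, o:(o + .CTX_W - 1L), drop = FALSE])
      nxt <- codes[, o + .CTX_W]
      cond_tab <- cond_tab + tabulate(ctx + .N_CTX * (nxt - 1L), .N_CTX * 4L)
    }
    for (o in seq_len(L - .CTX_W + 1L)) {
      ctx <- .kmer_index(codes[, o:(o + .CTX_W - 1L), drop = FALSE])
      init_tab <- init_tab + tabulate(ctx, .N_CTX)
    }
  }
  counts <- matrix(cond_tab, .N_CTX, 4L, dimnames = list(NULL, DNA_BASES))
  .new_markov_bg(counts, init_tab, pseudocount)
}

#' Markov background from explicit chain probabilities
#'
#' Builds an exact `markov_bg` from a conditional probability table and a
#' stationary 5-mer distribution, with no smoothing. Conditional counts are
#' weighted by the stationary context frequencies so that marginalized
#' conditionals (needed for wildcard-containing contexts) are
#' stationarity-weighted averages, as they would be in a large corpus drawn
#' from the chain.
#'
#' @param cond_probs 4096 x 4 matrix, rows summing to 1: P(base | context).
#' @param init_probs length-4096 vector summing to 1: marginal 5-mer
#'   distribution.
#' @export
markov_bg_from_probs <- function(cond_probs, init_probs) {
  stopifnot(nrow(cond_probs) == .N_CTX, ncol(cond_probs) == 4L,
            length(init_probs) == .N_CTX)
  if (max(abs(rowSums(cond_probs) - 1)) > 1e-9)
    stop("cond_probs rows must sum to 1")
  if (abs(sum(init_probs) - 1) > 1e-9)
    stop("init_probs must sum to 1")
  counts <- cond_probs * init_probs
  colnames(counts) <- DNA_BASES
  .new_markov_bg(counts, init_probs, pseudocount = 0)
}

#' Uniform background chain
#' @export
uniform_background <- function() {
  markov_bg_from_probs(matrix(0.25, .N_CTX, 4L), rep(1 / .N_CTX, .N_CTX))
}

#' Zeroth-order compositional bias embedded in the order-5 interface
#'
#' Every conditional equals the given mononucleotide distribution and the
#' 5-mer marginals are its products, modelling a library whose synthesis
#' chemistry over- or under-delivers particular phosphoramidites uniformly
#' along the randomized region. The default is a strong A/T skew: at the
#' sequencing depths simulated here, the >=50-count filter retains gapped
#' k-mers only when the library bias concentrates probability on a reduced
#' alphabet, exactly the regime in which background normalization matters.
#'
#' @param base_probs length-4 probability vector in A, C, G, T order.
#' @export
biased_background <- function(base_probs = c(A = 0.46, C = 0.04, G = 0.04, T = 0.46)) {
  stopifnot(length(base_probs) == 4L)
  base_probs <- base_probs / sum(base_probs)
  digits <- .ctx_digits()
  init <- rep(1, .N_CTX)
  for (j in seq_len(.CTX_W)) init <- init * base_probs[digits[, j]]
  cond <- matrix(base_probs, .N_CTX, 4L, byrow = TRUE)
  markov_bg_from_probs(cond, init)
}

#' @export
print.markov_bg <- function(x, ...) {
  cat(sprintf("Order-%d Markov background: %s context windows, pseudocount %g\n",
              x$order, format(sum(x$counts), big.mark = ","), x$pseudocount))
  invisible(x)
}

## normalized tables used by the read sampler
.markov_sampling_tables <- function(model) {
  pc <- model$pseudocount
  cond <- model$counts + pc
  cond <- cond / rowSums(cond)
  init <- model$init_counts + pc
  init <- init / sum(init)
  list(cond_cum = t(apply(cond, 1L, cumsum)), init = init)
}

#' Probability of gapped k-mer patterns under the background model
#'
#' Factorizes each pattern as the probability of its initial 5-mer times the
#' conditional probability of each later character given the preceding
#' 5-character context, with every wildcard character contributing a factor
#' of exactly 1 (a wildcard matches any base). Wildcards appearing inside
#' the conditioning context of later characters are handled by marginalizing
#' the trained counts over the wildcard slots.
#'
#' @param model a `markov_bg`.
#' @param patterns character vector; wildcards written as `x`,
#'   e.g. `"ACTACxxxACGC"`. Each pattern must span at least 6 characters.
#' @return numeric vector of probabilities.
#' @export
pattern_probability <- function(model, patterns) {
  stopifnot(inherits(model, "markov_bg"))
  if (length(patterns) == 0L) return(numeric(0))
  if (any(grepl("[^ACGTx]", patterns)))
    stop("patterns may contain only A, C, G, T and wildcard 'x'")
  k <- nchar(patterns)
  if (any(k < model$order + 1L))
    stop("unsupported pattern: span must be at least order + 1 (6)")

  pc <- model$pseudocount
  n_init <- model$n_init
  out <- numeric(length(patterns))
  sig <- gsub("[ACGT]", "B", patterns)
  for (s in unique(sig)) {
    rows <- which(sig == s)
    pat <- patterns[rows]
    kk <- nchar(s)
    spec_pos <- which(strsplit(s, "")[[1L]] == "B")
    chars <- .char_matrix(pat)
    codes <- .base_codes(chars)

    ## initial 5-mer (marginalized over its wildcard slots)
    sp0 <- spec_pos[spec_pos <= .CTX_W]
    mask0 <- sum(2L^(sp0 - 1L)) + 1L
    t0 <- .CTX_W - length(sp0)
    if (length(sp0)) {
      ridx <- .kmer_index(codes[, sp0, drop = FALSE])
    } else ridx <- rep(1L, length(rows))
    p <- (model$agg$init[[mask0]][ridx] + pc * 4^t0) / (n_init + pc * 4^.CTX_W)

    for (i in setdiff(spec_pos, seq_len(.CTX_W))) {
      ctx_pos <- (i - .CTX_W):(i - 1L)
      spec_in_ctx <- which(ctx_pos %in% spec_pos)      # slots 1..5 of context
      mask <- sum(2L^(spec_in_ctx - 1L)) + 1L
      tw <- .CTX_W - length(spec_in_ctx)
      if (length(spec_in_ctx)) {
        ridx <- .kmer_index(codes[, ctx_pos[spec_in_ctx], drop = FALSE])
      } else ridx <- rep(1L, length(rows))
      b <- codes[, i]
      num <- model$agg$cond[[mask]][cbind(ridx, b)] + pc * 4^tw
      den <- model$agg$tot[[mask]][ridx] + 4 * pc * 4^tw
      p <- p * num / den
    }
    out[rows] <- p
  }
  out
}
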
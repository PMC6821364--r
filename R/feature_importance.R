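## Which positions and characters distinguish inducible from uninducible
## operators. A wrapper feature selection (simulated annealing over binary
## feature masks, scored by cross-validated regression error) is repeated
## over bootstrap resamples; the fraction of resamples in which a feature
## lands in the best-ever mask (its bagged frequency) is multiplied by the
## observed character frequency within each class to give the feature
## importance score
##
##   score[i, j, k] = bagged_frequency[i, j] * observed_frequency[i, j, k]
##
## for position i, character j in {A,T,G,C,-} and class k in {inducible,
## uninducible}; scores are then normalized to sum 1 per (position, class)
## and rendered as class-specific PWMs.

#' Split operators into inducible and uninducible classes
#'
#' @param operators data.frame with a `fold_induction` column.
#' @param threshold fold induction at or above which an operator counts as
#'   inducible (2 by default).
#' @return list of two data.frames: `inducible`, `uninducible`.
#' @export
split_classes <- function(operators, threshold = 2) {
  ind <- operators[operators$fold_induction >= threshold, , drop = FALSE]
  unind <- operators[operators$fold_induction < threshold, , drop = FALSE]
  if (nrow(ind) == 0L || nrow(unind) == 0L)
    stop("both classes must be non-empty at this fold-induction threshold")
  list(inducible = ind, uninducible = unind)
}

#' Simulated-annealing feature selection
#'
#' Minimizes `objective(mask)` over binary feature masks by single-feature
#' flips with Metropolis acceptance under a geometric cooling schedule
#' `T_t = t0 * alpha^t`; the best mask ever visited is returned. With
#' `t0 = 0` the search reduces to strict hill-climbing.
#'
#' @param n_features number of features.
#' @param objective function(logical mask) -> numeric error (lower is
#'   better).
#' @param iterations proposed flips.
#' @param t0 initial temperature.
#' @param alpha geometric cooling factor.
#' @param init_mask starting mask (all features on by default).
#' @param seed optional RNG seed.
#' @return list: `mask` (best mask), `objective` (its error), `trace`
#'   (accepted objective values).
#' @export
anneal_select <- function(n_features, objective, iterations = 500L,
                          t0 = 1, alpha = 0.95,
                          init_mask = rep(TRUE, n_features), seed = NULL) {
  if (n_features < 2L) stop("at least 2 features are required")
  if (!is.null(seed)) set.seed(seed)
  mask <- init_mask
  cur <- objective(mask)
  best_mask <- mask; best_obj <- cur
  trace <- numeric(0)
  if (iterations > 0L) {
    flips <- sample.int(n_features, iterations, replace = TRUE)
    for (t in seq_len(iterations)) {
      cand <- mask
      cand[flips[t]] <- !cand[flips[t]]
      obj <- objective(cand)
      dE <- obj - cur
      temp <- t0 * alpha^t
      accept <- dE < 0 || (temp > 0 && runif(1L) < exp(-dE / temp))
      if (accept) {
        mask <- cand; cur <- obj
        trace <- c(trace, cur)
        if (cur < best_obj) { best_obj <- cur; best_mask <- mask }
      }
    }
  }
  list(mask = best_mask, objective = best_obj, trace = trace)
}

#' Cross-validated regression error objective over a feature mask
#'
#' Returns a closure suitable for [anneal_select()]. The default scorer is
#' a ridge regression solved in closed form — a fast linear surrogate whose
#' additive structure matches the one-hot encoding, making tens of
#' thousands of mask evaluations affordable inside the bootstrap loop. The
#' RBF-kernel SVR used for the final sequence-function model is available
#' as an alternative scorer (`model = "svr"`, fixed mid-grid
#' hyperparameters).
#'
#' @param X feature matrix.
#' @param y targets.
#' @param model `"ridge"` or `"svr"`.
#' @param folds CV folds used by the objective (fixed at construction so
#'   the objective is deterministic across mask evaluations).
#' @param lambda ridge penalty.
#' @param seed RNG seed for the fold assignment.
#' @export
cv_error_objective <- function(X, y, model = c("ridge", "svr"), folds = 2L,
                               lambda = 1, seed = 1L) {
  model <- match.arg(model)
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  if (model == "ridge") {
    function(mask) {
      se <- 0
      for (f in seq_len(folds)) {
        tr <- fold != f
        Xtr <- X[tr, mask, drop = FALSE]; ytr <- y[tr]
        Xte <- X[!tr, mask, drop = FALSE]
        mu <- mean(ytr)
        if (ncol(Xtr) == 0L) {
          pred <- rep(mu, sum(!tr))
        } else {
          xm <- colMeans(Xtr)
          Xc <- sweep(Xtr, 2L, xm)
          beta <- solve(crossprod(Xc) + lambda * diag(ncol(Xc)),
                        crossprod(Xc, ytr - mu))
          pred <- mu + sweep(Xte, 2L, xm) %*% beta
        }
        se <- se + sum((pred - y[!tr])^2)
      }
      se / n
    }
  } else {
    function(mask) {
      if (!any(mask)) return(mean((y - mean(y))^2))
      se <- 0
      for (f in seq_len(folds)) {
        tr <- fold != f
        m <- e1071::svm(X[tr, mask, drop = FALSE], y[tr], kernel = "radial",
                        cost = 4, gamma = 1 / sum(mask), epsilon = 0.1,
                        scale = FALSE)
        pred <- predict(m, X[!tr, mask, drop = FALSE])
        se <- se + sum((pred - y[!tr])^2)
      }
      se / n
    }
  }
}

#' Bagged feature-selection frequencies over bootstrap resamples
#'
#' For each of `n_bootstrap` resamples (with replacement, original size) of
#' the dataset, [anneal_select()] is run on a cross-validated regression
#' objective built from the resample; the bagged frequency of a feature is
#' the fraction of resamples whose best mask contains it.
#'
#' @param X one-hot feature matrix (5 rows of characters per position).
#' @param y fold-induction targets.
#' @param n_bootstrap bootstrap resamples (100 by default).
#' @param iterations,t0,alpha annealing schedule per resample.
#' @param model objective scorer, see [cv_error_objective()].
#' @param seed RNG seed.
#' @return 5 x L matrix of frequencies in [0, 1] (rows A,T,G,C,-).
#' @export
bagged_frequency <- function(X, y, n_bootstrap = 100L, iterations = 60L,
                             t0 = 1, alpha = 0.9,
                             model = c("ridge", "svr"), seed = 1L) {
  model <- match.arg(model)
  set.seed(seed)
  p <- ncol(X)
  sel <- numeric(p)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
    obj <- cv_error_objective(X[idx, , drop = FALSE], y[idx], model = model,
                              seed = sample.int(.Machine$integer.max / 2, 1L))
    res <- anneal_select(p, obj, iterations = iterations, t0 = t0,
                         alpha = alpha)
    sel <- sel + res$mask
  }
  freq <- matrix(sel / n_bootstrap, nrow = 5L,
                 dimnames = list(SEQ_ALPHABET, NULL))
  freq
}

#' Observed per-class character frequencies
#'
#' @param seqs equal-length gap-filled sequences.
#' @param classes class label per sequence.
#' @return 3-d array [character (A,T,G,C,-), position, class]; each
#'   (position, class) column sums to 1.
#' @export
observed_frequency <- function(seqs, classes) {
  stopifnot(length(seqs) == length(classes))
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must share one aligned length")
  lv <- unique(classes)
  out <- array(0, dim = c(5L, w, length(lv)),
               dimnames = list(SEQ_ALPHABET, NULL, lv))
  for (k in seq_along(lv)) {
    chars <- .char_matrix(seqs[classes == lv[k]])
    for (j in seq_len(w)) {
      tab <- table(factor(chars[, j], levels = SEQ_ALPHABET))
      out[, j, k] <- as.numeric(tab) / sum(tab)
    }
  }
  out
}

#' Feature importance scores and class PWMs
#'
#' Elementwise product of the bagged selection frequency and the per-class
#' observed character frequency, normalized to sum 1 within each
#' (position, class) column. Positions whose raw scores are all zero fall
#' back to a uniform column with a warning.
#'
#' @param bagged 5 x L matrix from [bagged_frequency()].
#' @param observed 5 x L x class array from [observed_frequency()].
#' @return object of class `importance_matrix`: `raw` (unnormalized
#'   scores), `scores` (normalized), `bagged`, `observed`, and `pwms`
#'   (per-class 5-row PWMs over {A,T,G,C,-}).
#' @export
importance_scores <- function(bagged, observed) {
  stopifnot(dim(bagged)[1L] == 5L, all(dim(observed)[1:2] == dim(bagged)))
  classes <- dimnames(observed)[[3L]]
  raw <- observed
  for (k in seq_along(classes)) raw[, , k] <- bagged * observed[, , k]
  scores <- raw
  for (k in seq_along(classes)) for (j in seq_len(ncol(bagged))) {
    s <- sum(raw[, j, k])
    if (s == 0) {
      warning(sprintf("all-zero importance column (position %d, class %s): uniform fallback",
                      j, classes[k]))
      scores[, j, k] <- 1 / 5
    } else {
      scores[, j, k] <- raw[, j, k] / s
    }
  }
  pwms <- lapply(stats::setNames(seq_along(classes), classes),
                 function(k) scores[, , k])
  structure(list(raw = raw, scores = scores, bagged = bagged,
                 observed = observed, pwms = pwms),
            class = "importance_matrix")
}

#' @export
print.importance_matrix <- function(x, ...) {
  cat(sprintf("Importance matrix: %d positions x %d classes\n",
              ncol(x$bagged), dim(x$observed)[3L]))
  invisible(x)
}

#' Per-position differential importance between two classes
#'
#' Maximum absolute difference of normalized importance scores across
#' characters, per position — the quantity used to flag key sequence
#' features separating inducible from uninducible operators.
#'
#' @param im an [importance_scores()] result with exactly two classes.
#' @export
differential_importance <- function(im) {
  stopifnot(dim(im$scores)[3L] == 2L)
  apply(abs(im$scores[, , 1L] - im$scores[, , 2L]), 2L, max)
}
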
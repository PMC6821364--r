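## Sequence-function regression: one-hot encoded gap-filled operator
## sequences -> fold induction, via support vector regression with an RBF
## kernel, 5-fold cross-validation and a 10% held-out set.

SEQ_ALPHABET <- c("A", "T", "G", "C", "-")

#' One-hot encode gap-filled sequences
#'
#' Each position contributes a 5-way indicator block in fixed character
#' order A, T, G, C, - ; every row therefore sums to the aligned length.
#'
#' @param seqs equal-length sequences over {A,T,G,C,-}.
#' @return binary matrix (sequences x 5 * aligned_length) with
#'   column names `pos<i>.<char>` and attribute `aligned_length`.
#' @export
one_hot_encode <- function(seqs) {
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must share one aligned length")
  chars <- .char_matrix(seqs)
  ok <- matrix(chars %in% SEQ_ALPHABET, nrow = nrow(chars))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("illegal character '%s' at position %d of sequence %d",
                 chars[bad[1L, 1L], bad[1L, 2L]], bad[1L, 2L], bad[1L, 1L]))
  X <- matrix(0L, length(seqs), 5L * w)
  colnames(X) <- paste0("pos", rep(seq_len(w), each = 5L), ".",
                        rep(SEQ_ALPHABET, w))
  for (j in seq_len(w)) {
    code <- match(chars[, j], SEQ_ALPHABET)
    X[cbind(seq_len(length(seqs)), (j - 1L) * 5L + code)] <- 1L
  }
  attr(X, "aligned_length") <- w
  X
}

#' Decode a one-hot matrix back to sequences
#' @param X matrix produced by [one_hot_encode()].
#' @export
one_hot_decode <- function(X) {
  w <- ncol(X) / 5L
  apply(X, 1L, function(row) {
    paste(vapply(seq_len(w), function(j) {
      SEQ_ALPHABET[which(row[(j - 1L) * 5L + 1:5] == 1L)]
    }, character(1L)), collapse = "")
  })
}

#' Assign a 10% holdout and 5 cross-validation folds
#'
#' @param n number of sequences.
#' @param folds CV folds over the non-holdout portion.
#' @param holdout_frac fraction held out once for generalizability
#'   assessment.
#' @param seed RNG seed for the assignment.
#' @return list: `holdout` (indices), `fold` (fold id per index, NA for
#'   holdout rows).
#' @export
make_split <- function(n, folds = 5L, holdout_frac = 0.1, seed = 1L) {
  set.seed(seed)
  holdout <- sort(sample.int(n, round(holdout_frac * n)))
  rest <- setdiff(seq_len(n), holdout)
  fold <- rep(NA_integer_, n)
  fold[rest] <- sample(rep_len(seq_len(folds), length(rest)))
  list(holdout = holdout, fold = fold, folds = folds)
}

.default_svr_grid <- function(p) {
  list(cost = 2^seq(-2, 6, length.out = 5L),
       gamma = (1 / p) * 4^seq(-2, 2, length.out = 5L),
       epsilon = c(0.05, 0.1, 0.2))
}

.tune_svr <- function(X, y, grid, inner_folds = 3L) {
  n <- nrow(X)
  fold <- rep_len(seq_len(inner_folds), n)[sample.int(n)]
  combos <- expand.grid(cost = grid$cost, gamma = grid$gamma,
                        epsilon = grid$epsilon)
  errs <- vapply(seq_len(nrow(combos)), function(ci) {
    se <- 0
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      m <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = combos$cost[ci], gamma = combos$gamma[ci],
                      epsilon = combos$epsilon[ci], scale = FALSE)
      se <- se + sum((predict(m, X[!tr, , drop = FALSE]) - y[!tr])^2)
    }
    se / n
  }, numeric(1L))
  combos[which.min(errs), ]
}

#' Train and cross-validate the fold-induction SVR
#'
#' RBF-kernel support vector regression. Hyperparameters (cost, kernel
#' width, tube width) are selected by an inner cross-validation within each
#' training split; out-of-fold predictions are produced for every
#' non-holdout sequence and the holdout is scored once by a model tuned and
#' trained on all non-holdout data.
#'
#' @param X one-hot feature matrix.
#' @param y fold-induction targets.
#' @param split a [make_split()] assignment.
#' @param grid hyperparameter grid (lists `cost`, `gamma`, `epsilon`).
#' @param log_target model `log(y)` instead of `y` (predictions are
#'   back-transformed).
#' @param seed RNG seed for the inner-CV fold assignment.
#' @return list of class `svr_cv`: `oof` (out-of-fold predictions, NA at
#'   holdout rows), `holdout_pred`, `holdout_idx`, `params` (per fold),
#'   `final_model`, `metrics` (out-of-fold and holdout correlations).
#' @export
train_svr <- function(X, y, split = make_split(nrow(X)),
                      grid = .default_svr_grid(ncol(X)),
                      log_target = FALSE, seed = 1L) {
  stopifnot(nrow(X) == length(y), all(is.finite(y)))
  if (nrow(X) - length(split$holdout) < 20L)
    stop("at least 20 training sequences are required")
  set.seed(seed)
  ty <- if (log_target) log(y) else y
  back <- if (log_target) exp else identity
  oof <- rep(NA_real_, nrow(X))
  params <- vector("list", split$folds)
  for (f in seq_len(split$folds)) {
    tr <- which(!is.na(split$fold) & split$fold != f)
    te <- which(!is.na(split$fold) & split$fold == f)
    best <- .tune_svr(X[tr, , drop = FALSE], ty[tr], grid)
    params[[f]] <- best
    m <- e1071::svm(X[tr, , drop = FALSE], ty[tr], kernel = "radial",
                    cost = best$cost, gamma = best$gamma,
                    epsilon = best$epsilon, scale = FALSE)
    oof[te] <- back(predict(m, X[te, , drop = FALSE]))
  }
  rest <- which(!is.na(split$fold))
  best <- .tune_svr(X[rest, , drop = FALSE], ty[rest], grid)
  final <- e1071::svm(X[rest, , drop = FALSE], ty[rest], kernel = "radial",
                      cost = best$cost, gamma = best$gamma,
                      epsilon = best$epsilon, scale = FALSE)
  holdout_pred <- if (length(split$holdout)) {
    back(predict(final, X[split$holdout, , drop = FALSE]))
  } else numeric(0)
  metrics <- list(
    oof = evaluate_predictions(oof[rest], y[rest]),
    holdout = if (length(split$holdout) >= 3L) {
      evaluate_predictions(holdout_pred, y[split$holdout])
    } else NULL)
  structure(list(oof = oof, holdout_pred = holdout_pred,
                 holdout_idx = split$holdout, params = params,
                 final_params = best, final_model = final,
                 metrics = metrics, log_target = log_target),
            class = "svr_cv")
}

#' @export
print.svr_cv <- function(x, ...) {
  cat(sprintf("SVR (RBF) cross-validation: out-of-fold Spearman %.3f, Pearson %.3f\n",
              x$metrics$oof$spearman, x$metrics$oof$pearson))
  if (!is.null(x$metrics$holdout))
    cat(sprintf("  holdout (n=%d): Spearman %.3f, Pearson %.3f\n",
                length(x$holdout_idx), x$metrics$holdout$spearman,
                x$metrics$holdout$pearson))
  invisible(x)
}

#' Pearson and Spearman correlation of predictions against targets
#'
#' @param predictions,targets numeric vectors (at least 3 pairs).
#' @return list: pearson, spearman, n.
#' @export
evaluate_predictions <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets))
  if (length(predictions) < 3L) stop("at least 3 pairs are required")
  if (sd(predictions) == 0 || sd(targets) == 0)
    stop("correlation undefined: zero-variance vector")
  list(pearson = cor(predictions, targets, method = "pearson"),
       spearman = cor(predictions, targets, method = "spearman"),
       n = length(predictions))
}
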
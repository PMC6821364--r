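test_that("one-hot encoding follows the fixed A,T,G,C,- block layout", {
  X <- one_hot_encode("A-")
  expect_equal(unname(X[1, ]), c(1, 0, 0, 0, 0, 0, 0, 0, 0, 1))
  set.seed(15)
  seqs <- vapply(1:100, function(i) {
    paste(sample(c("A", "T", "G", "C", "-"), 12, replace = TRUE),
          collapse = "")
  }, character(1))
  X <- one_hot_encode(seqs)
  expect_true(all(rowSums(X) == 12))
  expect_identical(one_hot_decode(X), seqs)
  expect_error(one_hot_encode(c("ACGT", "ACG-T")), "aligned length")
  expect_error(one_hot_encode("ACNT"), "illegal character 'N' at position 3")
})

test_that("the holdout is disjoint from all CV folds", {
  sp <- make_split(200, seed = 3)
  expect_identical(length(sp$holdout), 20L)
  expect_true(all(is.na(sp$fold[sp$holdout])))
  rest <- setdiff(1:200, sp$holdout)
  expect_true(!any(is.na(sp$fold[rest])))
  expect_identical(sort(unique(sp$fold[rest])), 1:5)
})

test_that("SVR recovers a single-feature signal out of fold", {
  set.seed(16)
  seqs <- vapply(1:80, function(i) {
    paste(sample(c("A", "T", "G", "C"), 10, replace = TRUE), collapse = "")
  }, character(1))
  ## target depends only on the base at position 4
  eff <- c(A = 1, T = 3, G = 7, C = 12)
  y <- eff[substr(seqs, 4, 4)]
  X <- one_hot_encode(seqs)
  fit <- train_svr(X, unname(y), make_split(80, seed = 16), seed = 16)
  expect_gte(fit$metrics$oof$spearman, 0.95)
})

test_that("pure-noise targets score inside the permutation null band", {
  set.seed(17)
  seqs <- vapply(1:100, function(i) {
    paste(sample(c("A", "T", "G", "C"), 10, replace = TRUE), collapse = "")
  }, character(1))
  y <- rnorm(100)
  X <- one_hot_encode(seqs)
  small_grid <- list(cost = c(0.5, 4), gamma = 1 / ncol(X), epsilon = 0.1)
  fit <- train_svr(X, y, make_split(100, seed = 17), grid = small_grid,
                   seed = 17)
  rest <- which(!is.na(fit$oof))
  obs <- cor(fit$oof[rest], y[rest], method = "spearman")
  null <- vapply(1:500, function(i) {
    cor(fit$oof[rest], sample(y[rest]), method = "spearman")
  }, numeric(1))
  expect_gt(obs, quantile(null, 0.025))
  expect_lt(obs, quantile(null, 0.975))
})

test_that("duplicated rows with a fixed seed predict identically", {
  set.seed(18)
  seqs <- rep(vapply(1:30, function(i) {
    paste(sample(c("A", "T", "G", "C"), 8, replace = TRUE), collapse = "")
  }, character(1)), 2)
  y <- rep(rnorm(30), 2)
  X <- one_hot_encode(seqs)
  sp <- make_split(60, holdout_frac = 0, seed = 1)
  f1 <- train_svr(X, y, sp, seed = 5)
  f2 <- train_svr(X, y, sp, seed = 5)
  expect_identical(f1$oof, f2$oof)
})

test_that("out-of-fold predictions never see their own target", {
  set.seed(19)
  seqs <- vapply(1:60, function(i) {
    paste(sample(c("A", "T", "G", "C"), 8, replace = TRUE), collapse = "")
  }, character(1))
  y <- rnorm(60)
  X <- one_hot_encode(seqs)
  sp <- make_split(60, holdout_frac = 0, seed = 2)
  small_grid <- list(cost = 4, gamma = 1 / ncol(X), epsilon = 0.1)
  f1 <- train_svr(X, y, sp, grid = small_grid, seed = 3)
  i <- which(sp$fold == 2)[1]
  y2 <- y; y2[i] <- y2[i] + 100   # corrupt one target
  f2 <- train_svr(X, y2, sp, grid = small_grid, seed = 3)
  own_fold <- which(sp$fold == sp$fold[i])
  ## the model predicting i's fold is trained without i: unchanged there
  expect_equal(f1$oof[own_fold], f2$oof[own_fold], tolerance = 1e-10)
  ## other folds train on the corrupted point: they must differ
  other <- which(!is.na(sp$fold) & sp$fold != sp$fold[i])
  expect_gt(max(abs(f1$oof[other] - f2$oof[other])), 1e-6)
})

test_that("evaluation reports both correlation coefficients", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  ev <- evaluate_predictions(x, y)
  n <- length(x)
  pearson_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ev$pearson, pearson_hand)
  rx <- rank(x); ry <- rank(y)
  spearman_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(ev$spearman, spearman_hand)
  expect_equal(evaluate_predictions(1:5, 1:5)$spearman, 1)
  expect_equal(evaluate_predictions(1:5, -(1:5))$pearson, -1)
  expect_error(evaluate_predictions(rep(1, 5), 1:5), "zero-variance")
  expect_error(evaluate_predictions(1:2, 1:2), "3 pairs")
})
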
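test_that("class split applies the fold-induction threshold", {
  ops <- data.frame(id = 1:4, fold_induction = c(1.0, 1.1, 20, 30))
  cl <- split_classes(ops, threshold = 2)
  expect_identical(nrow(cl$inducible), 2L)
  expect_identical(nrow(cl$uninducible), 2L)
  expect_error(split_classes(data.frame(fold_induction = rep(1, 4))),
               "non-empty")
})

test_that("annealing recovers a planted feature pair", {
  ## objective strictly minimized by exactly the features {3, 17}
  target <- rep(FALSE, 20); target[c(3, 17)] <- TRUE
  objective <- function(mask) sum(mask != target)
  hits <- vapply(1:100, function(s) {
    res <- anneal_select(20, objective, iterations = 500, seed = s)
    identical(which(res$mask), c(3L, 17L))
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("annealing schedule edge cases behave as specified", {
  obj <- function(mask) sum(mask)
  init <- c(TRUE, FALSE, TRUE, TRUE)
  res0 <- anneal_select(4, obj, iterations = 0, init_mask = init)
  expect_identical(res0$mask, init)
  ## zero temperature: strict hill climbing, accepted objectives non-increasing
  res <- anneal_select(30, function(m) sum(m) + 0.1 * sum(m[1:3]),
                       iterations = 300, t0 = 0, seed = 9)
  expect_true(all(diff(res$trace) <= 0))
  expect_identical(sum(res$mask), 0L)
})

test_that("bagged frequencies are selection fractions in [0, 1]", {
  set.seed(20)
  ops <- generate_labeled_operator_sets(n_per_class = 30, seed = 20)
  X <- one_hot_encode(ops$sequence)
  bf <- bagged_frequency(X, ops$fold_induction, n_bootstrap = 5,
                         iterations = 10, seed = 20)
  expect_identical(dim(bf), c(5L, 16L))
  expect_true(all(bf >= 0 & bf <= 1))
  expect_identical(rownames(bf), c("A", "T", "G", "C", "-"))
})

test_that("importance scores obey the product identity and normalization", {
  set.seed(21)
  bagged <- matrix(runif(5 * 6), 5, 6, dimnames = list(c("A","T","G","C","-"), NULL))
  obs <- array(0, c(5, 6, 2), dimnames = list(c("A","T","G","C","-"), NULL,
                                              c("inducible", "uninducible")))
  for (k in 1:2) for (j in 1:6) {
    p <- runif(5); obs[, j, k] <- p / sum(p)
  }
  im <- importance_scores(bagged, obs)
  ## identity: raw score is the elementwise product, per displayed definition
  for (k in 1:2) expect_equal(im$raw[, , k], bagged * obs[, , k])
  ## normalized columns sum to one per (position, class)
  expect_equal(apply(im$scores, c(2, 3), sum),
               matrix(1, 6, 2, dimnames = list(NULL, dimnames(obs)[[3]])),
               ignore_attr = TRUE)
  ## direct product example: 0.5 x 0.4 = 0.2 before normalization
  b2 <- matrix(0.5, 5, 1, dimnames = list(c("A","T","G","C","-"), NULL))
  o2 <- array(c(0.4, 0.3, 0.1, 0.1, 0.1), c(5, 1, 1),
              dimnames = list(c("A","T","G","C","-"), NULL, "inducible"))
  expect_equal(importance_scores(b2, o2)$raw[1, 1, 1], 0.2)
  ## uniform observed: normalized column proportional to bagged alone
  o3 <- array(0.2, c(5, 1, 1), dimnames = list(c("A","T","G","C","-"), NULL, "k"))
  b3 <- matrix(c(0.8, 0.4, 0.2, 0.4, 0.2), 5, 1,
               dimnames = list(c("A","T","G","C","-"), NULL))
  sc <- importance_scores(b3, o3)$scores[, 1, 1]
  expect_equal(unname(sc), c(0.8, 0.4, 0.2, 0.4, 0.2) / 2)
  ## all-zero column falls back to uniform with a warning
  b4 <- matrix(0, 5, 1, dimnames = list(c("A","T","G","C","-"), NULL))
  expect_warning(im4 <- importance_scores(b4, o3), "uniform fallback")
  expect_equal(unname(im4$scores[, 1, 1]), rep(0.2, 5))
})

test_that("label permutation destroys the planted differential signal", {
  set.seed(22)
  ops <- generate_labeled_operator_sets(n_per_class = 60, seed = 22)
  labels <- ifelse(ops$fold_induction >= 2, "inducible", "uninducible")
  bagged <- matrix(1, 5, 16, dimnames = list(c("A","T","G","C","-"), NULL))
  planted <- c(1, 2, 3, 5, 6, 7, 13, 14)
  di_true <- differential_importance(
    importance_scores(bagged, observed_frequency(ops$sequence, labels)))
  stat <- function(di) mean(di[planted]) - mean(di[-planted])
  null <- vapply(1:200, function(i) {
    stat(differential_importance(
      importance_scores(bagged,
                        observed_frequency(ops$sequence, sample(labels)))))
  }, numeric(1))
  expect_gt(stat(di_true), quantile(null, 0.999))
  ## and the permuted statistic itself sits inside its own null spread
  expect_lt(abs(median(null)), stat(di_true) / 5)
})
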
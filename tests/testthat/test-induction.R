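test_that("fluorescence normalization is blank-corrected OD division", {
  expect_equal(normalize_fluorescence(1000, 0.5), 2000)
  expect_equal(normalize_fluorescence(50, 0.5, blank_gfp = 50), 0)
  expect_error(normalize_fluorescence(100, 0.1, blank_od = 0.2), "blank")
  ## synthetic 96-well plate equals the elementwise formula
  set.seed(9)
  gfp <- runif(96, 100, 5000); od <- runif(96, 0.2, 0.9)
  expect_equal(normalize_fluorescence(gfp, od, 30, 0.05),
               (gfp - 30) / (od - 0.05))
})

test_that("fold induction and repression are median ratios", {
  expect_equal(fold_induction(5000, 500), 10)
  expect_equal(fold_induction(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(fold_repression(4000, 400), 10)
  expect_error(fold_induction(10, 0), "zero")
  ## scale invariance
  set.seed(10)
  x <- rlnorm(50, 5, 1); y <- rlnorm(50, 4, 1)
  expect_equal(fold_induction(3.7 * x, 3.7 * y), fold_induction(x, y))
})

test_that("bimodal population fold induction matches the analytic mixture median", {
  ## induced: 70/30 lognormal mixture; uninduced: single lognormal
  w <- 0.7; ml1 <- log(3000); ml2 <- log(300); sdl <- 0.25
  mix_cdf <- function(q) w * plnorm(q, ml1, sdl) + (1 - w) * plnorm(q, ml2, sdl)
  true_med_ind <- uniroot(function(q) mix_cdf(q) - 0.5, c(1, 1e6))$root
  true_med_unind <- qlnorm(0.5, log(250), sdl)
  set.seed(11)
  n <- 2e5
  comp <- runif(n) < w
  induced <- rlnorm(n, ifelse(comp, ml1, ml2), sdl)
  uninduced <- rlnorm(n, log(250), sdl)
  fi <- fold_induction(induced, uninduced)
  expect_equal(fi, true_med_ind / true_med_unind, tolerance = 0.01)
})

test_that("induction summary computes per-clone ratios and reference percent", {
  cfg <- expression_sim_config(noise_cv = 0, seed = 1)
  ops <- data.frame(clone_id = c("weak", "strong", "ref"),
                    kd = c(1000, 5, 1e9))  # ref ~ unrepressed constitutive
  rec <- simulate_expression(ops, c(0, 10, 100, 1000), cfg)
  s <- induction_summary(rec, reference_clone = "ref")
  expect_equal(s$fold_induction[s$clone_id == "ref"], 1, tolerance = 1e-6)
  expect_gt(s$fold_induction[s$clone_id == "strong"],
            s$fold_induction[s$clone_id == "weak"])
  expect_equal(s$percent_of_constitutive[s$clone_id == "ref"], 100)
  expect_error(induction_summary(rec, reference_clone = "nope"), "absent")
})

test_that("Hill fit recovers noiseless parameters to machine-level accuracy", {
  concs <- rep(c(0, 5, 10, 25, 50, 100, 250, 500), each = 2)
  y <- 5 + 100 * concs^2 / (50^2 + concs^2)
  f <- fit_hill(concs, y)
  expect_true(f$converged)
  expect_equal(f$y0, 5, tolerance = 1e-6)
  expect_equal(f$v_max, 100, tolerance = 1e-6)
  expect_equal(f$k_m, 50, tolerance = 1e-6)
  expect_equal(f$hill_n, 2, tolerance = 1e-6)
  ## half-maximum identity holds by construction
  expect_equal(predict(f, f$k_m) - f$y0, f$v_max / 2, tolerance = 1e-9)
  ## residual invariant to replicate ordering
  set.seed(12)
  ynoisy <- y * rlnorm(length(y), 0, 0.03)
  ord <- sample(length(concs))
  f2 <- fit_hill(concs, ynoisy)
  f3 <- fit_hill(concs[ord], ynoisy[ord])
  expect_equal(f2$residual_sse, f3$residual_sse, tolerance = 1e-8)
})

test_that("flat responses are flagged rather than over-fitted", {
  concs <- c(0, 1, 10, 100, 1000)
  f <- fit_hill(concs, rep(200, 5))
  expect_true(!f$converged || f$v_max < 1e-3 * 200)
  expect_error(fit_hill(c(0, 1, 1, 1), c(1, 2, 2, 2)), "4 distinct")
  expect_error(fit_hill(c(1, 10, 100, 1000), 1:4), "zero-ligand")
})

test_that("Hill parameters are recovered under replicate noise", {
  true <- c(y0 = 5, vmax = 100, km = 50, n = 2)
  concs <- c(0, 5, 10, 25, 50, 100, 250, 500)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    L <- rep(concs, each = 3)
    mu <- true["y0"] + true["vmax"] * L^true["n"] / (true["km"]^true["n"] + L^true["n"])
    s2 <- log(1 + 0.05^2)
    f <- fit_hill(L, mu * rlnorm(length(L), -s2 / 2, sqrt(s2)))
    c(km = abs(f$k_m - 50) / 50, vmax = abs(f$v_max - 100) / 100,
      n = abs(f$hill_n - 2))
  }, numeric(3))
  med <- apply(errs, 1, median)
  expect_lt(med["km"], 0.15)
  expect_lt(med["vmax"], 0.10)
  expect_lt(med["n"], 0.3)
})

test_that("Levenshtein distance agrees with the recursive oracle and is a metric", {
  expect_equal(levenshtein("TACA", "TACA"), 0L)
  expect_equal(levenshtein("TACA", "TGCA"), 1L)
  set.seed(13)
  for (i in 1:100) {
    a <- random_dna(1, sample(0:8, 1))
    b <- random_dna(1, sample(0:8, 1))
    expect_identical(as.integer(levenshtein(a, b)),
                     as.integer(recursive_levenshtein(a, b)))
  }
  for (i in 1:50) {
    x <- random_dna(3, sample(4:10, 1))
    d12 <- levenshtein(x[1], x[2]); d23 <- levenshtein(x[2], x[3])
    expect_lte(levenshtein(x[1], x[3]), d12 + d23)
  }
})

test_that("speedometer coordinates center on the top-inducing operator", {
  seqs <- c("TACAGGTT", "TACAGGTA", "TTTTGGTT")
  fi <- c(25, 3, 1)
  sp <- speedometer_coordinates(seqs, fi)
  expect_equal(sp$radial, c(0, 1, 3))
  expect_equal(sp$angular, fi)
})
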
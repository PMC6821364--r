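test_that("background library is equimolar across lengths and seed-deterministic", {
  b <- biased_background()
  r1 <- generate_background_library(b, 16:19, 4000, seed = 5)
  expect_equal(unname(table(nchar(r1))), rep(1000L, 4L), ignore_attr = TRUE)
  r2 <- generate_background_library(b, 16:19, 4000, seed = 5)
  expect_identical(r1, r2)
  expect_error(generate_background_library(b, integer(0), 100), "length")
})

test_that("motif energy is zero at consensus and additive over mismatches", {
  mo <- dimeric_motif()
  core <- sub("x+", strrep("A", mo$spacer), motif_consensus_pattern(mo))
  expect_equal(motif_energy(core, mo), 0)
  one_mm <- paste0("G", substr(core, 2, nchar(core)))
  expect_equal(motif_energy(one_mm, mo), log(0.7 / 0.1), tolerance = 1e-12)
  expect_equal(motif_energy("ACGTACG", mo), Inf)
})

test_that("selection with beta = 0 is a neutral multinomial resample", {
  set.seed(21)
  mo <- dimeric_motif()
  core <- motif_consensus_pattern(mo)
  carriers <- vapply(1:100, function(i) paste0(random_dna(1, 3), core,
                                               random_dna(1, 3)), character(1))
  lib <- c(carriers, random_dna(1900, 16))
  cfg <- selection_sim_config(true_motif = mo, reads_per_round = 2000L,
                              rounds = 3L, stringency = 0, seed = 22)
  sel <- simulate_selection(lib, cfg)
  frac <- mean(grepl(core, sel$rounds[[3]]))
  ## neutral: stays near the library's 5% carrier fraction
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("strong selection fixes a single perfect site", {
  set.seed(23)
  mo <- dimeric_motif()
  core <- sub("x+", "", motif_consensus_pattern(mo))
  perfect <- paste0("ACG", core, "CGT")
  lib <- c(perfect, random_dna(999, 16))
  cfg <- selection_sim_config(true_motif = mo, reads_per_round = 1000L,
                              rounds = 2L, stringency = 50, seed = 24)
  sel <- simulate_selection(lib, cfg)
  expect_equal(mean(sel$rounds[[2]] == perfect), 1)
})

test_that("one selection round matches the exact reweighting oracle", {
  set.seed(31)
  mo <- dimeric_motif()
  core <- motif_consensus_pattern(mo)
  lib <- c(vapply(1:50, function(i) paste0(random_dna(1, 3), core,
                                           random_dna(1, 3)), character(1)),
           random_dna(5000, 16))
  beta <- 1.5
  cfg <- selection_sim_config(true_motif = mo, reads_per_round = 20000L,
                              rounds = 1L, stringency = beta, seed = 32)
  sel <- simulate_selection(lib, cfg)
  w <- exp(-beta * motif_energy(lib, mo))
  expected_frac <- sum(w[grepl(core, lib)]) / sum(w)
  obs_frac <- mean(grepl(core, sel$rounds[[1]]))
  se <- sqrt(expected_frac * (1 - expected_frac) / 20000)
  expect_lt(abs(obs_frac - expected_frac), 4 * se)
})

test_that("planted core enriches >= 10x under the default stringency at small scale", {
  cfg <- selection_sim_config(reads_per_round = 5000L,
                              library_size = 50000L, seed = 33)
  sel <- simulate_selection(config = cfg)
  core <- motif_consensus_pattern(cfg$true_motif)
  f0 <- mean(grepl(core, sel$library))
  f5 <- mean(grepl(core, sel$rounds[[5]]))
  expect_gt(f0, 0)
  expect_gt(f5 / f0, 10)
})

test_that("noise-free expression equals the closed-form occupancy model", {
  cfg <- expression_sim_config(noise_cv = 0)
  ops <- data.frame(clone_id = c("a", "b"), kd = c(5, 500))
  concs <- c(0, 1, 10, 100, 1000)
  rec <- simulate_expression(ops, concs, cfg)
  rec$norm <- normalize_fluorescence(rec$gfp_raw, rec$od600)
  for (i in seq_len(nrow(rec))) {
    kd <- ops$kd[match(rec$clone_id[i], ops$clone_id)]
    expect_equal(rec$norm[i], occupancy_expression(kd, rec$ligand_conc[i], cfg),
                 tolerance = 1e-12)
  }
  ## limits: full repression at L = 0 with atf >> Kd; v_const as L -> Inf
  tight <- expression_sim_config(atf_level = 1e6, noise_cv = 0)
  expect_lt(occupancy_expression(1, 0, tight) / tight$v_const, 1e-4)
  expect_equal(occupancy_expression(1, 1e12, tight) / tight$v_const, 1,
               tolerance = 1e-2)
})

test_that("induced plateau and baseline order monotonically with Kd", {
  cfg <- expression_sim_config(noise_cv = 0)
  kd <- c(1, 10, 100, 1000)
  base <- occupancy_expression(kd, 0, cfg)
  plateau <- occupancy_expression(kd, 1e7, cfg)
  expect_true(all(diff(base) > 0))
  expect_true(all(diff(plateau) > 0))
})

test_that("labeled operator sets carry the planted contrast", {
  ops <- generate_labeled_operator_sets(n_per_class = 50, seed = 4)
  ind <- ops[ops$class == "inducible", ]
  unind <- ops[ops$class == "uninducible", ]
  expect_true(all(substr(ind$sequence, 1, 4) == "TACA"))
  expect_true(all(substr(unind$sequence, 3, 6) == "TACA"))
  ## thresholding fold induction at 2 separates the classes perfectly
  expect_true(all(ind$fold_induction >= 2))
  expect_true(all(unind$fold_induction < 2))
  ## flank rule overlapping the core window is a configuration error
  bad_rules <- list(inducible = list(`2` = c(A = 1, C = 0, G = 0, T = 0)),
                    uninducible = list())
  expect_error(generate_labeled_operator_sets(n_per_class = 5,
                                              flank_rules = bad_rules,
                                              seed = 1),
               "overlap")
})
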
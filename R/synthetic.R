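## Synthetic-data generators emulating the two experimental arms of the
## study: (i) in vitro selection of a randomized operator library by a
## dimeric repressor, sequenced once per round; (ii) reporter-expression
## measurements of clones carrying selected operators, uninduced and across
## a ligand dose series.

#' Dimeric operator motif with an energy matrix
#'
#' The planted truth of the selection simulator: two half-site position
#' probability matrices separated by a fixed spacer. Binding energy of a
#' sequence window is the standard log-odds mismatch penalty
#' `sum(log(p_consensus / p_base))`, zero for the consensus and positive
#' otherwise, summed over both half-sites; the energy of a read is the
#' minimum over all windows.
#'
#' The default motif is the 10 bp palindrome TAATA.TATTA: two 5 bp
#' half-sites, directly abutting. Keeping every motif position under
#' selection (no free spacer inside the site) is what makes the planted
#' site identifiable from pools of this depth; wider spacers are supported
#' and behave identically up to the spacer positions being unconstrained.
#'
#' @param left_consensus,right_consensus half-site consensus strings (the
#'   selected repressors bind palindromes, so the right half-site is
#'   typically the reverse complement of the left).
#' @param spacer number of unconstrained positions between the half-sites.
#' @param consensus_prob probability mass on the consensus base in each
#'   half-site column; the remainder is spread evenly over the other bases.
#' @param left_pwm,right_pwm alternatively, explicit 4 x width matrices
#'   (rows A, C, G, T; columns summing to 1).
#' @export
dimeric_motif <- function(left_consensus = "TAATA", right_consensus = "TATTA",
                          spacer = 0L, consensus_prob = 0.7,
                          left_pwm = NULL, right_pwm = NULL) {
  cons_pwm <- function(cons) {
    codes <- match(strsplit(cons, "")[[1L]], DNA_BASES)
    m <- matrix((1 - consensus_prob) / 3, 4L, length(codes),
                dimnames = list(DNA_BASES, NULL))
    m[cbind(codes, seq_along(codes))] <- consensus_prob
    m
  }
  left <- left_pwm %||% cons_pwm(left_consensus)
  right <- right_pwm %||% cons_pwm(right_consensus)
  stopifnot(nrow(left) == 4L, nrow(right) == 4L, spacer >= 0L)
  if (max(abs(colSums(left) - 1)) > 1e-9 || max(abs(colSums(right) - 1)) > 1e-9)
    stop("half-site PWM columns must sum to 1")
  energy <- function(pwm) {
    eps <- -log(sweep(pwm, 2L, apply(pwm, 2L, max), "/"))
    rownames(eps) <- DNA_BASES
    eps
  }
  structure(list(left = left, right = right, spacer = as.integer(spacer),
                 left_energy = energy(left), right_energy = energy(right)),
            class = "dimeric_motif")
}

#' @export
print.dimeric_motif <- function(x, ...) {
  cons <- function(m) paste(DNA_BASES[apply(m, 2L, which.max)], collapse = "")
  cat(sprintf("Dimeric motif %s-[%d]-%s (span %d)\n", cons(x$left), x$spacer,
              cons(x$right), motif_span(x)))
  invisible(x)
}

#' @export
motif_span <- function(motif) {
  ncol(motif$left) + motif$spacer + ncol(motif$right)
}

#' Consensus gapped k-mer of a dimeric motif
#' @export
motif_consensus_pattern <- function(motif) {
  cons <- function(m) paste(DNA_BASES[apply(m, 2L, which.max)], collapse = "")
  paste0(cons(motif$left), strrep("x", motif$spacer), cons(motif$right))
}

#' Binding energy of reads against a dimeric motif
#'
#' @param reads character vector of A/C/G/T reads.
#' @param motif a [dimeric_motif()].
#' @return numeric vector: minimum (best) window energy per read; `Inf` for
#'   reads shorter than the motif span.
#' @export
motif_energy <- function(reads, motif) {
  span <- motif_span(motif)
  wl <- ncol(motif$left); wr <- ncol(motif$right)
  out <- numeric(length(reads))
  for (L in sort(unique(nchar(reads)))) {
    sel <- which(nchar(reads) == L)
    if (L < span) { out[sel] <- Inf; next }
    codes <- .base_codes(.char_matrix(reads[sel]))
    best <- rep(Inf, length(sel))
    for (o in seq_len(L - span + 1L)) {
      e <- numeric(length(sel))
      for (j in seq_len(wl)) e <- e + motif$left_energy[cbind(codes[, o + j - 1L], j)]
      for (j in seq_len(wr)) e <- e + motif$right_energy[cbind(codes[, o + wl + motif$spacer + j - 1L], j)]
      best <- pmin(best, e)
    }
    out[sel] <- best
  }
  out
}

#' Draw background-library reads from a Markov chain
#'
#' Reads are sampled from the supplied order-5 background chain, split
#' equimolar across the requested randomized-region lengths (to within one
#' read, mirroring pooled equimolar library synthesis).
#'
#' @param background_spec a `markov_bg` describing the library bias.
#' @param lengths randomized-region lengths, e.g. `16:19`.
#' @param n_reads total reads to draw.
#' @param seed optional RNG seed for reproducibility.
#' @return character vector of reads.
#' @export
generate_background_library <- function(background_spec, lengths = 16:19,
                                        n_reads, seed = NULL) {
  stopifnot(inherits(background_spec, "markov_bg"), n_reads >= 1)
  if (length(lengths) == 0L) stop("at least one library length is required")
  if (!is.null(seed)) set.seed(seed)
  tabs <- .markov_sampling_tables(background_spec)
  per <- diff(floor(seq(0, n_reads, length.out = length(lengths) + 1L)))
  reads <- character(0)
  for (i in seq_along(lengths)) {
    if (per[i] == 0) next
    reads <- c(reads, .sample_chain(tabs, lengths[i], per[i]))
  }
  reads
}

.sample_chain <- function(tabs, L, n) {
  stopifnot(L >= .CTX_W)
  codes <- matrix(0L, n, L)
  ctx <- sample.int(.N_CTX, n, replace = TRUE, prob = tabs$init)
  codes[, 1:.CTX_W] <- .ctx_digits()[ctx, , drop = FALSE]
  if (L > .CTX_W) {
    for (j in (.CTX_W + 1L):L) {
      u <- runif(n)
      cum <- tabs$cond_cum[ctx, , drop = FALSE]
      b <- 1L + (u > cum[, 1L]) + (u > cum[, 2L]) + (u > cum[, 3L])
      codes[, j] <- b
      ctx <- ((ctx - 1L) %% 4L^(.CTX_W - 1L)) * 4L + (b - 1L) + 1L
    }
  }
  chars <- matrix(DNA_BASES[codes], n, L)
  do.call(paste0, asplit(chars, 2L))
}

#' Configuration for the selection simulator
#'
#' @param true_motif a [dimeric_motif()].
#' @param library_lengths randomized-region lengths in the pooled library.
#' @param reads_per_round reads sequenced (and amplified to) per round.
#' @param rounds number of selection rounds (five in the experiments this
#'   emulates).
#' @param stringency inverse-temperature-like selection stringency
#'   (beta >= 0); 0 means no selection.
#' @param background_spec `markov_bg` from which the naive library is drawn.
#' @param library_size reads in the naive (round 0) library; the starting
#'   library is far more diverse than the per-round sequencing bottleneck,
#'   so this defaults to 160 times `reads_per_round`.
#' @param seed optional RNG seed.
#' @export
selection_sim_config <- function(true_motif = dimeric_motif(),
                                 library_lengths = 16:19,
                                 reads_per_round = 50000L,
                                 rounds = 5L,
                                 stringency = 2,
                                 background_spec = biased_background(),
                                 library_size = 160L * reads_per_round,
                                 seed = NULL) {
  stopifnot(rounds >= 1L, reads_per_round >= 1L)
  if (stringency < 0) stop("stringency (beta) must be >= 0")
  structure(list(true_motif = true_motif, library_lengths = library_lengths,
                 reads_per_round = as.integer(reads_per_round),
                 rounds = as.integer(rounds), stringency = stringency,
                 background_spec = background_spec,
                 library_size = as.integer(library_size), seed = seed),
            class = "selection_sim_config")
}

#' Simulate rounds of in vitro selection
#'
#' Each round resamples the current pool with probability proportional to
#' `exp(-beta * E)` — E the best-window binding energy, zero for a perfect
#' dimeric site — and amplifies back to `reads_per_round` by multinomial
#' resampling (PCR modeled as multinomial amplification). With beta = 0
#' every round is a plain multinomial resample of its predecessor.
#'
#' @param library optional starting reads; drawn from
#'   `config$background_spec` when `NULL`.
#' @param config a [selection_sim_config()].
#' @return list with elements `library` (round 0 reads) and `rounds` (list
#'   of per-round read vectors).
#' @export
simulate_selection <- function(library = NULL, config = selection_sim_config()) {
  stopifnot(inherits(config, "selection_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(library)) {
    library <- generate_background_library(config$background_spec,
                                           config$library_lengths,
                                           config$library_size)
  }
  if (length(library) == 0L) stop("starting library is empty")
  pool <- library
  rounds <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    uniq <- unique(pool)
    w_uniq <- if (config$stringency == 0) {
      rep(1, length(uniq))
    } else {
      exp(-config$stringency * motif_energy(uniq, config$true_motif))
    }
    cnt <- table(factor(pool, levels = uniq))
    w <- as.numeric(cnt) * w_uniq
    if (all(w == 0)) stop("all selection weights are zero; lower stringency")
    draw <- sample.int(length(uniq), config$reads_per_round, replace = TRUE,
                       prob = w)
    pool <- uniq[draw]
    rounds[[r]] <- pool
  }
  list(library = library, rounds = rounds)
}

#' Configuration for the expression simulator
#'
#' Single-operator occupancy model: the repressor occupies the operator
#' with probability `theta = R_eff / (R_eff + Kd)` where the free-repressor
#' concentration `R_eff = atf_level / (1 + L / ligand_kd)` falls as ligand
#' L accumulates; expression is `v_const * (1 - theta)` with multiplicative
#' lognormal noise.
#'
#' @param atf_level effective free-repressor concentration (nM).
#' @param ligand_kd ligand-aTF dissociation constant (uM).
#' @param v_const maximal constitutive expression (arbitrary fluorescence
#'   units per OD).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param od600 culture density at harvest (the simulated plate reader
#'   reports raw fluorescence `expression * od600`).
#' @param seed optional RNG seed.
#' @export
expression_sim_config <- function(atf_level = 100, ligand_kd = 50,
                                  v_const = 2000, noise_cv = 0.05,
                                  od600 = 0.5, seed = NULL) {
  stopifnot(atf_level > 0, ligand_kd > 0, v_const > 0, noise_cv >= 0, od600 > 0)
  structure(list(atf_level = atf_level, ligand_kd = ligand_kd,
                 v_const = v_const, noise_cv = noise_cv, od600 = od600,
                 seed = seed),
            class = "expression_sim_config")
}

#' Deterministic occupancy expression (closed form, no noise)
#' @param kd operator-aTF dissociation constant (nM).
#' @param ligand_conc ligand concentration (uM).
#' @param config an [expression_sim_config()].
#' @export
occupancy_expression <- function(kd, ligand_conc, config) {
  r_eff <- config$atf_level / (1 + ligand_conc / config$ligand_kd)
  theta <- r_eff / (r_eff + kd)
  config$v_const * (1 - theta)
}

#' Simulate reporter-expression measurements for operator clones
#'
#' @param operators data.frame with columns `clone_id` and `kd`
#'   (operator-aTF dissociation constant, nM).
#' @param ligand_concs ligand concentrations (uM); include 0 for the
#'   uninduced condition.
#' @param config an [expression_sim_config()].
#' @param n_replicates replicate wells per (clone, concentration).
#' @return data.frame of expression records: clone_id, condition,
#'   ligand_conc, od600, gfp_raw.
#' @export
simulate_expression <- function(operators, ligand_concs,
                                config = expression_sim_config(),
                                n_replicates = 1L) {
  stopifnot(all(ligand_concs >= 0), all(operators$kd > 0))
  if (!is.null(config$seed)) set.seed(config$seed)
  grid <- expand.grid(i = seq_len(nrow(operators)), L = ligand_concs,
                      rep = seq_len(n_replicates))
  mu <- occupancy_expression(operators$kd[grid$i], grid$L, config)
  if (config$noise_cv > 0) {
    s2 <- log(1 + config$noise_cv^2)
    mu <- mu * rlnorm(length(mu), meanlog = -s2 / 2, sdlog = sqrt(s2))
  }
  data.frame(clone_id = operators$clone_id[grid$i],
             condition = ifelse(grid$L == 0, "uninduced", "induced"),
             ligand_conc = grid$L,
             replicate = grid$rep,
             od600 = config$od600,
             gfp_raw = mu * config$od600,
             stringsAsFactors = FALSE)
}

.default_flank_rules <- function() {
  list(
    inducible = list(
      `7` = c(A = 0.55, C = 0.15, G = 0.15, T = 0.15),
      `13` = c(A = 0.15, C = 0.55, G = 0.15, T = 0.15),
      `14` = c(A = 0.15, C = 0.15, G = 0.25, T = 0.45)),
    uninducible = list(
      `7` = c(A = 0.15, C = 0.15, G = 0.55, T = 0.15),
      `13` = c(A = 0.15, C = 0.15, G = 0.15, T = 0.55),
      `14` = c(A = 0.45, C = 0.25, G = 0.15, T = 0.15)))
}

.default_flank_effects <- function() {
  list(`7` = c(A = 1.6, C = 1.0, G = 0.7, T = 0.45),
       `13` = c(A = 0.5, C = 1.5, G = 1.0, T = 0.7),
       `14` = c(A = 0.8, C = 1.0, G = 1.2, T = 1.4))
}

#' Generate labeled inducible / uninducible operator sets
#'
#' Emulates the sequence contrast between functional promoter classes: both
#' classes carry the same core half-site motif, but at shifted windows
#' (positions 1-4 for the inducible class versus 3-6 for the uninducible
#' class by default), and with class-specific base preferences at flanking
#' positions. Fold induction of the inducible class is high on average and
#' modulated multiplicatively by the flanking bases, giving a learnable
#' within-class sequence-function gradient; the uninducible class sits at
#' fold induction ~1.
#'
#' @param n_per_class sequences per class.
#' @param core core motif string planted in both classes.
#' @param seq_length operator length (gap-free).
#' @param inducible_start,uninducible_start 1-based start of the core window
#'   in each class.
#' @param flank_rules per-class list mapping position (as character name) to
#'   a base-probability vector; positions must not overlap the core window.
#' @param flank_effects list mapping position to per-base fold-induction
#'   multipliers (applied to the inducible class only).
#' @param fi_inducible,fi_uninducible mean fold induction of each class.
#' @param noise_cv lognormal noise CV on fold induction.
#' @param seed optional RNG seed.
#' @return data.frame: id, sequence, class, fold_induction.
#' @export
generate_labeled_operator_sets <- function(n_per_class = 100L, core = "TACA",
                                           seq_length = 16L,
                                           inducible_start = 1L,
                                           uninducible_start = 3L,
                                           flank_rules = .default_flank_rules(),
                                           flank_effects = .default_flank_effects(),
                                           fi_inducible = 20,
                                           fi_uninducible = 1.05,
                                           noise_cv = 0.05,
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- nchar(core)
  starts <- c(inducible = inducible_start, uninducible = uninducible_start)
  if (any(starts + w - 1L > seq_length)) stop("core window exceeds sequence length")
  for (cls in names(flank_rules)) {
    pos <- as.integer(names(flank_rules[[cls]]))
    if (any(pos >= starts[[cls]] & pos <= starts[[cls]] + w - 1L))
      stop("flank rule overlaps the core window: contradictory configuration")
  }
  gen_class <- function(cls, n) {
    chars <- matrix(sample(DNA_BASES, n * seq_length, replace = TRUE),
                    n, seq_length)
    st <- starts[[cls]]
    core_chars <- strsplit(core, "")[[1L]]
    for (j in seq_len(w)) chars[, st + j - 1L] <- core_chars[j]
    for (p in names(flank_rules[[cls]])) {
      chars[, as.integer(p)] <- sample(DNA_BASES, n, replace = TRUE,
                                       prob = flank_rules[[cls]][[p]])
    }
    seqs <- do.call(paste0, asplit(chars, 2L))
    s2 <- log(1 + noise_cv^2)
    noise <- rlnorm(n, -s2 / 2, sqrt(s2))
    if (cls == "inducible") {
      mult <- rep(1, n)
      for (p in names(flank_effects)) {
        eff <- flank_effects[[p]]
        ## center so the class mean stays at fi_inducible
        eff <- eff / sum(eff * flank_rules[[cls]][[p]])
        mult <- mult * eff[chars[, as.integer(p)]]
      }
      fi <- fi_inducible * mult * noise
    } else {
      fi <- fi_uninducible * noise
    }
    data.frame(sequence = seqs, class = cls, fold_induction = fi,
               stringsAsFactors = FALSE)
  }
  out <- rbind(gen_class("inducible", n_per_class),
               gen_class("uninducible", n_per_class))
  out <- cbind(id = sprintf("op%03d", seq_len(nrow(out))), out)
  out
}
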
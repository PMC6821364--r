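# operatr

Tools for engineering **ligand-inducible bacterial promoters** by placing an
operator — the binding site of an allosteric transcription factor (aTF) —
between the −35 and −10 elements of a constitutive promoter. When the aTF
(a dimeric repressor such as PmeR, TtgR or NalC) occupies the operator it
blocks transcription; its ligand releases it, switching the promoter on.
`operatr` implements the computational side of this workflow for people who
build such biosensors: analysing in vitro selection (SELEX) sequencing of
randomized operator libraries, characterizing induction of individual
promoter clones, and learning which operator sequence features make a
promoter inducible rather than constitutively repressed.

## What it computes

**Gapped k-mer enrichment with a Markov background.** Selection reads are
demultiplexed by an 8 bp barcode and truncated to the randomized 16–19 bp
region. Patterns of the form *l*-mer / *m*-spacer / *n*-mer (written e.g.
`ACTACxxxACGC` for a 5–3–4 gapped 12-mer; *l*, *n* ∈ {4, 5}, *m* = 0 … N−l−n)
are counted once per read, and patterns seen in fewer than 50 reads are
dropped. Enrichment is observed / expected, where the expected count comes
from a fifth-order Markov model of the unselected library:

    P(ACTACxxxACGC) = P(ACTAC) · P(x|ACTAC) · P(x|CTACx) · P(x|TACxx)
                      · P(A|ACxxx) · P(C|CxxxA) · P(G|xxxAC) · P(C|xxACG),

with every wildcard factor equal to 1 and wildcard-containing contexts
marginalized from the trained counts. The most enriched pattern seeds a
position weight matrix (PWM) whose columns are the enrichments of all
single-mismatch variants, normalized per position.

**Cluster rank-size analysis.** Unique selected sequences passing 10×
coverage are clustered greedily at 90% identity (most-abundant-first, the
CD-HIT strategy); descending cluster sizes follow the exponential
`size ≈ a·exp(−b·rank)` characteristic of a successfully enriched pool.

**Induction and dose response.** Fluorescence is blank-corrected and
OD-normalized; fold induction FI = induced / uninduced normalized
fluorescence (medians for populations). Dose series are fitted to the Hill
equation `y = y0 + Vmax·L^n / (Km^n + L^n)` by bounded multi-start
nonlinear least squares, giving the maximal activity, ligand sensitivity
(Km) and cooperativity (n) of every promoter.

**Sequence → function learning.** Gap-filled operator sequences are one-hot
encoded over {A, T, G, C, −} and an RBF-kernel support vector regression
predicts fold induction under 5-fold cross-validation with a 10% holdout.
Feature importance contrasting inducible with uninducible operators is

    score[i, j, k] = bagged_frequency[i, j] × observed_frequency[i, j, k]

for position *i*, character *j*, class *k*, where the bagged frequency is
how often feature (i, j) lands in the best mask of a simulated-annealing
feature selection across 100 bootstrap resamples; normalized scores form
class-specific PWMs whose differences flag the positions that control
inducibility.

**Synthetic data.** Because every stage needs inputs with known truth, the
package ships generators that emulate the experiments: a compositionally
biased randomized library sampled from an order-5 chain, affinity selection
by a planted palindromic dimeric site (resampling ∝ exp(−β·E) with a
log-odds mismatch energy), thermodynamic-occupancy reporter expression
(`expression = v_const·(1−θ)`, θ = R_eff/(R_eff+Kd),
R_eff = aTF/(1+L/K_ligand)) with lognormal noise, and labeled
inducible/uninducible operator sets differing in core-motif position and
flanking bases.

## Worked example

Simulate a small selection, recover the planted operator motif, and fit a
dose response:

```r
library(operatr)

cfg <- selection_sim_config(reads_per_round = 5000, library_size = 200000,
                            seed = 42)
sel <- simulate_selection(config = cfg)
model <- train_markov(sel$library)
reads <- sel$rounds[[5]]
et <- enrichment_table(count_patterns(reads), model, length(reads),
                       region_lengths = nchar(reads),
                       convention = "per-read-any-offset")
head(as.data.frame(et), 3)
#>       pattern l m n observed  expected enrichment
#> 1  TAATATATTA 5 0 5     5000 18.004931   277.7017
#> 2 TAATAxATTAC 5 1 5      228  1.391395   163.8643
#> 3 CTAATxTATTA 5 1 5      214  1.376727   155.4411
```

Every final-round read contains the planted palindrome TAATA·TATTA, which
tops the table at 278-fold enrichment over the Markov background; the
runners-up are its one-position extensions. Seeding a PWM from
single-mismatch enrichments recovers the site at ~2 bits per position:

```r
seed_row <- select_seed(et)
pwm <- build_pwm(mismatch_enrichments(seed_row$pattern, count_patterns(reads),
                                      model, length(reads), nchar(reads),
                                      "per-read-any-offset"))
pwm
#> PWM of width 10, consensus TAATATATTA
#>   seeded from TAATATATTA
round(pwm_info_content(pwm), 2)
#>  [1] 2 2 2 2 2 2 2 1.9 2 2
```

A dose response for one operator clone (Kd = 20 nM, three replicate wells
per concentration, 5% noise):

```r
doses <- c(0, 2, 5, 10, 25, 50, 100, 250, 500, 1000)
rec <- simulate_expression(data.frame(clone_id = "op1", kd = 20), doses,
                           expression_sim_config(noise_cv = 0.05, seed = 7),
                           n_replicates = 3)
rec$norm <- normalize_fluorescence(rec$gfp_raw, rec$od600)
fit_hill(rec$ligand_conc, rec$norm)
#> Hill fit: Vmax 2020, Km 466.3 uM, n 0.901, y0 340.7 (SSE 4.459e+04)
induction_summary(rec)$fold_induction
#> [1] 4.9
```

The clone is repressed ~6-fold at baseline and induces 4.9-fold at the top
dose, with half-maximal response near 470 µM — the graded (n < 1) response
expected from simple occupancy without cooperativity.

## Analysis workflow

The numbered scripts under `analysis/` run the full pipeline on generated
data, writing tables under `results/`:

1. `01_simulate_selection.R` — library + five selection rounds, barcoded
   FASTQ per round.
2. `02_enrichment_motifs.R` — demultiplexing, Markov background, enrichment
   table, seeded PWM (MEME + TSV).
3. `03_cluster_rank.R` — coverage filter, 90%-identity clustering,
   exponential rank-size fit, no-selection control.
4. `04_induction_hill.R` — fold induction and Hill fits across an operator
   affinity series; occupancy-model checks.
5. `05_sequence_model.R` — one-hot encoding, SVR cross-validation, holdout,
   speedometer coordinates.
6. `06_feature_importance.R` — bootstrap annealing selection, importance
   scores, class PWMs.

Run them in order: `Rscript analysis/01_simulate_selection.R` etc.
(01–03 chain through files; 04–06 are self-contained).

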
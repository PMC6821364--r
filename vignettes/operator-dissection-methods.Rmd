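---
title: "Methods: dissecting ligand-inducible promoters from selection and expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting ligand-inducible promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operatr)
```

This vignette documents the models behind `operatr`, the parameters that
matter, the design choices that were genuinely open, and what the
synthetic-data generators do and do not capture about real experiments.

## The system

A constitutive bacterial promoter is made ligand-inducible by embedding an
operator — the site of an allosteric transcription factor (aTF), here a
dimeric efflux-pump repressor — between its −35 and −10 elements. The aTF
occludes RNA polymerase until its ligand lowers the aTF's effective DNA
affinity. Two experimental arms feed the analysis: deep sequencing of an
in vitro selection that enriches operator variants from randomized 16–19 bp
libraries, and per-clone fluorescence measurements (uninduced, induced, and
full dose series) of promoters carrying selected operators.

## Gapped k-mer enrichment

Operators of these dimers are two short half-sites separated by a spacer,
so the pattern class counted is an $l$-mer, $m$ wildcard positions, and an
$n$-mer, with $l, n \in \{4, 5\}$ and $m$ from 0 to $N - l - n$ for region
length $N$. A pattern is counted at most once per read; patterns observed
in fewer than `count_threshold = 50` reads are dropped. The choice of a
*per-read first-occurrence* count (rather than total occurrences) makes the
observed statistic a binomial count, which is what the expected-count
conventions below target.

Expected counts come from a fifth-order Markov model trained on the
unselected library: conditional probabilities $P(b \mid 5\text{-mer})$ are
smoothed maximum-likelihood estimates (pseudocount 1 per context–base
cell), and the initial 5-mer distribution is estimated from *every* read
offset, since a pattern can sit anywhere in the region. A pattern's
probability is the product of its initial 5-mer probability and one
conditional per later character, with wildcard characters contributing a
factor of exactly 1. When wildcards fall *inside* a conditioning context,
the conditional is computed by marginalizing the trained counts over the
wildcard slots, weighted by how often each concrete context occurs in the
corpus. This estimator makes the marginalization identity exact: summing
pattern probabilities over all completions of a template recovers the
wildcard template's probability (a property test in the suite).

Two expected-count conventions are implemented. The *single-position*
convention multiplies the pattern probability by the total read count and
is the default, being the plainest reading of "probability × total reads".
The *per-read-any-offset* convention returns
$\sum_L n_L\,[1 - (1-p)^{L - k + 1}]$, the expected number of reads
containing the pattern at one or more offsets — the quantity the per-read
counting rule actually estimates. Whenever enrichment values are compared
against an absolute scale (the β = 0 calibration band, or ranking patterns
of different spans), the per-read convention is the right one: the
single-position convention understates expected counts by roughly the
offset count, which differs across spans and would tilt rankings toward
long patterns. The analyses and acceptance checks therefore use
`convention = "per-read-any-offset"` while leaving the literal convention
available.

## Seeded PWM construction

The most enriched pattern is the seed (ties break to the higher observed
count, then lexicographic). For every non-wildcard position and base, the
single-mismatch variant's enrichment is computed identically; variants
failing the 50-count filter contribute 0, consistent with the
filter-before-analysis pipeline order. Columns are the per-position
enrichment vectors normalized to sum 1 — the simplest defensible reading of
"weighting each position by enrichment"; a log2-enrichment alternative sits
behind `scheme = "log"`. Wildcard (spacer) positions are emitted uniform
and flagged so renderers can grey them. Information content is
$2 + \sum_b p_b \log_2 p_b$ bits.

## Cluster rank-size analysis

Unique sequences passing `min_coverage = 10` are clustered greedily: sorted
by count then length (descending), each sequence joins the first cluster
whose *representative* it matches at ≥ 90% identity, else founds a cluster.
Identity between 16–19 bp sequences is best-ungapped-offset matches divided
by the longer length (conservative). Clusters with fewer than 5 members'
worth of reads are dropped and the rest sorted by size. This is the
documented greedy strategy of CD-HIT without its short-word prefilter,
which is unnecessary at these input sizes. The descending size curve is fit
as $\log(\text{size}) = \log a - b\,\text{rank}$ by least squares; an
enriched pool gives a clean exponential (high $R^2$, $b > 0$), while a
neutral pool at this depth leaves nothing past the coverage filter at all —
the no-selection control in `analysis/03_cluster_rank.R`.

## Induction and Hill fits

Normalized fluorescence is $(F - F_\text{blank})/(OD - OD_\text{blank})$.
Fold induction is the ratio of induced to uninduced normalized
fluorescence; for cell populations, medians are taken first. Dose
responses are fit to $y = y_0 + V_\max L^n/(K_m^n + L^n)$:

* $y_0$ (basal activity) is a free parameter by default because repressed
  baselines are visibly nonzero; `fix_y0` pins it for background-subtracted
  data.
* Multi-start initialization over a log-spaced $K_m$ grid spanning the
  measured concentrations and $n \in \{0.5, 1, 2, 4\}$, with bounds
  $n \in (0, 10]$, $K_m, V_\max > 0$, $y_0 \ge 0$; the best
  sum-of-squares fit wins and non-convergence from all starts is reported
  as `converged = FALSE` rather than silently patched. This replaces the
  manual inspection of fitted curves that a bench workflow would use.
* For low-$K_d$ (high-affinity) operators the response barely turns on over
  a finite dose range, so the fitted plateau $y_0 + V_\max$ is an
  extrapolation with little data support. Comparisons across an affinity
  series therefore use the fitted activity *at the maximal measured dose*,
  which is identified for every clone.

The occupancy logic being tested: expression $= v\,(1-\theta)$ with
$\theta = R_\text{eff}/(R_\text{eff} + K_d)$ and
$R_\text{eff} = [\text{aTF}]/(1 + L/K_\text{ligand})$, so higher-affinity
operators (small $K_d$) repress deeper and retain more residual repression
at full induction — lower induced maxima. Hill-shaped dose curves emerge
from this single-operator occlusion model without any explicit
cooperativity term.

## Sequence–function model

Gap-filled operator sequences (externally aligned; a pad-to-length fallback
exists only for equal-structure synthetic sets) are one-hot encoded in the
fixed character order A, T, G, C, "−", five indicators per position. A 10%
holdout is split off once; the remainder is 5-fold cross-validated. The
RBF-kernel SVR's hyperparameters (cost, kernel width γ, tube ε) are chosen
by inner cross-validation over a log-spaced 5 × 5 × 3 grid inside each
training split, so every out-of-fold prediction comes from a model that
never saw that sequence (a leakage test corrupts one target and asserts the
point's own fold is unchanged). Spearman correlation is the headline
metric; Pearson is reported alongside. Fold-induction targets are used
untransformed by default with a `log_target` flag.

One structural note on the Spearman ceiling: with balanced classes whose
uninducible half has fold induction ≈ 1 and purely stochastic ordering, the
class separation alone contributes ρ ≈ 0.75 and perfect within-inducible
ordering raises it to ≈ 0.94; out-of-fold values in the high 0.8s indicate
the model captures most of the learnable within-class gradient.

## Feature importance

For each of 100 bootstrap resamples, a simulated annealing runs over binary
feature masks (single-feature flips, Metropolis acceptance, geometric
cooling $T_t = T_0\,\alpha^t$), scoring each mask by the cross-validated
error of a regression restricted to the masked features; the best-ever mask
is kept. The bagged frequency of feature $(i, j)$ is the fraction of
resamples selecting it, and
$\text{score}_{i,j,k} = \text{bagged}_{i,j} \times \text{observed}_{i,j,k}$
for class $k$; "internally normalized" is interpreted as sum-to-one per
(position, class), giving class PWMs over {A, T, G, C, −}.

Two schedule decisions were open:

* *Objective model.* Scoring masks with the full SVR is quadratic cost —
  at 100 bootstraps × hundreds of flips × CV folds it is ~25× the
  runtime budget of the recovery analyses. The default objective is a
  closed-form ridge regression CV error: a fast linear surrogate whose
  additive structure matches one-hot encoding, used only to *select*
  features (the final predictive model remains the SVR). The SVR objective
  is available via `model = "svr"`.
* *Schedule.* $T_0 = 1$, $\alpha = 0.9$, 60 flips per bootstrap by default
  in the bagging loop (500 flips for standalone selection). Starting from
  the all-features mask, 60 flips prune only a minority of features, so
  bagged frequencies stay high overall; the *differential* importance
  between classes is driven by the observed-frequency contrast and is what
  the recovery analyses assess.

A label-permutation test confirms the differential signal vanishes when
class labels are shuffled.

## What the generators emulate — and what they do not

* **Library bias.** The naive library is an order-5 chain; the default is a
  strong A/T skew (A = T = 0.46, C = G = 0.04). The skew is deliberately
  extreme: at 10^5-read sampling depth, the ≥ 50-count filter retains *no*
  gapped k-mers from a mildly biased library (expected counts of 8-plus
  specified positions all sit far below 50), so the calibration property —
  most retained patterns should show enrichment ≈ 1 under no selection —
  is only non-vacuous when the bias concentrates probability on a reduced
  alphabet. This mirrors the real situation in which background
  normalization matters most. Poisson noise at threshold-adjacent counts
  puts an intrinsic ceiling (~96%) on the fraction inside a ±25%
  enrichment band.
* **Planted motif.** A 10 bp palindrome TAATA·TATTA of two abutting 5 bp
  half-sites, consensus probability 0.7 per column. Keeping every motif
  position under selection (no internal spacer) is what makes the planted
  site identifiable at desk scale: free spacer positions inside the
  pattern span act as clone-specific fingerprints that can out-enrich the
  core when the selected pool contains only thousands of distinct clones.
  Wider spacers are fully supported by the motif type and behave
  identically up to those unconstrained positions.
* **Selection.** Resampling ∝ exp(−β·E) with E the best-window log-odds
  mismatch energy (0 at consensus). Anchoring the energy at the consensus
  makes the weight saturate at 1, so all perfect sites stay equivalent and
  the pool keeps its clone diversity; an unanchored energy makes repeated
  exponential reweighting collapse onto the single best random read.
  Amplification is multinomial (no per-cycle PCR jackpots). The naive
  library defaults to 160× the per-round read count so the pool holds
  ~10^4 perfect clones, each below the count filter.
* **Expression.** Single-operator occlusion with lognormal multiplicative
  noise (CV 5% by default — replicate-averaged plate measurements); no
  RNAP competition term, no growth feedback, no FACS optics. Bimodal
  repressed populations seen by cytometry are not emulated (the
  fold-induction medians machinery handles mixtures regardless, tested
  against an analytic mixture-median oracle).
* **Labeled operator sets.** Both classes carry the same TACA core, at
  positions 1–4 (inducible) versus 3–6 (uninducible), with class-specific
  base preferences at flanking positions 7, 13 and 14; inducible fold
  induction (mean 20) is modulated multiplicatively by the flank bases,
  uninducible sits at ~1.05. This plants both signals the importance
  analysis is meant to find — a core-position shift and flank preferences —
  and a within-class gradient the regression can learn. Real operator sets
  are not balanced, not gap-free, and their functional determinants
  include interactions beyond single positions; passing on this generator
  shows the machinery recovers planted single-position structure, not that
  real inducibility is single-position.

## Problem sizes

The simulation scales used by the test suite and `scripts/acceptance.R`:
selection at 5 rounds × 50,000 reads/round from an 8 × 10^6-read library
(Markov model trained on a 10^6-read sample); null calibration at one β = 0
round of 10^5 reads from a 4 × 10^6-read library; Hill recovery over 100
replicate simulations of 8 concentrations × 3 replicates; affinity series
of 12 operators spanning Kd 1–100 nM against an aTF level of 100 nM;
sequence models on 200 labeled operators; importance recovery over 10 outer
seeds × 100 bootstraps.

## Known limitations

* Forward-strand counting only by default; the selected motifs are
  palindromic, making reverse-complement collapsing nearly a no-op.
* The greedy clustering is order-dependent by construction (as is CD-HIT);
  determinism is guaranteed by the documented sort.
* Enrichment of heavily self-overlapping patterns (homopolymer-like) is
  computed under offset independence; clumping makes their per-read match
  probability slightly lower than the independence formula.
* The expected-count model assumes the background chain is homogeneous
  along the read; position-specific synthesis bias would require a
  per-offset model.
* Importance scores are associations between planted features and fold
  induction under a linear-surrogate selection; they are not causal claims
  about binding energetics.
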
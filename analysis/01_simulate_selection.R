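#!/usr/bin/env Rscript

## In vitro selection, in silico: draw a compositionally biased randomized
## operator library (16-19 bp, equimolar), run five rounds of affinity
## selection by a dimeric repressor with a planted palindromic site, and
## write the sequenced rounds as barcoded FASTQ plus a deep sample of the
## naive library for background-model training.

suppressPackageStartupMessages(library(operatr))
dir.create("results/selection", recursive = TRUE, showWarnings = FALSE)

cfg <- selection_sim_config(seed = 20260928)
cat("Planted motif:\n")
print(cfg$true_motif)
cat(sprintf("Library: %s reads (16-19 bp, A/T-skewed); %d rounds x %s reads\n",
            format(cfg$library_size, big.mark = ","), cfg$rounds,
            format(cfg$reads_per_round, big.mark = ",")))

sel <- simulate_selection(config = cfg)

core <- motif_consensus_pattern(cfg$true_motif)
f0 <- mean(grepl(core, sel$library))
cat(sprintf("Planted core frequency: %.2e in the naive library\n", f0))
for (r in seq_along(sel$rounds)) {
  cat(sprintf("  round %d: %.4f (%.0fx)\n", r,
              mean(grepl(core, sel$rounds[[r]])),
              mean(grepl(core, sel$rounds[[r]])) / f0))
}

## rounds as FASTQ, tagged with one 8 bp barcode per round so the
## demultiplexing step of the pipeline is exercised downstream
barcodes <- c("ACGTACGT", "TGCATGCA", "GGAATTCC", "CCTTGGAA", "AATTGGCC")
for (r in seq_along(sel$rounds)) {
  write_fastq(paste0(barcodes[r], sel$rounds[[r]]),
              sprintf("results/selection/round%d.fastq", r),
              ids = sprintf("r%d_read%d", r, seq_along(sel$rounds[[r]])))
}
writeLines(paste(barcodes, paste0("round", seq_along(sel$rounds)), sep = "\t"),
           "results/selection/barcodes.tsv")

## a 1e6-read sample of the naive library for Markov training
set.seed(1)
lib_sample <- sample(sel$library, 1e6)
writeLines(paste0(">lib", seq_along(lib_sample), "\n", lib_sample),
           "results/selection/library_sample.fasta")
cat("Wrote results/selection/round*.fastq, barcodes.tsv, library_sample.fasta\n")
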
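#!/usr/bin/env Rscript

## Gapped k-mer enrichment and motif discovery. Demultiplexes the sequenced
## selection rounds by their 8 bp barcodes, trains the fifth-order Markov
## background on the naive-library sample, computes observed/expected
## enrichment for every gapped k-mer passing the 50-count filter in the
## final round, and builds a PWM from the single-mismatch enrichments of
## the top-enriched seed.

suppressPackageStartupMessages({
  library(operatr)
  library(data.table)
})
dir.create("results/motifs", recursive = TRUE, showWarnings = FALSE)

bc <- fread("results/selection/barcodes.tsv", header = FALSE)
barcode_map <- setNames(bc$V2, bc$V1)

final_fastq <- "results/selection/round5.fastq"
dm <- demultiplex(final_fastq, barcode_map, region_span = c(9L, NA))
cat(sprintf("Demultiplexed %s reads: %s assigned to round5, %d discarded\n",
            format(dm$n_input, big.mark = ","),
            format(dm$tally[["round5"]], big.mark = ","), dm$discarded))
reads <- dm$samples$round5

lib_lines <- readLines("results/selection/library_sample.fasta")
lib <- lib_lines[!startsWith(lib_lines, ">")]
cat(sprintf("Training order-5 Markov background on %s library reads\n",
            format(length(lib), big.mark = ",")))
model <- train_markov(lib)

counts <- count_patterns(reads)                        # >= 50 reads each
et <- enrichment_table(counts, model, length(reads),
                       region_lengths = nchar(reads),
                       convention = "per-read-any-offset")
fwrite(et, "results/motifs/enrichment_table.tsv", sep = "\t")
cat(sprintf("%s gapped k-mers pass the count filter; top of the table:\n",
            format(nrow(et), big.mark = ",")))
print(head(as.data.frame(et), 5))

seed_row <- select_seed(et)
cat(sprintf("Seed pattern: %s (enrichment %.0f)\n",
            seed_row$pattern, seed_row$enrichment))

me <- mismatch_enrichments(seed_row$pattern, counts, model, length(reads),
                           nchar(reads), "per-read-any-offset")
pwm <- build_pwm(me)
print(pwm)
write_motif(pwm, "results/motifs/operator_motif.meme", dialect = "meme",
            name = seed_row$pattern)
write_motif(pwm, "results/motifs/operator_motif.tsv", dialect = "tab")
ic <- data.frame(position = seq_along(pwm$wildcard),
                 wildcard = pwm$wildcard,
                 info_bits = pwm_info_content(pwm))
fwrite(ic, "results/motifs/information_content.tsv", sep = "\t")
cat(sprintf("Total information content: %.1f bits over %d positions\n",
            sum(ic$info_bits), nrow(ic)))
cat("Wrote results/motifs/{enrichment_table.tsv,operator_motif.meme,operator_motif.tsv,information_content.tsv}\n")
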
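#!/usr/bin/env Rscript

## Sequence-function regression. Generates labeled inducible/uninducible
## operator sets with a planted core-position shift and flank preferences,
## one-hot encodes the gap-free sequences, and trains an RBF-kernel support
## vector regression for fold induction under 5-fold cross-validation with
## a 10% holdout; also writes the speedometer (edit distance vs fold
## induction) coordinates describing the dataset's diversity.

suppressPackageStartupMessages(library(operatr))
dir.create("results/model", recursive = TRUE, showWarnings = FALSE)

ops <- generate_labeled_operator_sets(n_per_class = 100, seed = 555)
write_aligned_fasta(setNames(ops$sequence, ops$id), "results/model/operators.fasta")
write.csv(ops[, c("id", "class", "fold_induction")],
          "results/model/fold_induction.csv", row.names = FALSE)

sp <- speedometer_coordinates(ops$sequence, ops$fold_induction)
write.csv(cbind(id = ops$id, sp[, c("radial", "angular")]),
          "results/model/speedometer.csv", row.names = FALSE)
cat(sprintf("Sequence diversity: edit distances to the top inducer span %d-%d\n",
            min(sp$radial), max(sp$radial)))

X <- one_hot_encode(ops$sequence)
split <- make_split(nrow(X), folds = 5L, holdout_frac = 0.1, seed = 555)
fit <- train_svr(X, ops$fold_induction, split, seed = 555)
print(fit)

pred <- data.frame(id = ops$id, observed = ops$fold_induction,
                   oof_predicted = fit$oof)
pred$holdout_predicted <- NA_real_
pred$holdout_predicted[fit$holdout_idx] <- fit$holdout_pred
write.csv(pred, "results/model/predictions.csv", row.names = FALSE)
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(fit$metrics, "results/model/metrics.json",
                       auto_unbox = TRUE, digits = NA)
}
cat("Wrote results/model/{operators.fasta,fold_induction.csv,speedometer.csv,predictions.csv,metrics.json}\n")
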
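Package: operatr
Title: Dissecting Ligand-Inducible Promoters from In Vitro Selection and
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for engineering bacterial promoters whose
    activity is controlled by an allosteric transcription factor (aTF) bound
    to an operator site between the -35 and -10 promoter elements. Implements
    gapped k-mer counting with fifth-order Markov background normalization to
    discover operator motifs from in vitro selection (SELEX) reads, seeded
    position weight matrix construction from single-mismatch enrichments,
    greedy identity clustering with rank-size analysis of selected pools,
    normalized-fluorescence fold-induction summaries and Hill dose-response
    fitting, support vector regression linking operator sequence to fold
    induction, and bootstrap simulated-annealing feature importance
    contrasting inducible with uninducible operators. A synthetic-data
    generator reproduces the statistical structure of the selection and
    expression experiments so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    e1071,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
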
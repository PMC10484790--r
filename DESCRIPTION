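Package: plmvep
Title: Protein Language Model Variant Effect Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores coding variants with per-position amino-acid
    log-probabilities from a protein language model backend. Computes
    log-likelihood-ratio (LLR) matrices for all missense substitutions,
    handles proteins longer than the model's input limit by tiling them
    into overlapping windows combined with sigmoid edge weights, scores
    in-frame insertions, deletions and delins variants by
    pseudo-log-likelihood ratios (PLLR), scores stop-gain variants by the
    minimum LLR over the lost region, applies the 50-bp rule for
    nonsense-mediated decay, detects isoform-sensitive variants, and
    decomposes score distributions of variants of uncertain significance
    into benign and pathogenic fractions with Gaussian mixtures. Includes
    the full benchmark statistics suite (global and gene-average ROC-AUC,
    balanced PRC-AUC, permutation tests, bootstrap uncertainty, deep
    mutational scanning correlations, alignment baselines) and a
    deterministic synthetic backend plus fixture generators so the entire
    pipeline runs without model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
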
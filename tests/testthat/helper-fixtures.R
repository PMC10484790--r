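# shared fixture builders; all randomness is locally seeded so tests are
# order-independent

random_protein_seq <- function(id, L, seed) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed(protein_sequence(
    id, paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")))
}

# brute-force Mann-Whitney AUC by pair enumeration (independent oracle)
pairwise_auc <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p < q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# independent window extraction (no backend domains in play, so the id
# does not influence scores)
subseq_protein_oracle <- function(seq, a, b) {
  protein_sequence(paste0(seq$id, "_oracle"), substr(seq$residues, a, b))
}

# construct an isoform_profile directly from a score vector
profile_from_scores <- function(scores) {
  m <- mean(scores)
  structure(list(scores = scores, min_score = min(scores),
                 max_score = max(scores),
                 sd = sqrt(mean((scores - m)^2)),
                 n_isoforms = length(scores)),
            class = "isoform_profile")
}
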
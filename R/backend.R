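# Deterministic synthetic scorer backend.
#
# The backend contract: given a protein sequence, return an L x 20 matrix of
# per-position log-probabilities over the canonical amino-acid alphabet,
# conditioned on the whole input sequence. The synthetic backend emulates a
# protein language model with a seeded integer-hash scheme: logits are a
# deterministic function of (seed, full-sequence digest, local 7-mer context,
# position, amino acid), plus a probability bonus for the wild-type residue
# that is strongly elevated inside planted low-tolerance "domain" intervals.
# This gives context-sensitive, bitwise-reproducible scores with domain-like
# LLR structure, at zero model cost.

.HASH_M <- 67108864  # 2^26; all hash state stays < 2^26 so double arithmetic is exact

hash_mix <- function(v) {
  v <- (v * 8121 + 28411) %% .HASH_M
  (v * 4969 + 21031) %% .HASH_M
}

# polynomial digest of the full residue string (context carrier)
seq_digest <- function(codes) {
  h <- 7
  for (cd in codes) h <- (h * 131 + cd) %% .HASH_M
  h
}

# rolling 7-mer context hash per position, zero-padded at the ends
local_context_hash <- function(codes) {
  L <- length(codes)
  acc <- numeric(L)
  pw <- 1
  for (o in -3:3) {
    shifted <- numeric(L)
    src <- seq_len(L) + o
    ok <- src >= 1L & src <= L
    shifted[ok] <- codes[src[ok]]
    acc <- (acc + shifted * pw) %% .HASH_M
    pw <- (pw * 53) %% .HASH_M
  }
  acc
}

#' Create a deterministic synthetic scoring backend
#'
#' Builds a backend whose per-position amino-acid log-probabilities are a
#' deterministic function of the seed, the full input sequence, the local
#' sequence context and the queried amino acid. Inside planted domain
#' intervals the wild-type residue receives strongly elevated probability
#' mass, so non-wild-type substitutions there obtain strongly negative LLR
#' scores; outside domains the distribution is much flatter.
#'
#' @param seed Integer seed; together with the input sequence it fully
#'   determines the output.
#' @param domain_spec Optional `data.frame` with columns `start`, `end`,
#'   `tolerance` and optionally `seq_id`, planting low-mutation-tolerance
#'   intervals (1-based inclusive residue coordinates). `tolerance` is the
#'   approximate total probability mass left for non-wild-type residues
#'   (e.g. `0.001` makes substitutions score around -10 LLR). Rows without a
#'   `seq_id` apply to every sequence. Intervals for one sequence must be
#'   ordered and non-overlapping.
#' @param max_input_length Longest sequence the backend accepts (default
#'   1022, the published transformer limit). `Inf` is allowed for test-oracle
#'   use.
#' @param noise_scale Amplitude of the local-context logit noise.
#' @param global_weight Amplitude of the whole-sequence logit component; any
#'   change anywhere in the sequence perturbs every position through this
#'   term.
#' @param wt_bonus Baseline logit bonus for the wild-type residue outside
#'   domains (keeps benign-like LLRs mildly negative).
#' @return An object of class `plm_backend` (kind `"synthetic"`).
#' @examples
#' be <- synthetic_backend(seed = 7)
#' lp <- score_sequence(be, protein_sequence("p", "MKTAYIAKQR"))
#' dim(lp)  # 10 x 20
#' @export
synthetic_backend <- function(seed, domain_spec = NULL,
                              max_input_length = 1022L,
                              noise_scale = 1.5, global_weight = 0.02,
                              wt_bonus = 1.0) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            seed == round(seed))
  if (!(is.numeric(max_input_length) && length(max_input_length) == 1L &&
        (is.infinite(max_input_length) || max_input_length >= 2))) {
    stop("max_input_length must be >= 2", call. = FALSE)
  }
  if (!is.null(domain_spec)) domain_spec <- validate_domain_spec(domain_spec)
  structure(
    list(kind = "synthetic", seed = seed %% .HASH_M,
         domain_spec = domain_spec,
         max_input_length = max_input_length,
         noise_scale = noise_scale, global_weight = global_weight,
         wt_bonus = wt_bonus),
    class = "plm_backend"
  )
}

validate_domain_spec <- function(domain_spec) {
  stopifnot(is.data.frame(domain_spec))
  req <- c("start", "end", "tolerance")
  if (!all(req %in% names(domain_spec))) {
    stop("domain_spec needs columns start, end, tolerance", call. = FALSE)
  }
  if (!"seq_id" %in% names(domain_spec)) domain_spec$seq_id <- NA_character_
  if (any(domain_spec$start > domain_spec$end) || any(domain_spec$start < 1)) {
    stop("domain intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  if (any(domain_spec$tolerance <= 0 | domain_spec$tolerance >= 0.5)) {
    stop("domain tolerance must lie in (0, 0.5)", call. = FALSE)
  }
  key <- ifelse(is.na(domain_spec$seq_id), "", domain_spec$seq_id)
  for (sid in unique(key)) {
    rows <- domain_spec[key == sid, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) > 1L &&
        any(rows$start[-1L] <= rows$end[-nrow(rows)])) {
      stop("overlapping or out-of-order domain intervals", call. = FALSE)
    }
  }
  domain_spec
}

#' @export
print.plm_backend <- function(x, ...) {
  cat(sprintf("<plm_backend> kind=%s seed=%s max_input_length=%s\n",
              x$kind, format(x$seed), format(x$max_input_length)))
  if (!is.null(x$domain_spec)) {
    cat("  planted domains:", nrow(x$domain_spec), "\n")
  }
  invisible(x)
}

#' Score a protein sequence with a backend
#'
#' Returns one row of log-probabilities over the 20 canonical amino acids per
#' residue, conditioned on the entire input sequence. Rows are
#' log-normalized (each row's log-sum-exp is 0). Scoring is deterministic:
#' identical (backend, sequence) pairs give bitwise-identical matrices.
#'
#' @param backend A `plm_backend`.
#' @param seq A [protein_sequence()].
#' @return An `L x 20` matrix of class `position_logprobs` with attributes
#'   `sequence_id` and `residues`; columns are ordered by [aa_alphabet()].
#' @export
score_sequence <- function(backend, seq) {
  UseMethod("score_sequence")
}

#' @export
score_sequence.plm_backend <- function(backend, seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (backend$kind != "synthetic") {
    stop("backend kind '", backend$kind, "' has no scorer registered",
         call. = FALSE)
  }
  L <- seq$length
  if (L > backend$max_input_length) {
    stop("sequence '", seq$id, "' has length ", L,
         " > backend max_input_length ", backend$max_input_length,
         "; tile it into overlapping windows (see tile_sequence)",
         call. = FALSE)
  }
  codes <- aa_codes(seq)
  dg <- seq_digest(codes)
  lk <- local_context_hash(codes)
  pos <- seq_len(L)
  seedterm <- (backend$seed * 104729) %% .HASH_M

  logits <- matrix(0, nrow = L, ncol = 20L,
                   dimnames = list(NULL, .AA))
  # the strong "local" component depends on k-mer content only (not the
  # absolute position), so an indel leaves downstream per-position
  # probabilities almost unchanged — like a content-conditioned model, and
  # necessary for PLLR scores to reflect the indel rather than a global
  # re-randomization; the weak "global" component ties every row to the
  # full sequence and the position
  for (j in 1:20) {
    ul <- hash_mix((lk * 2963 + j * 7919 + seedterm) %% .HASH_M) / .HASH_M
    ug <- hash_mix((dg * 3299 + pos * 977 + j * 7919 + seedterm + 12345) %%
                     .HASH_M) / .HASH_M
    logits[, j] <- backend$noise_scale * (2 * ul - 1) +
      backend$global_weight * (2 * ug - 1)
  }

  bonus <- rep(backend$wt_bonus, L)
  ds <- backend$domain_spec
  if (!is.null(ds)) {
    ds <- ds[is.na(ds$seq_id) | ds$seq_id == seq$id, , drop = FALSE]
    if (nrow(ds) > 0L && any(ds$end > L)) {
      stop("domain interval exceeds length of sequence '", seq$id, "'",
           call. = FALSE)
    }
    for (k in seq_len(nrow(ds))) {
      t <- ds$tolerance[k]
      bonus[ds$start[k]:ds$end[k]] <- log((1 - t) / t) + log(19)
    }
  }
  logits[cbind(pos, codes)] <- logits[cbind(pos, codes)] + bonus

  # row-wise log-softmax
  rmax <- apply(logits, 1L, max)
  lse <- rmax + log(rowSums(exp(logits - rmax)))
  lp <- logits - lse
  structure(lp, class = c("position_logprobs", "matrix", "array"),
            sequence_id = seq$id, residues = seq$residues)
}
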
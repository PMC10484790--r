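# Missense LLR matrices and stop-gain scoring.

#' Build a missense LLR matrix from per-position log-probabilities
#'
#' The LLR (log-likelihood ratio) of a substitution is the log-probability of
#' the alternate amino acid minus the log-probability of the wild-type amino
#' acid at that position, both conditioned on the wild-type sequence. More
#' negative scores predict more damaging substitutions. Wild-type entries are
#' exactly 0.
#'
#' @param logprobs An `L x 20` `position_logprobs` matrix from
#'   [score_sequence()].
#' @return A `20 x L` matrix of class `llr_matrix` (rows ordered by
#'   [aa_alphabet()], columns are residue positions) with attributes
#'   `protein_id` and `residues`.
#' @export
llr_matrix <- function(logprobs) {
  stopifnot(inherits(logprobs, "position_logprobs"))
  residues <- attr(logprobs, "residues")
  codes <- unname(.AA_IDX[strsplit(residues, "", fixed = TRUE)[[1]]])
  L <- nrow(logprobs)
  wt_lp <- logprobs[cbind(seq_len(L), codes)]
  vals <- t(unclass(logprobs)) - rep(wt_lp, each = 20L)
  new_llr_matrix(vals, attr(logprobs, "sequence_id"), residues)
}

new_llr_matrix <- function(vals, protein_id, residues) {
  dimnames(vals) <- list(.AA, NULL)
  structure(vals, class = c("llr_matrix", "matrix", "array"),
            protein_id = protein_id, residues = residues)
}

#' @export
print.llr_matrix <- function(x, ...) {
  cat(sprintf("<llr_matrix> %s: 20 x %d\n", attr(x, "protein_id"), ncol(x)))
  invisible(x)
}

#' Score a missense variant from an LLR matrix
#'
#' @param matrix An [llr_matrix()].
#' @param position 1-based residue position.
#' @param ref_aa,alt_aa One-letter wild-type and substituted amino acids;
#'   `ref_aa` must match the matrix's sequence at `position`.
#' @return The LLR score (numeric scalar). `alt_aa == ref_aa` returns 0 with
#'   a warning.
#' @export
score_missense <- function(matrix, position, ref_aa, alt_aa) {
  stopifnot(inherits(matrix, "llr_matrix"))
  L <- ncol(matrix)
  if (position < 1 || position > L) {
    stop("position ", position, " outside 1..", L, call. = FALSE)
  }
  observed <- substr(attr(matrix, "residues"), position, position)
  if (observed != ref_aa) {
    stop("reference mismatch at position ", position, ": expected '",
         ref_aa, "', sequence has '", observed, "'", call. = FALSE)
  }
  if (!alt_aa %in% .AA) stop("unknown amino acid '", alt_aa, "'", call. = FALSE)
  if (alt_aa == ref_aa) {
    warning("alt_aa equals ref_aa at position ", position,
            "; LLR is 0 by definition", call. = FALSE)
    return(0)
  }
  unname(matrix[alt_aa, position])
}

#' Score a stop-gain variant
#'
#' A premature stop codon at `stop_position` truncates the protein, losing
#' the region from `stop_position` to the C terminus (inclusive of the
#' substituted residue itself). The effect score is the lowest (most
#' damaging) missense LLR among all possible substitutions in the lost
#' region; wild-type self-entries (which are 0 and not substitutions) are
#' excluded.
#'
#' @param matrix An [llr_matrix()].
#' @param stop_position 1-based position of the residue replaced by the stop
#'   codon.
#' @return The minimum LLR over the lost region (numeric scalar).
#' @export
score_stop_gain <- function(matrix, stop_position) {
  stopifnot(inherits(matrix, "llr_matrix"))
  L <- ncol(matrix)
  if (stop_position < 1 || stop_position > L) {
    stop("stop_position ", stop_position, " outside 1..", L, call. = FALSE)
  }
  cols <- stop_position:L
  sub <- unclass(matrix)[, cols, drop = FALSE]
  codes <- unname(.AA_IDX[strsplit(attr(matrix, "residues"), "",
                                   fixed = TRUE)[[1]]])[cols]
  sub[cbind(codes, seq_along(cols))] <- NA_real_  # mask WT self-entries
  min(sub, na.rm = TRUE)
}

#' Residues lost to a stop-gain variant
#'
#' Baseline severity measures for a premature stop: the count of lost
#' residues (from the substituted position, inclusive, to the C terminus)
#' and the lost fraction of the wild-type length.
#'
#' @param stop_position 1-based stop position.
#' @param L Wild-type protein length.
#' @return List with `count` and `fraction`.
#' @export
residues_lost <- function(stop_position, L) {
  stopifnot(stop_position >= 1, stop_position <= L)
  count <- L - stop_position + 1L
  list(count = count, fraction = count / L)
}

#' Build a minimal transcript model for the NMD rule
#'
#' Exons are given in transcript order (5' to 3', already strand-resolved)
#' by their lengths in nucleotides; CDS start/end are 1-based transcript
#' coordinates.
#'
#' @param transcript_id Identifier.
#' @param exon_lengths Integer vector of exon lengths (nt), 5' to 3'.
#' @param cds_start,cds_end CDS bounds in transcript coordinates.
#' @return Object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, exon_lengths, cds_start, cds_end) {
  stopifnot(length(exon_lengths) >= 1L, all(exon_lengths >= 1))
  total <- sum(exon_lengths)
  if (!(cds_start >= 1 && cds_start <= cds_end && cds_end <= total)) {
    stop("CDS bounds outside transcript extent", call. = FALSE)
  }
  structure(
    list(transcript_id = transcript_id,
         exon_lengths = as.integer(exon_lengths),
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)),
    class = "transcript_model"
  )
}

#' Predict nonsense-mediated decay with the 50-bp rule
#'
#' A transcript carrying a premature stop codon is expected to undergo NMD
#' iff the stop codon lies more than 50 nt upstream of the last exon-exon
#' junction within its coding region. A single-exon CDS has no such junction
#' and is never predicted to undergo NMD.
#'
#' @param transcript A [transcript_model()].
#' @param stop_cds_position_nt 1-based position of the first nucleotide of
#'   the stop codon in CDS coordinates.
#' @return `TRUE` if NMD is expected, otherwise `FALSE`.
#' @export
predict_nmd <- function(transcript, stop_cds_position_nt) {
  stopifnot(inherits(transcript, "transcript_model"))
  cds_len <- transcript$cds_end - transcript$cds_start + 1L
  if (stop_cds_position_nt < 1 || stop_cds_position_nt > cds_len) {
    stop("stop position outside the CDS", call. = FALSE)
  }
  # junction j sits after the last nt of exon j (transcript coordinate)
  junctions <- cumsum(transcript$exon_lengths)
  junctions <- junctions[-length(junctions)]
  coding <- junctions[junctions >= transcript$cds_start &
                        junctions < transcript$cds_end]
  if (length(coding) == 0L) return(FALSE)
  stop_tx <- transcript$cds_start + stop_cds_position_nt - 1L
  (max(coding) - stop_tx) > 50L
}
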
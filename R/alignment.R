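# Sequence-similarity baselines for indel effect scores. All three share
# the premise that the more dissimilar the wild-type and mutated sequences,
# the more damaging the indel.

#' Levenshtein edit distance between two sequences
#'
#' Minimal number of single-character insertions, deletions or
#' substitutions transforming `wt` into `mut`, by the standard dynamic
#' program.
#'
#' @param wt,mut Non-empty character scalars.
#' @return Integer edit distance.
#' @export
levenshtein <- function(wt, mut) {
  stopifnot(nzchar(wt), nzchar(mut))
  a <- strsplit(wt, "", fixed = TRUE)[[1]]
  b <- strsplit(mut, "", fixed = TRUE)[[1]]
  prev <- 0:length(b)
  for (i in seq_along(a)) {
    cur <- numeric(length(b) + 1L)
    cur[1] <- i
    sub_cost <- prev[-length(prev)] + (a[i] != b)
    del_cost <- prev[-1] + 1
    for (j in seq_along(b)) {
      cur[j + 1L] <- min(sub_cost[j], del_cost[j], cur[j] + 1)
    }
    prev <- cur
  }
  as.integer(prev[length(prev)])
}

#' Global alignment score with flat match/mismatch scoring
#'
#' Needleman-Wunsch global alignment with match score 2, mismatch score -1
#' and a linear gap penalty (default -1 per gapped residue).
#'
#' @param wt,mut Non-empty amino-acid strings.
#' @param match,mismatch Substitution scores.
#' @param gap Penalty per gapped residue (positive number; subtracted).
#' @return Optimal global alignment score.
#' @export
simple_alignment_score <- function(wt, mut, match = 2, mismatch = -1,
                                   gap = 1) {
  stopifnot(nzchar(wt), nzchar(mut))
  letters_used <- unique(strsplit(paste0(wt, mut), "", fixed = TRUE)[[1]])
  sub <- matrix(mismatch, length(letters_used), length(letters_used),
                dimnames = list(letters_used, letters_used))
  diag(sub) <- match
  pa <- Biostrings::pairwiseAlignment(wt, mut, type = "global",
                                      substitutionMatrix = sub,
                                      gapOpening = 0, gapExtension = gap,
                                      scoreOnly = TRUE)
  as.numeric(pa)
}

#' Global alignment score with BLOSUM62 and affine gaps
#'
#' BlastP-like baseline: Needleman-Wunsch with the BLOSUM62 substitution
#' matrix and affine gap penalties (a length-g gap costs
#' `gap_open + g * gap_extend`).
#'
#' @param wt,mut Non-empty canonical amino-acid strings.
#' @param gap_open,gap_extend Affine gap penalties (defaults 11 and 1).
#' @return Optimal global alignment score.
#' @export
blosum_alignment_score <- function(wt, mut, gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(wt), nzchar(mut))
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(wt),
                                      Biostrings::AAString(mut),
                                      type = "global",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend,
                                      scoreOnly = TRUE)
  as.numeric(pa)
}
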
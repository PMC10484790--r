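# Pseudo-log-likelihood-ratio (PLLR) scoring of in-frame indels.
#
# The effect score of an in-frame indel is PLL(mutant) - PLL(wild type),
# where PLL(s) = sum_i log Pr(x_i = s_i | s) is the pseudo-log-likelihood
# of sequence s under the backend. When either sequence exceeds the backend
# input limit, both PLLs are computed on matched context subsequences: 511
# residues upstream of the indel (or as many as there are), the affected
# region, and enough downstream residues to bring the longer of the two
# subsequences to exactly the window length.

#' Describe an in-frame indel at the protein level
#'
#' @param kind One of `"deletion"`, `"insertion"`, `"delins"`.
#' @param start,end 1-based inclusive span of wild-type residues removed
#'   (deletion/delins). Ignored for insertions.
#' @param inserted Amino-acid string inserted (insertion/delins); empty for
#'   deletions.
#' @param anchor For insertions: the residue after which the new residues
#'   are inserted (`0` = before the first residue).
#' @return Object of class `indel_variant`.
#' @export
indel_variant <- function(kind = c("deletion", "insertion", "delins"),
                          start = NULL, end = NULL, inserted = "",
                          anchor = NULL) {
  kind <- match.arg(kind)
  inserted <- toupper(inserted)
  if (nzchar(inserted)) {
    chars <- strsplit(inserted, "", fixed = TRUE)[[1]]
    if (!all(chars %in% .AA)) {
      stop("inserted residues must be canonical amino acids", call. = FALSE)
    }
  }
  if (kind == "insertion") {
    if (is.null(anchor) || !nzchar(inserted)) {
      stop("insertion needs an anchor and a non-empty inserted string",
           call. = FALSE)
    }
    start <- NA_integer_; end <- NA_integer_
  } else {
    if (is.null(start) || is.null(end) || start > end || start < 1) {
      stop(kind, " needs a valid 1-based span start..end", call. = FALSE)
    }
    if (kind == "deletion" && nzchar(inserted)) {
      stop("deletion cannot carry inserted residues (use delins)",
           call. = FALSE)
    }
    if (kind == "delins" && !nzchar(inserted)) {
      stop("delins needs inserted residues (use deletion)", call. = FALSE)
    }
    anchor <- NA_integer_
  }
  structure(list(kind = kind, start = as.integer(start),
                 end = as.integer(end), inserted = inserted,
                 anchor = as.integer(anchor)),
            class = "indel_variant")
}

indel_dims <- function(seq, indel) {
  L <- seq$length
  if (indel$kind == "insertion") {
    if (indel$anchor < 0L || indel$anchor > L) {
      stop("insertion anchor outside 0..L", call. = FALSE)
    }
    list(span_len = 0L, ins_len = nchar(indel$inserted),
         first = indel$anchor + 1L, last = indel$anchor)
  } else {
    if (indel$end > L) stop("indel span outside the sequence", call. = FALSE)
    list(span_len = indel$end - indel$start + 1L,
         ins_len = nchar(indel$inserted),
         first = indel$start, last = indel$end)
  }
}

#' Apply an in-frame indel to a protein sequence
#'
#' @param seq A [protein_sequence()].
#' @param indel An [indel_variant()].
#' @return The mutated `protein_sequence` of length
#'   `L - span_length + inserted_length`, with id suffix `"|mut"`.
#' @export
apply_indel <- function(seq, indel) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(indel, "indel_variant"))
  d <- indel_dims(seq, indel)
  before <- substr(seq$residues, 1L, d$first - 1L)
  after <- substr(seq$residues, d$last + 1L, seq$length)
  mut <- paste0(before, indel$inserted, after)
  if (identical(mut, seq$residues)) {
    stop("indel is a no-op on sequence '", seq$id, "'", call. = FALSE)
  }
  protein_sequence(paste0(seq$id, "|mut"), mut)
}

#' Pseudo-log-likelihood of a sequence
#'
#' `PLL(s) = sum_i log Pr(x_i = s_i | s)`: the sum, over all positions, of
#' the backend's log-probability for the observed residue, conditioned on
#' the entire sequence in a single scoring pass. Always <= 0.
#'
#' @param seq A [protein_sequence()] within the backend's input limit.
#' @param backend A `plm_backend`.
#' @return Numeric scalar PLL.
#' @export
compute_pll <- function(seq, backend) {
  lp <- score_sequence(backend, seq)
  sum(lp[cbind(seq_len(nrow(lp)), aa_codes(seq))])
}

#' Matched context subsequences for scoring a long-protein indel
#'
#' When the wild-type or mutated sequence exceeds `window_length`, PLLs are
#' computed on subsequences: 511 residues (or as many as there are) upstream
#' of the indel, the affected region, and downstream residues filling the
#' longer of the two subsequences to exactly `window_length`. Both
#' subsequences share identical upstream and downstream context and differ
#' only by the indel.
#'
#' @param wt Wild-type [protein_sequence()].
#' @param indel An [indel_variant()] valid for `wt`.
#' @param window_length Model input limit (default 1022).
#' @param upstream Upstream context size (default 511).
#' @return List with `wt_sub` and `mut_sub` (`protein_sequence`s). If both
#'   full sequences already fit, they are returned unchanged.
#' @export
indel_context <- function(wt, indel, window_length = 1022L, upstream = 511L) {
  d <- indel_dims(wt, indel)
  mut <- apply_indel(wt, indel)
  if (wt$length <= window_length && mut$length <= window_length) {
    return(list(wt_sub = wt, mut_sub = mut, offset = 0L))
  }
  longer_aff <- max(d$span_len, d$ins_len)
  u <- min(upstream, d$first - 1L)
  if (u + longer_aff > window_length) {
    stop("affected region plus context exceeds window_length; variant ",
         "unsupported", call. = FALSE)
  }
  down <- min(window_length - u - longer_aff, wt$length - d$last)
  a <- d$first - u
  b <- d$last + down
  wt_sub <- subseq_protein(wt, a, b, tag = "ctx")
  mut_res <- paste0(substr(wt$residues, a, d$first - 1L), indel$inserted,
                    substr(wt$residues, d$last + 1L, b))
  mut_sub <- protein_sequence(paste0(wt$id, "|ctx|mut"), mut_res)
  list(wt_sub = wt_sub, mut_sub = mut_sub, offset = a - 1L)
}

# Remap the backend's planted-domain annotations through an indel, so the
# mutant (and the context subsequences) are scored with biologically
# coherent constraints: a domain whose interval is disrupted by the indel
# loses its constraint entirely in the mutant; domains downstream of the
# indel shift with the sequence; domains not fully inside a context
# subsequence are dropped.
indel_backend <- function(backend, wt, indel, ctx) {
  spec <- backend$domain_spec
  if (is.null(spec)) return(backend)
  mine <- is.na(spec$seq_id) | spec$seq_id == wt$id
  if (!any(mine)) return(backend)
  rows <- spec[mine, , drop = FALSE]
  rows$seq_id <- wt$id  # pin catch-all rows to the WT so they cannot leak
  d <- indel_dims(wt, indel)

  clip_to <- function(r, id, len, offset) {
    r$start <- r$start - offset
    r$end <- r$end - offset
    r <- r[r$start >= 1L & r$end <= len, , drop = FALSE]
    if (nrow(r)) r$seq_id <- id
    r
  }
  # WT-side: same coordinates, shifted into subsequence frame
  wt_rows <- if (identical(ctx$wt_sub$id, wt$id)) {
    rows
  } else {
    clip_to(rows, ctx$wt_sub$id, ctx$wt_sub$length, ctx$offset)
  }
  # mutant-side: destroy disrupted domains, shift downstream ones
  shift <- d$ins_len - d$span_len
  if (indel$kind == "insertion") {
    disrupted <- rows$start <= d$last & rows$end > d$last
    downstream <- rows$start > d$last
  } else {
    disrupted <- rows$start <= d$last & rows$end >= d$first
    downstream <- rows$start > d$last
  }
  mut_rows <- rows[!disrupted, , drop = FALSE]
  keep_down <- downstream[!disrupted]
  mut_rows$start[keep_down] <- mut_rows$start[keep_down] + shift
  mut_rows$end[keep_down] <- mut_rows$end[keep_down] + shift
  mut_rows <- clip_to(mut_rows, ctx$mut_sub$id, ctx$mut_sub$length,
                      ctx$offset)

  backend$domain_spec <- rbind(spec[!mine, , drop = FALSE], wt_rows, mut_rows)
  backend
}

#' PLLR effect score of an in-frame indel
#'
#' Three score variants are supported: `vanilla` is
#' `PLL(mut) - PLL(wt)`; `weighted` divides each PLL by its sequence length
#' before subtracting, `PLL(mut)/L_mut - PLL(wt)/L_wt`, to correct for
#' length differences; `absolute` is `|PLL(mut) - PLL(wt)|`, treating large
#' likelihood increases as potentially damaging too. Sequences beyond the
#' backend limit are routed through [indel_context()] and both PLLs are
#' computed on the matched subsequences.
#'
#' With a synthetic backend carrying planted domains, the domain
#' annotations are remapped through the indel before the mutant is scored:
#' an indel that disrupts a domain interval removes that domain's
#' constraint from the mutant (its remaining residues look unconstrained,
#' driving the PLLR strongly negative), while domains downstream of the
#' indel shift with the sequence.
#'
#' @param wt Wild-type [protein_sequence()].
#' @param indel An [indel_variant()].
#' @param backend A `plm_backend`.
#' @param mode One of `"vanilla"`, `"weighted"`, `"absolute"`.
#' @param upstream Upstream context for long sequences (default 511).
#' @return List of class `indel_score` with `pllr`, `mode`, `wt_pll`,
#'   `mut_pll`, `wt_length`, `mut_length`, `truncated` (whether context
#'   subsequences were used).
#' @export
score_indel <- function(wt, indel, backend,
                        mode = c("vanilla", "weighted", "absolute"),
                        upstream = 511L) {
  mode <- match.arg(mode)
  wl <- backend$max_input_length
  ctx <- indel_context(wt, indel, window_length = wl, upstream = upstream)
  truncated <- ctx$wt_sub$length < wt$length ||
    !identical(ctx$wt_sub$residues, wt$residues)
  be <- indel_backend(backend, wt, indel, ctx)
  wt_pll <- compute_pll(ctx$wt_sub, be)
  mut_pll <- compute_pll(ctx$mut_sub, be)
  pllr <- switch(mode,
    vanilla = mut_pll - wt_pll,
    weighted = mut_pll / ctx$mut_sub$length - wt_pll / ctx$wt_sub$length,
    absolute = abs(mut_pll - wt_pll)
  )
  structure(list(pllr = pllr, mode = mode, wt_pll = wt_pll,
                 mut_pll = mut_pll, wt_length = ctx$wt_sub$length,
                 mut_length = ctx$mut_sub$length, truncated = truncated),
            class = "indel_score")
}

#' @export
print.indel_score <- function(x, ...) {
  cat(sprintf("<indel_score> PLLR = %.4f (%s)%s\n", x$pllr, x$mode,
              if (x$truncated) " [context-truncated]" else ""))
  invisible(x)
}
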
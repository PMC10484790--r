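# Sliding-window handling of proteins longer than the backend input limit.
#
# Long proteins are tiled into fixed-length windows grown alternately from
# both ends of the sequence with an exact min_overlap step; if the innermost
# left/right pair overlaps by less than min_overlap, one extra centered
# window is inserted. Per-window scores are then combined with sigmoid edge
# weights so that windows contribute little near their edges, where the
# model sees truncated context.

#' Tile a sequence into overlapping fixed-length windows
#'
#' For `L <= window_length` the single window `(1, L)` is returned.
#' Otherwise every window has length exactly `window_length`, consecutive
#' windows overlap by at least `min_overlap` residues, every residue is
#' covered by at least one and at most three windows, and windows are grown
#' from both sequence ends with exact `min_overlap` steps plus, when the
#' central pair would overlap by less than `min_overlap`, one additional
#' centered window.
#'
#' @param L Sequence length.
#' @param window_length Window size (default 1022, the model input limit).
#' @param min_overlap Minimum overlap between consecutive windows
#'   (default 511).
#' @return A `data.frame` of class `window_set` with columns `start`, `end`
#'   (1-based inclusive) sorted by `start`, and attributes `L`,
#'   `window_length`, `min_overlap`.
#' @examples
#' tile_sequence(1533)          # two windows: (1,1022), (512,1533)
#' nrow(tile_sequence(5000))
#' @export
tile_sequence <- function(L, window_length = 1022L, min_overlap = 511L) {
  if (L < 1 || window_length < 2 || min_overlap < 1 ||
      min_overlap >= window_length) {
    stop("need L >= 1 and 1 <= min_overlap < window_length", call. = FALSE)
  }
  L <- as.integer(L)
  wl <- as.integer(window_length)
  ov <- as.integer(min_overlap)
  if (L <= wl) {
    return(new_window_set(1L, L, L, wl, ov))
  }
  # grow left- and right-anchored windows in exact-step pairs until the
  # innermost pair overlaps by >= min_overlap or the anchors cross
  step <- wl - ov
  k <- 0L                               # pairs added so far
  repeat {
    ls <- 1L + k * step                 # k-th left-anchored window
    rs <- L - wl + 1L - k * step        # k-th right-anchored window
    if (ls > rs) {                      # anchors crossed: ends met
      k <- k - 1L
      break
    }
    if ((ls + wl - 1L) - rs + 1L >= ov || ls == rs) break
    k <- k + 1L
  }
  lefts <- 1L + step * 0:k
  rights <- L - wl + 1L - step * k:0
  ls <- lefts[k + 1L]
  rs <- rights[1L]
  centre <- integer(0)
  if (ls == rs) {
    rights <- rights[-1L]               # innermost pair coincides
  } else if ((ls + wl - 1L) - rs + 1L < ov) {
    # central top-up window when the innermost pair overlaps by < min_overlap
    centre <- as.integer((ls + rs) %/% 2L)
  }
  starts <- c(lefts, centre, rights)
  new_window_set(starts, starts + wl - 1L, L, wl, ov)
}

# direct construction avoids data.frame() overhead (tiling is called per
# protein in genome-scale sweeps)
new_window_set <- function(start, end, L, window_length, min_overlap) {
  structure(list(start = start, end = end),
            row.names = seq_along(start),
            L = L, window_length = window_length, min_overlap = min_overlap,
            class = c("window_set", "data.frame"))
}

#' Check the tiling invariants of a window set
#'
#' Verifies full gap-free coverage of `1..L`, exact window length (for tiled
#' proteins), minimum consecutive overlap, and the at-most-3-windows-per
#' -residue bound.
#'
#' @param ws A `window_set` from [tile_sequence()].
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_window_set <- function(ws) {
  L <- attr(ws, "L")
  wl <- attr(ws, "window_length")
  ov <- attr(ws, "min_overlap")
  if (nrow(ws) == 0L) stop("empty window set", call. = FALSE)
  if (is.unsorted(ws$start)) stop("windows not sorted by start", call. = FALSE)
  if (L > wl && any(ws$end - ws$start + 1L != wl)) {
    stop("window with length != window_length", call. = FALSE)
  }
  if (ws$start[1] != 1L || ws$end[nrow(ws)] != L) {
    stop("windows do not span 1..L", call. = FALSE)
  }
  if (nrow(ws) > 1L) {
    overlap <- ws$end[-nrow(ws)] - ws$start[-1L] + 1L
    if (any(overlap < ov)) stop("consecutive overlap < min_overlap", call. = FALSE)
  }
  cov <- coverage_counts(ws)
  if (any(cov == 0L)) stop("coverage gap", call. = FALSE)
  if (max(cov) > 3L) stop("residue covered by more than 3 windows", call. = FALSE)
  invisible(TRUE)
}

# shift the backend's planted-domain annotations into window-local
# coordinates; domains not fully contained in the window are dropped for
# that window (their constraint is only fully visible where the window
# holds the whole interval)
window_backend <- function(backend, seq, a, b, sub_id) {
  spec <- backend$domain_spec
  if (is.null(spec)) return(backend)
  mine <- is.na(spec$seq_id) | spec$seq_id == seq$id
  if (!any(mine)) return(backend)
  rows <- spec[mine & spec$start >= a & spec$end <= b, , drop = FALSE]
  if (nrow(rows)) {
    rows$start <- rows$start - (a - 1L)
    rows$end <- rows$end - (a - 1L)
    rows$seq_id <- sub_id
  }
  backend$domain_spec <- rbind(spec[!mine, , drop = FALSE], rows)
  if (nrow(backend$domain_spec) == 0L) backend$domain_spec <- NULL
  backend
}

# per-residue coverage counts via a difference array
coverage_counts <- function(ws) {
  L <- attr(ws, "L")
  d <- integer(L + 1L)
  for (i in seq_len(nrow(ws))) {
    d[ws$start[i]] <- d[ws$start[i]] + 1L
    d[ws$end[i] + 1L] <- d[ws$end[i] + 1L] - 1L
  }
  cumsum(d[seq_len(L)])
}

#' Sigmoid edge weight for a position inside a window
#'
#' Weight used when averaging a variant's scores across the windows that
#' cover it. The weight is a logistic function of the distance to the
#' nearest window edge, `w(p) = sigmoid(steepness * (d(p) - margin)) + eps`
#' with `d(p) = min(p - 1, window_length - p)`: near an edge the window
#' contributes almost nothing, beyond `margin` residues from the edge it
#' contributes with weight close to 1. Symmetric about the window centre.
#'
#' @param position_in_window 1-based position(s) within the window.
#' @param window_length Window size.
#' @param steepness Sigmoid slope (default 0.1, in 1/residues).
#' @param margin Distance from the edge at which the weight reaches 1/2
#'   (default 127 residues).
#' @param eps Small floor keeping weights strictly positive (default 1e-6).
#' @return Numeric weight(s) in (0, 1].
#' @export
edge_weight <- function(position_in_window, window_length,
                        steepness = 0.1, margin = 127, eps = 1e-6) {
  p <- position_in_window
  if (any(p < 1 | p > window_length)) {
    stop("position_in_window out of 1..window_length", call. = FALSE)
  }
  stopifnot(steepness > 0, margin > 0, margin < window_length / 2)
  d <- pmin(p - 1, window_length - p)
  stats::plogis(steepness * (d - margin)) + eps
}

#' Combine a variant's per-window scores into a final effect score
#'
#' The default `weighted` mode is the sigmoid-weighted average
#' `(w(i1) s1 + ... + w(ik) sk) / (w(i1) + ... + w(ik))` over the k windows
#' covering the variant (1 <= k <= 3), with `i_j` the variant's 1-based
#' position inside window j. `mean`, `min` and `max` are the plain
#' alternative aggregators.
#'
#' @param scores Numeric vector of per-window scores `s1..sk`.
#' @param positions_in_window Variant position inside each covering window.
#' @param window_length Window size (weights are computed relative to it).
#' @param mode One of `"weighted"`, `"mean"`, `"min"`, `"max"`.
#' @param steepness,margin,eps Edge-weight parameters, see [edge_weight()].
#' @return A single aggregated score, always within
#'   `[min(scores), max(scores)]`.
#' @export
aggregate_scores <- function(scores, positions_in_window, window_length,
                             mode = c("weighted", "mean", "min", "max"),
                             steepness = 0.1, margin = 127, eps = 1e-6) {
  mode <- match.arg(mode)
  k <- length(scores)
  if (k == 0L) stop("empty score list", call. = FALSE)
  if (length(positions_in_window) != k) {
    stop("scores and positions_in_window lengths differ", call. = FALSE)
  }
  if (k == 1L) return(scores[[1L]])
  switch(mode,
    weighted = {
      w <- edge_weight(positions_in_window, window_length,
                       steepness = steepness, margin = margin, eps = eps)
      sum(w * scores) / sum(w)
    },
    mean = mean(scores),
    min = min(scores),
    max = max(scores)
  )
}

#' Missense LLR matrix with sliding-window handling of long proteins
#'
#' Computes the full 20 x L log-likelihood-ratio matrix for a protein of any
#' length. Sequences within the backend's input limit are scored in a single
#' pass; longer sequences are tiled with [tile_sequence()], each window
#' subsequence is scored independently, and per-position scores are combined
#' across the up-to-three covering windows with [aggregate_scores()] using
#' window-local coordinates. For `L <= window_length` the result is
#' bit-identical to the direct single-pass matrix.
#'
#' @param seq A [protein_sequence()].
#' @param backend A `plm_backend`; its `max_input_length` sets the window
#'   length.
#' @param mode Aggregation mode, see [aggregate_scores()].
#' @param min_overlap Minimum window overlap (default 511).
#' @param steepness,margin,eps Edge-weight parameters.
#' @return A 20 x L `llr_matrix`, see [llr_matrix()].
#' @export
tiled_llr <- function(seq, backend, mode = c("weighted", "mean", "min", "max"),
                      min_overlap = 511L, steepness = 0.1, margin = 127,
                      eps = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(seq, "protein_sequence"))
  wl <- backend$max_input_length
  L <- seq$length
  if (L <= wl) {
    return(llr_matrix(score_sequence(backend, seq)))
  }
  ws <- tile_sequence(L, window_length = wl, min_overlap = min_overlap)
  num <- matrix(0, nrow = 20L, ncol = L)
  den <- matrix(0, nrow = 20L, ncol = L)
  usum <- matrix(0, nrow = 20L, ncol = L)
  cnt <- integer(L)
  single <- matrix(NA_real_, nrow = 20L, ncol = L)  # value when coverage == 1
  runmin <- matrix(Inf, nrow = 20L, ncol = L)
  runmax <- matrix(-Inf, nrow = 20L, ncol = L)
  for (i in seq_len(nrow(ws))) {
    a <- ws$start[i]; b <- ws$end[i]
    sub <- subseq_protein(seq, a, b, tag = sprintf("w%d", i))
    wbe <- window_backend(backend, seq, a, b, sub$id)
    m <- tryCatch(llr_matrix(score_sequence(wbe, sub)),
                  error = function(e) {
                    stop("backend error in window ", i, " (", a, "-", b,
                         ") of '", seq$id, "': ", conditionMessage(e),
                         call. = FALSE)
                  })
    cols <- a:b
    local_pos <- seq_len(b - a + 1L)
    w <- edge_weight(local_pos, b - a + 1L,
                     steepness = steepness, margin = margin, eps = eps)
    mm <- unclass(m)
    num[, cols] <- num[, cols] + sweep(mm, 2L, w, `*`)
    den[, cols] <- den[, cols] + rep(w, each = 20L)
    usum[, cols] <- usum[, cols] + mm
    cnt[cols] <- cnt[cols] + 1L
    single[, cols] <- mm
    runmin[, cols] <- pmin(runmin[, cols], mm)
    runmax[, cols] <- pmax(runmax[, cols], mm)
  }
  vals <- switch(mode,
    weighted = num / den,
    mean = sweep(usum, 2L, cnt, `/`),
    min = runmin,
    max = runmax
  )
  # columns covered by exactly one window: return that window's values
  # verbatim (avoids w*s/w floating-point drift)
  one <- which(cnt == 1L)
  if (length(one)) vals[, one] <- single[, one]
  new_llr_matrix(vals, seq$id, seq$residues)
}
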
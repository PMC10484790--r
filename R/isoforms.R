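# Cross-isoform variant scoring and isoform-sensitivity classification.
#
# The same amino-acid substitution can fall in different sequence contexts
# across the alternative isoforms of a gene (e.g. when an interacting domain
# is spliced out), so a language-model score for it can change drastically.
# A variant is isoform-sensitive when it looks benign in at least one
# isoform (max score > -7), pathogenic in another (min score < -8), and the
# two predictions differ substantially (range > 4 LLR units).

#' Default isoform-sensitivity thresholds
#'
#' All values are in LLR units: `benign_floor` (-7) is the score above which
#' a variant looks likely benign, `pathogenic_ceiling` (-8) the score below
#' which it looks likely pathogenic, `min_difference` (4) the required
#' min/max gap, `high_variance_sd` (2) the cross-isoform standard-deviation
#' cutoff for "highly variable" variants, and `classification_cutoff`
#' (-7.5) the single-threshold pathogenic/benign boundary.
#'
#' @param benign_floor,pathogenic_ceiling,min_difference,high_variance_sd,classification_cutoff
#'   Override individual thresholds.
#' @return Named list of thresholds.
#' @export
sensitivity_thresholds <- function(benign_floor = -7,
                                   pathogenic_ceiling = -8,
                                   min_difference = 4,
                                   high_variance_sd = 2,
                                   classification_cutoff = -7.5) {
  stopifnot(benign_floor > pathogenic_ceiling, min_difference > 0,
            high_variance_sd >= 0)
  list(benign_floor = benign_floor, pathogenic_ceiling = pathogenic_ceiling,
       min_difference = min_difference, high_variance_sd = high_variance_sd,
       classification_cutoff = classification_cutoff)
}

# population standard deviation (divisor n); convention documented in the
# methods vignette and isolated here
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Score one variant across the isoforms of a gene
#'
#' @param map `data.frame` with columns `isoform_id`, `position`, `ref`,
#'   `alt`, `absent` (logical; `TRUE` marks isoforms from which the variant
#'   position is spliced out). Absent entries contribute nothing.
#' @param matrices Named list of [llr_matrix()] objects keyed by isoform id;
#'   every present isoform in `map` must have one.
#' @return List of class `isoform_profile` with `scores` (named per-isoform
#'   LLRs), `min_score`, `max_score`, `sd` (population s.d.), `n_isoforms`.
#' @export
score_across_isoforms <- function(map, matrices) {
  stopifnot(is.data.frame(map))
  if (!"absent" %in% names(map)) map$absent <- FALSE
  present <- map[!map$absent, , drop = FALSE]
  if (nrow(present) == 0L) {
    stop("variant absent from every isoform", call. = FALSE)
  }
  scores <- numeric(nrow(present))
  for (i in seq_len(nrow(present))) {
    iso <- present$isoform_id[i]
    if (!iso %in% names(matrices)) {
      stop("no LLR matrix for isoform '", iso, "'", call. = FALSE)
    }
    scores[i] <- score_missense(matrices[[iso]], present$position[i],
                                present$ref[i], present$alt[i])
  }
  names(scores) <- present$isoform_id
  structure(list(scores = scores, min_score = min(scores),
                 max_score = max(scores), sd = pop_sd(scores),
                 n_isoforms = length(scores)),
            class = "isoform_profile")
}

#' Classify a variant as isoform-sensitive
#'
#' `TRUE` iff (1) the maximum cross-isoform score exceeds the benign floor,
#' (2) the minimum score is below the pathogenic ceiling, and (3) the
#' min/max difference exceeds `min_difference`. All inequalities strict.
#'
#' @param profile An `isoform_profile` from [score_across_isoforms()].
#' @param thresholds See [sensitivity_thresholds()].
#' @return Logical scalar.
#' @export
classify_isoform_sensitive <- function(profile,
                                       thresholds = sensitivity_thresholds()) {
  profile$max_score > thresholds$benign_floor &&
    profile$min_score < thresholds$pathogenic_ceiling &&
    (profile$max_score - profile$min_score) > thresholds$min_difference
}

#' Flag a variant with highly variable cross-isoform scores
#'
#' `TRUE` iff the population standard deviation of the per-isoform scores
#' strictly exceeds `high_variance_sd` (default 2 LLR units). With a single
#' present isoform the question does not apply and `NA` is returned.
#'
#' @inheritParams classify_isoform_sensitive
#' @return Logical scalar, or `NA` for single-isoform profiles.
#' @export
flag_high_variance <- function(profile,
                               thresholds = sensitivity_thresholds()) {
  if (profile$n_isoforms < 2L) return(NA)
  profile$sd > thresholds$high_variance_sd
}

#' Residue distance to the nearest splice junction
#'
#' @param position 1-based residue position in the isoform.
#' @param junction_positions_aa Splice-junction positions in residue
#'   coordinates of the same isoform.
#' @return Minimum absolute distance, or `NA_integer_` when the isoform has
#'   no junctions (single exon); such variants are excluded from summaries.
#' @export
distance_to_splice_junction <- function(position, junction_positions_aa) {
  if (length(junction_positions_aa) == 0L) return(NA_integer_)
  as.integer(min(abs(position - junction_positions_aa)))
}

#' Scan a variant table across an isoform group
#'
#' Convenience driver: computes LLR matrices for every isoform of a gene
#' (tiling long ones), scores each variant across its mapped isoforms and
#' reports the profile plus sensitivity/high-variance flags.
#'
#' @param isoforms Named list of [protein_sequence()] isoforms.
#' @param variant_map `data.frame` with columns `variant_id`, `isoform_id`,
#'   `position`, `ref`, `alt`, `absent`.
#' @param backend A `plm_backend`.
#' @param thresholds See [sensitivity_thresholds()].
#' @return `data.frame` with one row per variant: min/max/sd, flags.
#' @export
isoform_scan <- function(isoforms, variant_map, backend,
                         thresholds = sensitivity_thresholds()) {
  matrices <- lapply(isoforms, tiled_llr, backend = backend)
  names(matrices) <- vapply(isoforms, `[[`, character(1), "id")
  ids <- unique(variant_map$variant_id)
  out <- data.frame(variant_id = ids, n_isoforms = NA_integer_,
                    min_score = NA_real_, max_score = NA_real_,
                    sd = NA_real_, isoform_sensitive = NA,
                    high_variance = NA)
  for (i in seq_along(ids)) {
    sub <- variant_map[variant_map$variant_id == ids[i], , drop = FALSE]
    prof <- score_across_isoforms(sub, matrices)
    out$n_isoforms[i] <- prof$n_isoforms
    out$min_score[i] <- prof$min_score
    out$max_score[i] <- prof$max_score
    out$sd[i] <- prof$sd
    out$isoform_sensitive[i] <- classify_isoform_sensitive(prof, thresholds)
    out$high_variance[i] <- flag_high_variance(prof, thresholds)
  }
  out
}
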
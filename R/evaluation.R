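# Benchmark statistics for pathogenicity classification and DMS prediction.
#
# Orientation convention: every effect score in this package is "lower =
# more damaging", and pathogenic is the positive class. All classification
# metrics internally negate scores so that standard higher-ranks-positive
# machinery applies; ties receive half credit (Mann-Whitney midranks).

check_labeled <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (anyNA(labels) || anyNA(scores)) stop("missing labels or scores", call. = FALSE)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes (pathogenic and benign) must be present", call. = FALSE)
  }
  labels
}

#' Global ROC-AUC for pathogenic-vs-benign classification
#'
#' All variants are pooled into a single classification task. Lower scores
#' rank pathogenic; ties count 1/2 (the Mann-Whitney U convention), so the
#' AUC equals the probability that a random pathogenic variant scores below
#' a random benign one.
#'
#' @param labels Logical (or 0/1) vector; `TRUE` = pathogenic.
#' @param scores Numeric effect scores, lower = more damaging.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc_global <- function(labels, scores) {
  labels <- check_labeled(labels, scores)
  s <- -scores  # higher = more pathogenic
  r <- rank(s, ties.method = "average")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Gene-average ROC-AUC
#'
#' Each gene with at least one variant per class is evaluated separately;
#' the unweighted mean of the per-gene AUCs is returned. Ineligible genes
#' are excluded and counted.
#'
#' @inheritParams roc_auc_global
#' @param genes Gene identifier per variant.
#' @return List with `auc` (mean over eligible genes), `per_gene` (named
#'   vector), `n_eligible`, `n_excluded`.
#' @export
roc_auc_gene_average <- function(labels, scores, genes) {
  stopifnot(length(genes) == length(labels))
  labels <- as.logical(labels)
  per <- c()
  excluded <- 0L
  for (g in unique(genes)) {
    idx <- genes == g
    if (any(labels[idx]) && any(!labels[idx])) {
      per[g] <- roc_auc_global(labels[idx], scores[idx])
    } else {
      excluded <- excluded + 1L
    }
  }
  if (length(per) == 0L) stop("no gene has both classes", call. = FALSE)
  list(auc = mean(per), per_gene = per,
       n_eligible = length(per), n_excluded = excluded)
}

# ROC staircase on the "lower = pathogenic" convention: thresholds sweep
# from the most to the least pathogenic score
roc_points <- function(labels, scores) {
  labels <- check_labeled(labels, scores)
  ord <- order(-scores, decreasing = TRUE)  # most pathogenic first
  lab <- labels[ord]
  s <- (-scores)[ord]
  keep <- c(diff(s) != 0, TRUE)  # last index of each distinct threshold
  tp <- cumsum(lab)[keep]
  fp <- cumsum(!lab)[keep]
  list(tpr = c(0, tp / sum(labels)), fpr = c(0, fp / sum(!labels)))
}

#' True-positive rate at a fixed false-positive rate
#'
#' Walks the ROC staircase and returns the TPR at the most permissive
#' threshold whose FPR does not exceed `fpr`.
#'
#' @inheritParams roc_auc_global
#' @param fpr Target false-positive rate in (0, 1).
#' @return TPR in `[0, 1]`.
#' @export
tpr_at_fpr <- function(labels, scores, fpr = 0.05) {
  stopifnot(fpr > 0, fpr < 1)
  pts <- roc_points(labels, scores)
  max(pts$tpr[pts$fpr <= fpr])
}

# precision-recall AUC with step interpolation (threshold sweep identical
# to roc_points)
prc_auc <- function(labels, scores) {
  labels <- check_labeled(labels, scores)
  ord <- order(-scores, decreasing = TRUE)
  lab <- labels[ord]
  s <- (-scores)[ord]
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(lab)[keep]
  fp <- cumsum(!lab)[keep]
  recall <- tp / sum(labels)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Balanced PRC-AUC via repeated class-balanced downsampling
#'
#' PRC-AUC is sensitive to class imbalance, so each repeat draws an equal
#' number of pathogenic and benign variants — `floor(frac * minority-class
#' size)` per class, without replacement — computes the PRC-AUC on the
#' balanced subset, and the mean over `repeats` downsamples is reported.
#'
#' @inheritParams roc_auc_global
#' @param repeats Number of downsampling repeats (default 100).
#' @param frac Fraction of the minority class drawn per repeat (default 0.8).
#' @param seed Integer seed; results are bit-reproducible.
#' @return List with `auc` (mean), `sd`, `per_repeat`, `n_per_class`.
#' @export
balanced_prc_auc <- function(labels, scores, repeats = 100L, frac = 0.8,
                             seed = 1L) {
  labels <- check_labeled(labels, scores)
  pos <- which(labels)
  neg <- which(!labels)
  m <- floor(frac * min(length(pos), length(neg)))
  if (m < 2L) stop("minority class too small for balanced downsampling",
                   call. = FALSE)
  vals <- with_seed(seed, {
    vapply(seq_len(repeats), function(i) {
      idx <- c(sample(pos, m), sample(neg, m))
      prc_auc(labels[idx], scores[idx])
    }, numeric(1))
  })
  list(auc = mean(vals), sd = stats::sd(vals), per_repeat = vals,
       n_per_class = m)
}

#' Permutation test for a performance difference between two methods
#'
#' Both methods must score the identical variant set. Each iteration
#' shuffles the scores between the benchmark's variants, recomputes the
#' metric for both methods, and records the metric difference (method A
#' minus method B). The one-tailed empirical p-value — testing whether A
#' outperforms B — is the fraction of iterations whose difference is at
#' least as extreme as the observed one. With zero exceedances the p-value
#' is reported as `< 1/n`.
#'
#' By default one permutation per iteration is applied to both methods
#' (`shuffle = "shared"`), which keeps the two shuffled score vectors
#' paired; `shuffle = "independent"` draws a separate permutation per
#' method.
#'
#' @inheritParams roc_auc_global
#' @param scores_a,scores_b Score vectors of the two methods.
#' @param metric Function `(labels, scores) -> numeric`, e.g.
#'   [roc_auc_global()].
#' @param n Number of permutations (default 2000).
#' @param seed Integer seed.
#' @param shuffle `"shared"` (default) or `"independent"` permutations for
#'   the two methods.
#' @return List with `observed_diff` (metric A minus metric B), `p_value`
#'   (numeric; `1/n` when no permutation was as extreme), `p_string`
#'   (printable, `"<..."` in that case), `n_permutations`, `n_as_extreme`.
#' @export
permutation_test_diff <- function(labels, scores_a, scores_b,
                                  metric = roc_auc_global, n = 2000L,
                                  seed = 1L,
                                  shuffle = c("shared", "independent")) {
  shuffle <- match.arg(shuffle)
  stopifnot(length(scores_a) == length(scores_b))
  obs <- metric(labels, scores_a) - metric(labels, scores_b)
  diffs <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      pa <- sample.int(length(scores_a))
      pb <- if (shuffle == "shared") pa else sample.int(length(scores_b))
      metric(labels, scores_a[pa]) - metric(labels, scores_b[pb])
    }, numeric(1))
  })
  extreme <- sum(diffs >= obs)
  p <- extreme / n
  list(observed_diff = obs,
       p_value = if (extreme == 0L) 1 / n else p,
       p_string = if (extreme == 0L) sprintf("<%g", 1 / n) else sprintf("%g", p),
       n_permutations = n, n_as_extreme = extreme)
}

#' Bootstrap mean and s.d. of the ROC-AUC
#'
#' Each iteration samples `n_pos` pathogenic and `n_neg` benign variants
#' (without replacement when the class is large enough, otherwise with
#' replacement, flagged) and recomputes the ROC-AUC; the mean and s.d.
#' across iterations quantify metric uncertainty.
#'
#' @inheritParams roc_auc_global
#' @param n_pos,n_neg Per-class sample sizes (defaults 140).
#' @param iters Bootstrap iterations (default 20).
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `per_iteration`, `with_replacement`.
#' @export
bootstrap_roc_sd <- function(labels, scores, n_pos = 140L, n_neg = 140L,
                             iters = 20L, seed = 1L) {
  labels <- check_labeled(labels, scores)
  pos <- which(labels)
  neg <- which(!labels)
  repl_pos <- length(pos) < n_pos
  repl_neg <- length(neg) < n_neg
  vals <- with_seed(seed, {
    vapply(seq_len(iters), function(i) {
      idx <- c(sample(pos, n_pos, replace = repl_pos),
               sample(neg, n_neg, replace = repl_neg))
      roc_auc_global(labels[idx], scores[idx])
    }, numeric(1))
  })
  list(mean = mean(vals), sd = stats::sd(vals), per_iteration = vals,
       with_replacement = repl_pos || repl_neg)
}

#' Center-transform DMS measurements around the wild-type value
#'
#' For assays where deviation from the wild-type readout in either
#' direction indicates damage, measurements `x` are replaced by
#' `|x - x_wt|`.
#'
#' @param measurements Numeric assay measurements.
#' @param x_wt Assay-wide wild-type value.
#' @return Transformed measurements.
#' @export
dms_center_transform <- function(measurements, x_wt) {
  if (is.null(x_wt) || is.na(x_wt)) {
    stop("x_wt required for the center transform", call. = FALSE)
  }
  abs(measurements - x_wt)
}

#' Hierarchical Spearman correlation of predictions with DMS assays
#'
#' For every assay, the Spearman rank correlation between the method's
#' predictions and the (optionally center-transformed) measurements is
#' computed; per-gene means across assays and the overall mean of per-gene
#' means are reported. Correlations are taken directly between predictions
#' and measurements; Spearman's rank correlation makes any monotone
#' prediction transform irrelevant.
#'
#' @param dms `data.frame` with columns `gene_id`, `assay_id`,
#'   `measurement`, `prediction`, and optionally `x_wt` and
#'   `center_transform` (logical, per assay).
#' @return List with `overall` (mean of per-gene means), `per_gene`,
#'   `per_assay` (`data.frame`), `excluded_assays` (constant-vector
#'   assays).
#' @export
dms_correlations <- function(dms) {
  need <- c("gene_id", "assay_id", "measurement", "prediction")
  stopifnot(all(need %in% names(dms)))
  keys <- unique(dms[, c("gene_id", "assay_id")])
  rho <- numeric(0)
  gene <- character(0)
  assay <- character(0)
  excluded <- character(0)
  for (i in seq_len(nrow(keys))) {
    sub <- dms[dms$gene_id == keys$gene_id[i] &
                 dms$assay_id == keys$assay_id[i], , drop = FALSE]
    if (nrow(sub) < 3L) {
      stop("assay '", keys$assay_id[i], "' has < 3 variants", call. = FALSE)
    }
    meas <- sub$measurement
    if (isTRUE(sub$center_transform[1])) {
      meas <- dms_center_transform(meas, sub$x_wt[1])
    }
    if (pop_sd(meas) < 1e-15 || pop_sd(sub$prediction) < 1e-15) {
      warning("assay '", keys$assay_id[i],
              "' has a constant vector; excluded", call. = FALSE)
      excluded <- c(excluded, keys$assay_id[i])
      next
    }
    rho <- c(rho, stats::cor(sub$prediction, meas, method = "spearman"))
    gene <- c(gene, keys$gene_id[i])
    assay <- c(assay, keys$assay_id[i])
  }
  if (length(rho) == 0L) stop("no usable assay", call. = FALSE)
  per_gene <- tapply(rho, gene, mean)
  list(overall = mean(per_gene), per_gene = per_gene,
       per_assay = data.frame(gene_id = gene, assay_id = assay,
                              spearman = rho),
       excluded_assays = excluded)
}
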
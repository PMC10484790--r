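test_that("global ROC-AUC follows the Mann-Whitney convention", {
  expect_equal(roc_auc_global(c(TRUE, TRUE, FALSE, FALSE),
                              c(-10, -8, -2, -1)), 1)
  expect_equal(roc_auc_global(c(TRUE, TRUE, FALSE, FALSE),
                              c(-10, -2, -8, -1)), 0.75)
  # one tied pathogenic/benign pair among otherwise perfect: 1/2 pair credit
  expect_equal(roc_auc_global(c(TRUE, TRUE, FALSE, FALSE),
                              c(-10, -8, -8, -1)), 1 - 0.5 / 4)
  expect_error(roc_auc_global(c(TRUE, TRUE), c(-1, -2)), "both classes")
  # oracle equivalence on random instances
  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)  # rounding induces ties
    expect_equal(roc_auc_global(labels, scores), pairwise_auc(labels, scores))
  }
})

test_that("gene-average ROC-AUC is an unweighted mean over eligible genes", {
  labels <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  scores <- c(-9, -1, -8, -2, -5, -7)
  genes <- c("g1", "g1", "g2", "g2", "g2", "g3")  # g3 lacks a benign variant
  res <- roc_auc_gene_average(labels, scores, genes)
  expect_equal(res$n_eligible, 2L)
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$auc, mean(c(1, 0.5)))
  # per-gene calibrated scores with per-gene offsets: gene-average > global
  set.seed(3)
  lab <- rep(c(TRUE, FALSE), 150)
  gene <- rep(sprintf("g%d", 1:3), each = 100)
  offset <- rep(c(0, 15, 30), each = 100)
  sc <- ifelse(lab, -10, -2) + rnorm(300) - offset
  expect_gt(roc_auc_gene_average(lab, sc, gene)$auc,
            roc_auc_global(lab, sc))
})

test_that("tpr_at_fpr walks the ROC staircase", {
  expect_equal(tpr_at_fpr(c(TRUE, TRUE, FALSE, FALSE),
                          c(-9, -8, -2, -1), fpr = 0.05), 1)
  # 6-variant toy set (sorted: -10 P, -9 B, -8 P, -7 P, -6 B, -5 B);
  # staircase points (FPR, TPR): (0,1/3) (1/3,1/3) (1/3,2/3) (1/3,1)
  # (2/3,1) (1,1)
  labels <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  scores <- c(-10, -9, -8, -7, -6, -5)
  expect_equal(tpr_at_fpr(labels, scores, fpr = 0.3), 1 / 3)
  expect_equal(tpr_at_fpr(labels, scores, fpr = 0.4), 1)
  set.seed(11)
  lab <- rep(c(TRUE, FALSE), each = 4000)
  sc <- runif(8000)
  expect_lt(abs(tpr_at_fpr(lab, sc, fpr = 0.1) - 0.1),
            3 * sqrt(0.1 * 0.9 / 4000) + 2 / 4000)
})

test_that("balanced PRC-AUC is seeded, balanced and sane", {
  labels <- c(rep(TRUE, 10), rep(FALSE, 40))
  scores <- c(seq(-20, -11), seq(-10, -10 + 39))
  res <- balanced_prc_auc(labels, scores, repeats = 10, seed = 4)
  expect_equal(res$n_per_class, 8L)  # floor(0.8 * 10)
  expect_equal(res$per_repeat, rep(1, 10))  # perfect separation
  res2 <- balanced_prc_auc(labels, scores, repeats = 10, seed = 4)
  expect_identical(res$per_repeat, res2$per_repeat)
  expect_error(balanced_prc_auc(c(TRUE, FALSE), c(-1, -2)), "too small")
})

test_that("permutation tests report observed differences and p-values", {
  labels <- rep(c(TRUE, FALSE), each = 20)
  scores <- ifelse(labels, -10, -2) + plmvep:::with_seed(6, rnorm(40, 0, 0.5))
  same <- permutation_test_diff(labels, scores, scores, n = 200, seed = 2)
  expect_equal(same$observed_diff, 0)
  expect_equal(same$p_value, 1)
  rand <- plmvep:::with_seed(7, rnorm(40))
  strong <- permutation_test_diff(labels, scores, rand, n = 400, seed = 2)
  expect_equal(strong$n_as_extreme, 0L)
  expect_equal(strong$p_value, 1 / 400)
  expect_match(strong$p_string, "^<")
})

test_that("bootstrap ROC uncertainty is seeded and shrinks with n", {
  labels <- rep(c(TRUE, FALSE), each = 300)
  perfect <- ifelse(labels, -10, -2)
  res <- bootstrap_roc_sd(labels, perfect, n_pos = 50, n_neg = 50,
                          iters = 5, seed = 3)
  expect_equal(res$mean, 1)
  expect_equal(res$sd, 0)
  noisy <- ifelse(labels, -6, -4) + plmvep:::with_seed(9, rnorm(600, 0, 2))
  sds <- vapply(c(20, 80, 250), function(k) {
    bootstrap_roc_sd(labels, noisy, n_pos = k, n_neg = k, iters = 20,
                     seed = 5)$sd
  }, numeric(1))
  expect_true(all(diff(sds) < 0))  # monotone shrinkage over the 3 sizes
  r1 <- bootstrap_roc_sd(labels, noisy, seed = 8)
  r2 <- bootstrap_roc_sd(labels, noisy, seed = 8)
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_false(r1$with_replacement)  # 140 from 300: without replacement
  idx <- c(1:40, 301:340)
  small <- bootstrap_roc_sd(labels[idx], noisy[idx], n_pos = 140,
                            n_neg = 140, iters = 3, seed = 1)
  expect_true(small$with_replacement)
})

test_that("DMS transform and hierarchical correlations", {
  expect_equal(dms_center_transform(c(1, 3, 5, 2, 7), 3), c(2, 0, 2, 1, 4))
  expect_equal(dms_center_transform(3, 3), 0)
  # symmetric values about x_wt collapse to identical transforms
  expect_equal(dms_center_transform(c(2, 4), 3), c(1, 1))
  dms <- data.frame(
    gene_id = c(rep("gA", 8), rep("gB", 4)),
    assay_id = c(rep("a1", 4), rep("a2", 4), rep("b1", 4)),
    measurement = c(1, 2, 3, 4, 1, 3, 2, 4, 4, 3, 2, 1),
    prediction = c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2, 3, 4))
  res <- dms_correlations(dms)
  rho_a2 <- cor(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "spearman")
  expect_equal(unname(res$per_gene["gA"]), mean(c(1, rho_a2)))
  expect_equal(unname(res$per_gene["gB"]), -1)
  expect_equal(res$overall, mean(c(mean(c(1, rho_a2)), -1)))
  # monotone prediction transforms leave every level unchanged
  dms2 <- dms
  dms2$prediction <- exp(dms2$prediction / 2)
  expect_equal(dms_correlations(dms2)$overall, res$overall)
  # constant assays are excluded with a warning
  dms3 <- rbind(dms, data.frame(gene_id = "gC", assay_id = "c1",
                                measurement = c(1, 1, 1),
                                prediction = c(1, 2, 3)))
  expect_warning(res3 <- dms_correlations(dms3), "constant")
  expect_identical(res3$excluded_assays, "c1")
})

test_that("levenshtein distance matches the reference implementation", {
  expect_equal(levenshtein("MKTA", "MKTA"), 0L)
  expect_equal(levenshtein("MKTA", "MTA"), 1L)
  set.seed(31)
  seqs <- replicate(12, paste(sample(aa_alphabet(), sample(3:12, 1),
                                     replace = TRUE), collapse = ""))
  for (i in 1:12) {
    a <- sample(seqs, 1); b <- sample(seqs, 1); c_ <- sample(seqs, 1)
    expect_equal(levenshtein(a, b), drop(utils::adist(a, b)))
    expect_equal(levenshtein(a, b), levenshtein(b, a))
    expect_lte(levenshtein(a, c_), levenshtein(a, b) + levenshtein(b, c_))
  }
})

test_that("alignment baselines reproduce hand-computed scores", {
  expect_equal(simple_alignment_score("AAAA", "AAAA"), 8)
  expect_equal(simple_alignment_score("AAAA", "AACA"), 5)
  expect_equal(simple_alignment_score("MKTA", "MKA"),
               simple_alignment_score("MKA", "MKTA"))
  # identical sequences: sum of BLOSUM62 diagonal entries (M,K,T,A = 5,5,5,4)
  expect_equal(blosum_alignment_score("MKTA", "MKTA"), 19)
  # one deletion: retained-residue diagonal (M,K,A = 14) minus the affine
  # gap cost (11 + 1); the deleted residue's diagonal entry (5) is lost too
  expect_equal(blosum_alignment_score("MKTA", "MKA"), 19 - 5 - 12)
  set.seed(37)
  for (i in 1:10) {
    wt <- paste(sample(aa_alphabet(), 20, replace = TRUE), collapse = "")
    mut <- paste(sample(strsplit(wt, "")[[1]]), collapse = "")
    expect_lte(blosum_alignment_score(wt, mut),
               blosum_alignment_score(wt, wt))
  }
})
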
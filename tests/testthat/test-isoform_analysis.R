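test_that("cross-isoform profiles summarize per-isoform scores", {
  be <- synthetic_backend(seed = 7)
  iso <- random_protein_seq("G1.1", 60L, seed = 71)
  m <- llr_matrix(score_sequence(be, iso))
  ref <- substr(iso$residues, 10, 10)
  alt <- setdiff(aa_alphabet(), ref)[1]
  map <- data.frame(isoform_id = "G1.1", position = 10L, ref = ref,
                    alt = alt, absent = FALSE)
  prof <- score_across_isoforms(map, list(`G1.1` = m))
  expect_equal(prof$min_score, prof$max_score)
  expect_equal(prof$sd, 0)
  expect_equal(prof$min_score, score_missense(m, 10, ref, alt))
  expect_error(score_across_isoforms(map, list()), "G1.1")
  map$absent <- TRUE
  expect_error(score_across_isoforms(map, list(`G1.1` = m)), "every isoform")
})

test_that("isoform-sensitivity criteria use strict printed thresholds", {
  expect_true(classify_isoform_sensitive(profile_from_scores(c(-2, -10))))
  expect_false(classify_isoform_sensitive(profile_from_scores(c(-7.5, -8.5))))
  expect_false(classify_isoform_sensitive(profile_from_scores(c(-2, -3))))
  # brute-force agreement on random profiles
  set.seed(17)
  th <- sensitivity_thresholds()
  for (i in 1:1000) {
    scores <- runif(sample(2:5, 1), -15, 0)
    prof <- profile_from_scores(scores)
    brute <- max(scores) > -7 && min(scores) < -8 &&
      (max(scores) - min(scores)) > 4
    expect_identical(classify_isoform_sensitive(prof, th), brute)
  }
})

test_that("high-variance flag uses population s.d. with a strict cutoff", {
  expect_true(flag_high_variance(profile_from_scores(c(-2, -10))))   # sd 4
  expect_false(flag_high_variance(profile_from_scores(c(-5, -5, -5))))
  # population s.d. of {-4, -8} is exactly 2: not > 2
  expect_false(flag_high_variance(profile_from_scores(c(-4, -8))))
  expect_true(is.na(flag_high_variance(profile_from_scores(-5))))
})

test_that("classification ignores isoform order and absent entries", {
  be <- synthetic_backend(seed = 7)
  isoA <- random_protein_seq("G2.1", 50L, seed = 72)
  isoB <- random_protein_seq("G2.2", 50L, seed = 73)
  mats <- list(`G2.1` = llr_matrix(score_sequence(be, isoA)),
               `G2.2` = llr_matrix(score_sequence(be, isoB)))
  ref1 <- substr(isoA$residues, 5, 5)
  ref2 <- substr(isoB$residues, 5, 5)
  alt1 <- setdiff(aa_alphabet(), c(ref1, ref2))[1]
  map <- data.frame(isoform_id = c("G2.1", "G2.2"), position = 5L,
                    ref = c(ref1, ref2), alt = alt1, absent = FALSE)
  p1 <- score_across_isoforms(map, mats)
  p2 <- score_across_isoforms(map[2:1, ], mats)
  expect_equal(p1$min_score, p2$min_score)
  expect_equal(p1$sd, p2$sd)
  with_absent <- rbind(map, data.frame(isoform_id = "G2.9", position = 5L,
                                       ref = ref1, alt = alt1, absent = TRUE))
  p3 <- score_across_isoforms(with_absent, mats)
  expect_equal(p3$scores, p1$scores)
})

test_that("splice-junction distances handle edge cases", {
  expect_identical(distance_to_splice_junction(100, c(98, 300)), 2L)
  expect_identical(distance_to_splice_junction(98, c(98, 300)), 0L)
  expect_identical(distance_to_splice_junction(100, integer(0)), NA_integer_)
})

test_that("exon-skip fixtures enrich sensitive calls near the skipped segment", {
  bundle <- generate_fixtures(fixture_spec(seed = 5))
  near_flags <- c()
  far_flags <- c()
  for (grp in bundle$isoform_groups) {
    scan <- isoform_scan(grp$isoforms, grp$variant_map, bundle$backend)
    near_flags <- c(near_flags,
                    scan$isoform_sensitive[scan$variant_id %in%
                                             grp$near_variant_ids])
    far_flags <- c(far_flags,
                   scan$isoform_sensitive[scan$variant_id %in%
                                            grp$far_variant_ids])
  }
  # direction only: variants in the splice-disrupted domain are enriched
  expect_gt(mean(near_flags), mean(far_flags))
  expect_gt(sum(near_flags), 0)
})
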
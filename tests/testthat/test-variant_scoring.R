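test_that("missense scores equal direct recomputation from log-probs", {
  be <- synthetic_backend(seed = 7)
  p <- random_protein_seq("fix", 120L, seed = 9)
  lp <- score_sequence(be, p)
  m <- llr_matrix(lp)
  aas <- aa_alphabet()
  set.seed(1)
  for (i in 1:30) {
    pos <- sample(120L, 1)
    ref <- substr(p$residues, pos, pos)
    alt <- sample(setdiff(aas, ref), 1)
    expected <- unname(unclass(lp)[pos, match(alt, aas)] -
                         unclass(lp)[pos, match(ref, aas)])
    expect_equal(score_missense(m, pos, ref, alt), expected)
  }
})

test_that("missense validation: ref mismatch, range, degenerate variant", {
  be <- synthetic_backend(seed = 7)
  p <- protein_sequence("p", "MKTAYIAKQR")
  m <- llr_matrix(score_sequence(be, p))
  expect_error(score_missense(m, 3, "A", "W"), "mismatch")
  expect_error(score_missense(m, 99, "A", "W"), "outside")
  expect_warning(s <- score_missense(m, 3, "T", "T"), "LLR is 0")
  expect_identical(s, 0)
})

test_that("apply_indel edits sequences correctly and rejects no-ops", {
  p <- protein_sequence("p", "MKTAYIAKQRQISFVKSHFS")  # L = 20
  del <- apply_indel(p, indel_variant("deletion", start = 5, end = 9))
  expect_equal(del$length, 15L)
  expect_identical(del$residues, "MKTARQISFVKSHFS")
  di <- apply_indel(p, indel_variant("delins", start = 3, end = 4,
                                     inserted = "WPW"))
  expect_equal(di$length, 21L)
  expect_identical(substr(di$residues, 1, 6), "MKWPWY")
  ins <- apply_indel(p, indel_variant("insertion", inserted = "AA",
                                      anchor = 0))
  expect_identical(substr(ins$residues, 1, 4), "AAMK")
  expect_error(indel_variant("insertion", inserted = "", anchor = 0),
               "non-empty")
  # replacing a span with itself is a no-op and rejected
  expect_error(apply_indel(p, indel_variant("delins", start = 2, end = 2,
                                            inserted = "K")), "no-op")
})

test_that("PLL equals the independent WT column sum and is never positive", {
  be <- synthetic_backend(seed = 3)
  aas <- aa_alphabet()
  set.seed(5)
  for (i in 1:100) {
    L <- sample(1:60, 1)
    p <- protein_sequence(paste0("s", i),
                          paste(sample(aas, L, replace = TRUE),
                                collapse = ""))
    lp <- score_sequence(be, p)
    chars <- strsplit(p$residues, "")[[1]]
    oracle <- sum(vapply(seq_len(L),
                         function(j) unclass(lp)[j, match(chars[j], aas)],
                         numeric(1)))
    pll <- compute_pll(p, be)
    expect_equal(pll, oracle)
    expect_lte(pll, 0)
  }
  p1 <- protein_sequence("one", "W")
  expect_equal(compute_pll(p1, be),
               unname(unclass(score_sequence(be, p1))[1, match("W", aas)]))
})

test_that("indel context windows follow the stated construction", {
  wt <- random_protein_seq("long", 2000L, seed = 21)
  ctx <- indel_context(wt, indel_variant("deletion", start = 1000, end = 1004))
  expect_identical(ctx$wt_sub$residues, substr(wt$residues, 489, 1510))
  expect_equal(ctx$wt_sub$length, 1022L)   # 511 up + 5 deleted + 506 down
  expect_equal(ctx$mut_sub$length, 1017L)
  expect_identical(ctx$mut_sub$residues,
                   paste0(substr(wt$residues, 489, 999),
                          substr(wt$residues, 1005, 1510)))
  # near the N terminus the upstream context is "as many as there are"
  ctx2 <- indel_context(wt, indel_variant("deletion", start = 10, end = 14))
  expect_identical(ctx2$wt_sub$residues, substr(wt$residues, 1, 1022))
  prefix_len <- function(a, b) {
    i <- 0L
    while (i < min(nchar(a), nchar(b)) &&
           substr(a, i + 1, i + 1) == substr(b, i + 1, i + 1)) i <- i + 1L
    i
  }
  expect_equal(prefix_len(ctx2$wt_sub$residues, ctx2$mut_sub$residues), 9L)
  # short sequences pass through unchanged
  short <- random_protein_seq("short", 200L, seed = 22)
  ctx3 <- indel_context(short, indel_variant("deletion", start = 50, end = 52))
  expect_identical(ctx3$wt_sub$residues, short$residues)
  # an insertion longer than the window is unsupported
  expect_error(indel_context(wt, indel_variant(
    "insertion", inserted = paste(rep("A", 1100), collapse = ""),
    anchor = 1000)), "unsupported")
})

test_that("PLLR modes satisfy their algebraic identities", {
  be <- synthetic_backend(seed = 3)
  wt <- random_protein_seq("p", 80L, seed = 31)
  delins <- indel_variant("delins", start = 40, end = 41, inserted = "WP")
  v <- score_indel(wt, delins, be, mode = "vanilla")
  w <- score_indel(wt, delins, be, mode = "weighted")
  a <- score_indel(wt, delins, be, mode = "absolute")
  expect_equal(v$pllr, v$mut_pll - v$wt_pll)
  expect_equal(w$pllr, v$pllr / 80)   # equal lengths: weighted == vanilla / L
  expect_equal(a$pllr, abs(v$pllr))
  expect_gte(a$pllr, 0)
})

test_that("domain deletions score lower than matched non-domain deletions", {
  dom <- data.frame(start = 30L, end = 60L, tolerance = 0.01)
  be <- synthetic_backend(seed = 1, domain_spec = dom)
  wt <- random_protein_seq("p", 160L, seed = 41)
  # paired deletions of equal width; averaged so junction-context noise
  # does not mask the planted constraint
  inside <- vapply(c(35L, 40L, 45L, 50L, 55L), function(s) {
    score_indel(wt, indel_variant("deletion", start = s, end = s + 2), be)$pllr
  }, numeric(1))
  outside <- vapply(c(85L, 95L, 105L, 115L, 125L), function(s) {
    score_indel(wt, indel_variant("deletion", start = s, end = s + 2), be)$pllr
  }, numeric(1))
  expect_lt(mean(inside), mean(outside))
})

test_that("context-windowed PLLR approximates the full-length oracle", {
  oracle_be <- synthetic_backend(seed = 13, max_input_length = Inf)
  be <- synthetic_backend(seed = 13)  # limit 1022 forces the context route
  wt <- random_protein_seq("just_over", 1030L, seed = 51)
  del <- indel_variant("deletion", start = 520, end = 524)
  routed <- score_indel(wt, del, be)
  full <- score_indel(wt, del, oracle_be)
  expect_true(routed$truncated)
  expect_false(full$truncated)
  # tolerance 3 documented in the vignette: the whole-sequence logit
  # component (global_weight = 0.02) bounds the PLLR drift well below this
  expect_lt(abs(routed$pllr - full$pllr), 3)
})

test_that("stop-gain scores are the lost-region minimum and monotone", {
  be <- synthetic_backend(seed = 7)
  p <- random_protein_seq("fix", 100L, seed = 61)
  m <- llr_matrix(score_sequence(be, p))
  aas <- aa_alphabet()
  codes <- match(strsplit(p$residues, "")[[1]], aas)
  # exhaustive enumeration oracle at position 25
  vals <- c()
  for (pos in 25:100) {
    for (aa in setdiff(aas, aas[codes[pos]])) {
      vals <- c(vals, unclass(m)[aa, pos])
    }
  }
  expect_equal(score_stop_gain(m, 25), min(vals))
  expect_length(vals, 19 * 76)
  # last column: min of its 19 non-WT entries
  last <- unclass(m)[-codes[100], 100]
  expect_equal(score_stop_gain(m, 100), min(last))
  # monotone: earlier stops lose a superset of the region
  s <- vapply(1:100, function(pos) score_stop_gain(m, pos), numeric(1))
  expect_true(all(diff(s) >= 0))
  expect_error(score_stop_gain(m, 0), "outside")
})

test_that("residues_lost arithmetic", {
  expect_equal(residues_lost(25, 100), list(count = 76L, fraction = 0.76))
  expect_equal(residues_lost(100, 100)$count, 1L)
  expect_equal(residues_lost(1, 100)$fraction, 1)
})

test_that("the 50-bp NMD rule, its boundary, and single-exon transcripts", {
  tm <- transcript_model("t1", exon_lengths = c(200L, 300L, 400L),
                         cds_start = 50L, cds_end = 850L)
  # junctions at transcript 200 and 500; last coding junction = 500
  expect_true(predict_nmd(tm, 300))        # stop at tx 349, 151 nt upstream
  expect_true(predict_nmd(tm, 400))        # 51 nt upstream -> NMD
  expect_false(predict_nmd(tm, 401))       # exactly 50 nt: "more than 50"
  expect_false(predict_nmd(tm, 500))       # downstream of the last junction
  single <- transcript_model("t2", exon_lengths = 900L,
                             cds_start = 1L, cds_end = 900L)
  expect_false(predict_nmd(single, 100))
  expect_error(predict_nmd(tm, 2000), "outside")
  expect_error(transcript_model("bad", c(100L), cds_start = 50L,
                                cds_end = 200L), "extent")
})
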
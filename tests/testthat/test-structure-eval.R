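test_that("ROC handles perfect separation, all-ties and the 3-point case", {
  st <- make_structure("..()")
  perfect <- make_profile(c(0.9, 0.8, 0.1, 0.2))
  expect_equal(roc_auc(perfect, st)$auc, 1.0)

  ties <- make_profile(rep(0.3, 4))
  expect_equal(roc_auc(ties, st)$auc, 0.5)

  # two dots (0.3, 0.1) vs one paired base (0.2): one concordant pair,
  # one discordant, no ties -> 0.5 by the pairwise oracle
  st3 <- make_structure("..(...)")
  r3 <- make_profile(c(0.3, 0.1, 0.2, NaN, NaN, NaN, NaN),
                     valid = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(oracle_auc(c(0.3, 0.1, 0.2), c(TRUE, TRUE, FALSE)), 0.5)
  expect_equal(roc_auc(r3, st3)$auc, 0.5)
})

test_that("ROC result satisfies curve invariants", {
  set.seed(21)
  scores <- sample(seq(0, 1, by = 0.1), 60, replace = TRUE)
  st <- make_structure(paste0(strrep(".", 30), strrep("(", 14), "..",
                              strrep(")", 14)))
  r <- make_profile(scores)
  roc <- roc_auc(r, st)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[length(roc$fpr)], roc$tpr[length(roc$tpr)]), c(1, 1))
  expect_equal(roc$n_pos + roc$n_neg, 60)
  expect_s3_class(tidy(roc), "tbl_df")
  expect_equal(glance(roc)$auc, roc$auc)
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    positive <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(positive) || all(positive)) next
    base_auc <- probeval:::roc_from_scores(scores, positive)$auc
    expect_equal(probeval:::roc_from_scores(exp(3 * scores), positive)$auc,
                 base_auc)
    expect_equal(probeval:::roc_from_scores(-scores, positive)$auc,
                 1 - base_auc)
    expect_equal(base_auc, oracle_auc(scores, positive), tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- sample(seq(0, 1, by = 0.02), 150, replace = TRUE)
  positive <- sample(c(TRUE, FALSE), 150, replace = TRUE)
  ours <- probeval:::roc_from_scores(scores, positive)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = positive, predictor = scores, quiet = TRUE,
    direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("top-x% selection ranks by reactivity with position tie-break", {
  # 6 positions, reactivities 0.9,0.5,0.4,0.3,0.2,0.1 on "..(())":
  # top 3 are positions 1,2,3 -> two dots out of three
  st <- make_structure("..(())")
  r <- make_profile(c(0.9, 0.5, 0.4, 0.3, 0.2, 0.1))
  expect_equal(top_fraction_unpaired(r, st, 50), 2 / 3)

  # x = 100 returns the overall unpaired fraction of the valid set
  expect_equal(top_fraction_unpaired(r, st, 100), 2 / 6)

  # ties broken by ascending position: equal scores at 2 and 3,
  # k = ceiling(0.33 * 6) = 2, so the dot at position 2 wins the tie
  rt <- make_profile(c(0.9, 0.5, 0.5, 0.1, 0.1, 0.1))
  expect_equal(top_fraction_unpaired(rt, st, 33), 1.0)

  expect_error(top_fraction_unpaired(r, st, 0),
               class = "probeval_validation_error")
  expect_error(top_fraction_unpaired(r, st, 101),
               class = "probeval_validation_error")
})

test_that("rate histogram uses half-open bins with overflow pooling", {
  r <- make_profile(rep(0, 10))
  h <- rate_histogram(r, bin_width = 0.1, range_max = 1)
  body <- h[is.finite(h$bin_start) & is.finite(h$bin_end), ]
  expect_equal(body$count[1], 10)
  expect_equal(sum(body$count), 10)

  r2 <- make_profile(c(0.05, 0.15))
  h2 <- rate_histogram(r2, bin_width = 0.1, range_max = 1)
  expect_equal(h2$count[h2$bin_start %in% c(0, 0.1) & is.finite(h2$bin_start)],
               c(1, 1))

  # value exactly on a bin edge belongs to the bin starting there
  r3 <- make_profile(0.1)
  h3 <- rate_histogram(r3, bin_width = 0.1, range_max = 1)
  expect_equal(h3$count[abs(h3$bin_start - 0.1) < 1e-12], 1)

  # values at or above range_max pool into the overflow bin
  r4 <- make_profile(c(1, 0.5))
  h4 <- rate_histogram(r4, bin_width = 0.1, range_max = 1)
  expect_equal(h4$count[is.infinite(h4$bin_end)], 1)
})

test_that("fraction_at_least counts inclusively over valid positions", {
  r <- make_profile(c(0.0, 0.0, 0.2, 0.5))
  expect_equal(fraction_at_least(r, 0.1), 0.5)
  expect_equal(fraction_at_least(r, 0), 1.0)

  none <- make_profile(rep(NaN, 3), valid = rep(FALSE, 3))
  expect_error(fraction_at_least(none, 0.1),
               class = "probeval_degenerate_data_error")
})

test_that("class-conditional overlap coefficient behaves at its extremes", {
  st <- make_structure("..((..))")
  same <- make_profile(rep(c(0.2, 0.4), 4))
  # both classes see exactly {0.2, 0.4} with equal weight -> overlap 1
  expect_equal(class_conditional_summary(same, st)$overlap, 1.0)

  disjoint <- make_profile(c(0.8, 0.9, 0.1, 0.1, 0.85, 0.95, 0.05, 0.15))
  expect_equal(class_conditional_summary(disjoint, st)$overlap, 0.0)

  # unpaired mass {1, 0} vs paired mass {0.5, 0.5} on two bins -> 0.5
  st2 <- make_structure("..()")
  two_bin <- make_profile(c(0.01, 0.02, 0.015, 0.105))
  cs <- class_conditional_summary(two_bin, st2, bin_width = 0.1)
  expect_equal(cs$overlap, 0.5)
  expect_equal(sort(cs$by_class$n), c(2, 2))

  all_paired <- make_profile(rep(0.1, 4))
  expect_error(class_conditional_summary(all_paired, make_structure("(())")),
               class = "probeval_degenerate_labels_error")
})
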
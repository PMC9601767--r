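test_that("pooled confusion counts exclude unknowns and use the >= rule", {
  cc <- confusion_counts(c(0.9, 0.1), c(1L, 0L), 0.5)
  expect_equal(unlist(cc), c(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  cc2 <- confusion_counts(c(0.9, 0.1), c(1L, NA), 0.5)
  expect_equal(sum(unlist(cc2)), 1L)
  expect_equal(cc2$tp, 1L)
  cc3 <- confusion_counts(0.5, 0L, 0.5)  # boundary score is called positive
  expect_equal(cc3$fp, 1L)
})

test_that("F1 follows the harmonic-mean definition with zero conventions", {
  expect_equal(f1_score(list(tp = 1, fp = 0, fn = 0)), 1)
  expect_equal(f1_score(list(tp = 8, fp = 2, fn = 4)), 8 / 11)
  expect_equal(f1_score(list(tp = 0, fp = 0, fn = 5)), 0)
  expect_equal(f1_score(list(tp = 0, fp = 0, fn = 0)), 0)
})

test_that("Fmax maximises F1 over all cuts (exhaustive-enumeration oracle)", {
  # perfectly separating scores
  expect_equal(fmax_score(c(0.1, 0.9), c(0L, 1L))$fmax, 1)
  # interleaved labels: oracle value frozen from brute-force cut enumeration
  scores <- c(0.2, 0.4, 0.6, 0.8); labels <- c(0L, 1L, 0L, 1L)
  expect_equal(brute_fmax(scores, labels), 0.8)
  fm <- fmax_score(scores, labels)
  expect_equal(fm$fmax, 0.8)
  expect_equal(fm$threshold, 0.4)  # smallest threshold attaining the max
  # all labels unknown -> empty evaluation
  expect_error(fmax_score(c(0.2, 0.8), c(NA, NA)), "empty")
})

test_that("Fmax dominates F1 at any fixed threshold and matches the oracle randomly", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    scores <- round(runif(n), 2)
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (sum(labels) == 0L) labels[1] <- 1L
    fm <- fmax_score(scores, labels)
    expect_equal(fm$fmax, brute_fmax(scores, labels), tolerance = 1e-12)
    for (t in sample(scores, 3)) {
      expect_gte(fm$fmax + 1e-12,
                 f1_score(confusion_counts(scores, labels, t)))
    }
  }
})

test_that("ROC AUC equals brute-force pair counting, with ties worth one half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1L, 1L, 0L, 0L)), 1)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(1L, 0L, 1L, 0L)), 0.5)
  # 4 positive-negative pairs, 3 won, none tied
  scores <- c(0.9, 0.8, 0.7, 0.1); labels <- c(1L, 0L, 1L, 0L)
  expect_equal(brute_auc(scores, labels), 0.75)
  expect_equal(roc_auc(scores, labels), 0.75)
})

test_that("ROC AUC matches the pair-counting oracle on random instances", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 1)  # coarse grid forces ties
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (sum(labels) == 0L) labels[1] <- 1L
    if (sum(labels == 0L) == 0L) labels[n] <- 0L
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("negating scores maps AUC to its complement", {
  set.seed(5)
  scores <- runif(40)
  labels <- rep(c(0L, 1L), 20)
  expect_equal(roc_auc(-scores, labels), 1 - roc_auc(scores, labels))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- runif(200)
  labels <- as.integer(runif(200) < plogis(6 * scores - 3))
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("coverage is the matched fraction of reference targets", {
  expect_equal(round(coverage(paste0("T", 1:489), paste0("T", 1:645)), 2), 0.76)
  expect_equal(coverage(c("a", "b"), c("a", "b")), 1)
  expect_equal(coverage(c("x", "y"), c("a", "b")), 0)
})

test_that("fully-disordered calls apply the fraction threshold with >=", {
  tracks <- tibble::tibble(
    target_id = rep(c("p94", "p95", "all"), each = 100),
    call = c(rep(1L, 94), rep(0L, 6), rep(1L, 95), rep(0L, 5), rep(1L, 100))
  )
  fd <- fully_disordered(tracks)
  expect_equal(fd$fully_disordered[fd$target_id == "p94"], FALSE)
  expect_equal(fd$fully_disordered[fd$target_id == "p95"], TRUE)
  expect_equal(fd$fully_disordered[fd$target_id == "all"], TRUE)
  expect_error(fully_disordered(tracks[0, ]), "empty")
})

test_that("caid_evaluate pools residues, excludes unknowns and reports coverage", {
  pred <- tibble::tibble(
    target_id = rep(c("A", "B"), each = 4),
    position = rep(1:4, 2),
    score = c(0.9, 0.8, 0.2, 0.1, 0.7, 0.6, 0.3, 0.2)
  )
  ref <- tibble::tibble(
    target_id = rep(c("A", "B", "C"), each = 4),
    position = rep(1:4, 3),
    label = c(1L, 1L, 0L, 0L, 1L, NA, 0L, 0L, 1L, 1L, 0L, 0L)
  )
  ev <- caid_evaluate(pred, ref, variant = "DisProt")
  expect_s3_class(ev, "caid_evaluation")
  expect_equal(ev$n_residues, 7L)   # one unknown excluded
  expect_equal(ev$n_unknown, 1L)
  expect_equal(ev$coverage, 2 / 3)  # target C has no predictions
  expect_equal(ev$fmax, 1)          # scores separate perfectly
  expect_equal(ev$auc, 1)
  g <- glance(ev)
  expect_equal(g$coverage, 0.67)
  expect_equal(g$variant, "DisProt")
})

test_that("caid_evaluate rejects mismatched lengths and empty overlap", {
  pred <- tibble::tibble(target_id = "A", position = 1:3,
                         score = c(0.1, 0.2, 0.3))
  ref_short <- tibble::tibble(target_id = "A", position = 1:2,
                              label = c(1L, 0L))
  expect_error(caid_evaluate(pred, ref_short), "mismatch")
  ref_other <- tibble::tibble(target_id = "Z", position = 1:3,
                              label = c(1L, 0L, 1L))
  expect_error(caid_evaluate(pred, ref_other), "no overlap")
})

test_that("evaluation metrics are invariant to target order", {
  set.seed(14)
  pred <- tibble::tibble(
    target_id = rep(sprintf("T%d", 1:6), each = 30),
    position = rep(1:30, 6),
    score = runif(180)
  )
  ref <- tibble::tibble(
    target_id = pred$target_id,
    position = pred$position,
    label = sample(c(0L, 1L, NA), 180, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  )
  ev1 <- caid_evaluate(pred, ref)
  perm <- sample(nrow(pred))
  ev2 <- caid_evaluate(pred[perm, ], ref[rev(seq_len(nrow(ref))), ])
  expect_equal(ev1$fmax, ev2$fmax)
  expect_equal(ev1$auc, ev2$auc)
  expect_equal(ev1$coverage, ev2$coverage)
})

test_that("fmax dominates every point of the evaluation's own PR curve", {
  set.seed(21)
  pred <- tibble::tibble(target_id = "A", position = 1:200,
                         score = runif(200))
  ref <- tibble::tibble(target_id = "A", position = 1:200,
                        label = sample(c(0L, 1L), 200, replace = TRUE))
  ev <- caid_evaluate(pred, ref)
  expect_true(all(ev$fmax >= ev$pr_curve$f1 - 1e-12))
})

test_that("tidy, glance and autoplot work on evaluations and calibrations", {
  pred <- tibble::tibble(target_id = "A", position = 1:10,
                         score = seq(0.05, 0.95, by = 0.1))
  ref <- tibble::tibble(target_id = "A", position = 1:10,
                        label = rep(c(0L, 1L), each = 5))
  ev <- caid_evaluate(pred, ref)
  expect_true(all(c("precision", "recall", "f1") %in% names(tidy(ev, "pr"))))
  expect_true(all(c("fpr", "tpr") %in% names(tidy(ev, "roc"))))
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(ev, "roc"), "ggplot")

  cal <- optimize_threshold(pred$score, ref$label)
  expect_equal(glance(cal)$best_threshold, cal$best_threshold)
  expect_s3_class(autoplot(cal), "ggplot")
})
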
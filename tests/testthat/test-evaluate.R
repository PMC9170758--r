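test_that("roc_auc equals exhaustive pair counting on random vectors", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(roc_auc(scores, labels), auc_pair_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc endpoints and degenerate inputs behave", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "positive and one negative")
})

test_that("roc_auc agrees with pROC on a random vector", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- runif(200); labels <- rbinom(200, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("confusion metrics reproduce the defining formulas", {
  # TP=3 FP=1 FN=2 TN=4
  scores <- c(rep(0.9, 4), rep(0.1, 6))
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m <- confusion_metrics(scores, labels)
  expect_equal(unname(m$counts), c(3, 1, 2, 4))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(m$mcc, 10 / sqrt(600))
  expect_length(m$degenerate, 0)

  # all correct
  m2 <- confusion_metrics(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(c(m2$precision, m2$recall, m2$f1, m2$mcc), rep(1, 4))

  # no predicted positives: flagged zeros, never NaN
  m3 <- confusion_metrics(c(0.1, 0.2, 0.3), c(1, 0, 1))
  expect_equal(m3$precision, 0)
  expect_equal(m3$recall, 0)
  expect_true(all(c("precision", "f1", "mcc") %in% m3$degenerate))
  expect_false(anyNA(unlist(m3[c("precision", "recall", "f1", "mcc")])))
})

test_that("confusion metrics match hand formulas on random tables", {
  set.seed(31)
  for (i in 1:100) {
    cts <- rmultinom(1, sample(20:200, 1), prob = runif(4, 0.05, 1))[, 1]
    tp <- cts[1]; fp <- cts[2]; fn <- cts[3]; tn <- cts[4]
    scores <- c(rep(0.9, tp + fp), rep(0.1, fn + tn))
    labels <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
    m <- confusion_metrics(scores, labels)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    expect_equal(m$precision, prec)
    expect_equal(m$recall, rec)
    if (prec + rec > 0) {
      expect_equal(m$f1, 2 * prec * rec / (prec + rec))
    }
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den > 0) expect_equal(m$mcc, (tp * tn - fp * fn) / den)
    # MCC invariance under class swap with flipped labels
    m_swap <- confusion_metrics(1 - scores, 1 - labels)
    expect_equal(m_swap$mcc, m$mcc, tolerance = 1e-12)
  }
})

test_that("F1 is the harmonic mean of stored precision and recall", {
  set.seed(5)
  for (i in 1:20) {
    m <- confusion_metrics(runif(50), rbinom(50, 1, 0.5), threshold = 0.5)
    if (m$precision > 0 && m$recall > 0) {
      expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall))
    }
  }
})

test_that("pooled CV evaluation uses the pooled vector, not per-fold averages", {
  # crafted 2-fold case: each fold separates perfectly (AUC 1 within fold)
  # but the folds live on different score scales, so pooling mixes them
  scores <- c(0.4, 0.1, 0.9, 0.6)      # fold1: pos .4 / neg .1; fold2: pos .9 / neg .6
  labels <- c(1, 0, 1, 0)
  fold <- c(1, 1, 2, 2)
  cv <- structure(list(scores = scores, labels = labels, fold = fold,
                       chosen = NULL, models = NULL, k = 2, seed = 1),
                  class = "cv_result")
  m <- evaluate_cv(cv)
  fold_avg <- mean(c(roc_auc(scores[1:2], labels[1:2]),
                     roc_auc(scores[3:4], labels[3:4])))
  expect_equal(fold_avg, 1)
  expect_equal(m$auc, 0.75)            # the pooled value is the one reported

  # incomplete pooling is a hard error
  cv$scores[2] <- NA
  expect_error(evaluate_cv(cv), "incomplete pooling")
})

test_that("cross_apply evaluates foreign samples without retraining", {
  fit <- fixture_model()
  ds <- fixture_dataset()
  m <- cross_apply(fit, ds)
  # the model must beat its own label-permuted control
  set.seed(41)
  perm <- ds; perm$label <- sample(perm$label)
  m_perm <- cross_apply(fit, perm)
  expect_gt(m$auc, m_perm$auc)

  # a "foreign species" carrying the same planted motif transfers well
  sc2 <- synthetic_config(n_pos = 150L, n_neg = 150L, embed_prob = 1,
                          jitter = 0L, seed = 77L,
                          motifs = list(list(consensus = "GTTCNA",
                                             psi_index = 2L)))
  foreign <- generate_dataset(sc2)
  expect_gte(cross_apply(fit, foreign)$auc, 0.85)

  # a disjoint motif does not transfer
  sc3 <- synthetic_config(n_pos = 150L, n_neg = 150L, embed_prob = 1,
                          jitter = 0L, seed = 78L,
                          motifs = list(list(consensus = "CCTAA",
                                             psi_index = 2L)))
  disjoint <- generate_dataset(sc3)
  expect_lt(abs(cross_apply(fit, disjoint)$auc - 0.5), 0.2)

  expect_error(cross_apply(fit, data.frame(sequence = "ACGT", label = 1)),
               "input length")
})

test_that("metric reports serialize to JSON and ROC points are monotone", {
  set.seed(51)
  scores <- runif(100); labels <- rbinom(100, 1, 0.5)
  m <- confusion_metrics(scores, labels)
  m$auc <- roc_auc(scores, labels)
  f <- tempfile(fileext = ".json")
  write_metrics(m, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$auc, m$auc)
  pts <- roc_points(scores, labels)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(pts$tpr[nrow(pts)], 1)
})
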
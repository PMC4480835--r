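# Metric implementations against worked tables and independent oracles.

test_that("confusion counts partition labeled predictions and drop unlabeled", {
  pred <- c("effect", "effect", "neutral", "neutral", "effect")
  lab <- c("effect", "neutral", "neutral", "effect", "unlabeled")
  expect_message(cc <- confusion_counts(pred, lab), "1 unlabeled")
  expect_identical(unlist(cc[c("TP", "FP", "TN", "FN")]),
                   c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  all_right <- confusion_counts(rep("effect", 5), rep("effect", 5))
  expect_identical(all_right$TP, 5L)
  expect_identical(all_right$FP + all_right$TN + all_right$FN, 0L)
})

test_that("metrics agree with direct arithmetic on worked tables", {
  tabs <- worked_confusion_tables(seed = 1L, n_random = 10L)
  for (nm in names(tabs)) {
    cc <- tabs[[nm]]$counts
    exp <- tabs[[nm]]$expected
    got <- c(class_metrics(cc), f_measures(cc), Q2 = q2(cc), MCC = mcc(cc))
    expect_equal(got, exp, tolerance = 1e-12, info = nm)
  }
  canon <- tabs$canonical$counts
  expect_equal(q2(canon), 0.70)
  expect_equal(mcc(canon), 1000 / sqrt(6e6), tolerance = 1e-12)
  expect_equal(mcc(tabs$perfect$counts), 1)
  expect_equal(mcc(tabs$symmetric$counts), 0)
})

test_that("zero denominators yield undefined markers, never zero", {
  cc <- confusion_table(0, 0, 10, 5)
  m <- class_metrics(cc)
  expect_true(is.na(m[["accuracy_effect"]]))      # TP+FP = 0
  expect_identical(m[["coverage_effect"]], 0)     # 0/5: defined
  expect_true(is.na(class_metrics(confusion_table(0, 5, 10, 0))[["coverage_effect"]]))
  expect_false(is.na(m[["accuracy_neutral"]]))
  expect_true(is.na(mcc(cc)))
  expect_true(is.na(f_measures(cc)[["F_effect"]]))
  expect_error(q2(confusion_table(0, 0, 0, 0)))
})

test_that("F-measure matches the harmonic mean and its bound", {
  cc <- confusion_table(40, 10, 40, 40)   # precision 0.8, recall 0.5
  expect_equal(f_measures(cc)[["F_effect"]], 2 * 0.8 * 0.5 / 1.3, tolerance = 1e-12)
  for (tab in worked_confusion_tables(seed = 2L, n_random = 5L)) {
    m <- class_metrics(tab$counts)
    f <- f_measures(tab$counts)
    if (!is.na(f[["F_effect"]]))
      expect_lte(f[["F_effect"]], max(m[["accuracy_effect"]], m[["coverage_effect"]]) + 1e-12)
  }
})

test_that("trapezoid ROC AUC equals the rank statistic and the pairwise oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  set.seed(21)
  big <- list(scores = rnorm(2000), labels = rbinom(2000, 1, 0.5))
  expect_equal(roc_auc(big$scores, big$labels)$auc, 0.5, tolerance = 0.05)
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(10:120, 1)
    scores <- sample(seq(-3, 3, by = 0.25), n, replace = TRUE)  # forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, rank_auc(scores, labels), tolerance = 1e-12)
    expect_equal(r$auc, pairwise_auc(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(22)
  scores <- rnorm(200); labels <- rbinom(200, 1, 0.4)
  base <- roc_auc(scores, labels)$auc
  for (f in list(function(x) 2 * x + 3, function(x) exp(x), function(x) atan(x)))
    expect_equal(roc_auc(f(scores), labels)$auc, base, tolerance = 1e-12)
})

test_that("ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- rnorm(300); labels <- rbinom(300, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("bootstrap subsamples half without replacement with the stated SD/SE", {
  df <- data.frame(v = rnorm(100))
  const <- bootstrap_errors(df, function(d) 1, n_sets = 50L, seed = 1L)
  expect_identical(const$sd, 0)
  expect_identical(const$se, 0)

  b <- bootstrap_errors(df, function(d) mean(d$v), n_sets = 200L, seed = 2L)
  expect_equal(b$se, b$sd / sqrt(b$n_used - 1), tolerance = 1e-12)
  mu <- mean(b$values)
  expect_equal(b$sd, sqrt(mean((b$values - mu)^2)), tolerance = 1e-12)

  # independent re-implementation of the whole procedure
  for (seed in 1:5) {
    b1 <- bootstrap_errors(df, function(d) mean(d$v), n_sets = 300L, seed = seed)
    set.seed(seed)
    vals <- replicate(300, mean(df$v[sample.int(100, 50)]))
    sd_oracle <- sqrt(mean((vals - mean(vals))^2))
    expect_equal(b1$sd, sd_oracle, tolerance = sd_oracle * 0.1 + 1e-9)
  }
  # undefined-metric sets are skipped and counted
  flaky <- bootstrap_errors(df, function(d) if (mean(d$v) > 0) 1 else NA_real_,
                            n_sets = 50L, seed = 3L)
  expect_identical(flaky$n_used + flaky$n_skipped, 50L)
})

test_that("accuracy-coverage curves are consistent and monotone in coverage", {
  set.seed(24)
  scores <- rnorm(500)
  labels <- ifelse(scores + rnorm(500) > 0, "effect", "neutral")
  thr <- seq(-2, 2, by = 0.25)
  cur <- accuracy_coverage_curve(scores, labels, thr)
  expect_true(all(diff(cur$coverage_effect) <= 1e-12))
  expect_equal(cur$coverage_effect[1], 1)  # threshold below all scores
  # endpoint consistency with the confusion-based metrics
  cc <- confusion_counts(ifelse(scores > 0, "effect", "neutral"), labels)
  at0 <- cur[cur$threshold == 0, ]
  expect_equal(at0$accuracy_effect, class_metrics(cc)[["accuracy_effect"]])
})

test_that("reliability curves cover everything at r=0 and shrink monotonically", {
  res <- data.frame(class = c("effect", "effect", "neutral", "neutral"),
                    ri = c(9L, 2L, 5L, 0L))
  labels <- c("effect", "neutral", "neutral", "effect")
  cur <- reliability_curve(res, labels)
  expect_identical(cur$n[1], 4L)
  expect_equal(cur$coverage[1], 1)
  expect_true(all(diff(cur$coverage) <= 0))
  expect_equal(cur$q2[cur$ri == 9], 1)
})

test_that("difficulty triage partitions variants and scores the difficult set", {
  labels <- c(rep("effect", 6), rep("neutral", 4))
  right <- labels
  wrong <- ifelse(labels == "effect", "neutral", "effect")
  # both methods always correct: everything easy
  t1 <- triage_difficulty(list(a = right, b = right), labels)
  expect_true(all(t1$partition == "easy"))
  # methods are complements: everything difficult
  t2 <- triage_difficulty(list(a = right, b = wrong), labels)
  expect_true(all(t2$partition == "difficult"))
  expect_equal(unname(t2$difficult_q2[["a"]]), 1)
  expect_equal(unname(t2$difficult_q2[["b"]]), 0)
  # all agree and all wrong: unsolvable
  t3 <- triage_difficulty(list(a = wrong, b = wrong), labels)
  expect_true(all(t3$partition == "unsolvable"))
  # partition is exhaustive and mutually exclusive by construction
  expect_identical(length(t2$partition), length(labels))
  # missing predictions exclude the variant with a note
  right_na <- right; right_na[1] <- NA
  expect_message(t4 <- triage_difficulty(list(a = right_na, b = right), labels),
                 "excluding 1")
  expect_identical(length(t4$partition), 9L)
})

test_that("the 60:40 random baseline reproduces the closed form", {
  # printed difficult-subset class counts: 15,121 effect / 7,504 neutral
  p_eff <- 15121 / (15121 + 7504)
  expect_equal(random_baseline_q2(0.6, p_eff), 0.6 * p_eff + 0.4 * (1 - p_eff))
  expect_equal(random_baseline_q2(0.6, p_eff), 0.5337, tolerance = 5e-4)
  expect_equal(random_baseline_q2(0.5, 0.5), 0.5)
})
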
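# Performance measures: per-class accuracy/coverage, F-measures, two-state
# accuracy, Matthews correlation, ROC/AUC, bootstrap errors,
# accuracy-coverage and reliability curves, and multi-method triage.
#
# Convention: "effect" is the positive class. TP = correctly predicted
# effect variants; FP = neutral variants predicted effect; TN = correctly
# predicted neutrals; FN = effect variants predicted neutral. Undefined
# rates (zero denominators) are reported as NA, never silently as 0.

#' Confusion counts
#'
#' @param predicted,labels character vectors over {"neutral","effect"};
#'   rows with an "unlabeled" label are excluded with a logged count.
#' @return object of class `confusion_counts`: list(TP, FP, TN, FN).
#' @export
confusion_counts <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels))
  keep <- labels %in% c("neutral", "effect")
  if (any(!keep))
    message(sprintf("excluding %d unlabeled prediction(s)", sum(!keep)))
  predicted <- predicted[keep]; labels <- labels[keep]
  stopifnot(all(predicted %in% c("neutral", "effect")))
  structure(list(
    TP = sum(predicted == "effect" & labels == "effect"),
    FP = sum(predicted == "effect" & labels == "neutral"),
    TN = sum(predicted == "neutral" & labels == "neutral"),
    FN = sum(predicted == "neutral" & labels == "effect")
  ), class = "confusion_counts")
}

#' Construct confusion counts directly
#' @param TP,FP,TN,FN non-negative integers.
#' @return `confusion_counts`.
#' @export
confusion_table <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FP + TN + FN > 0)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN), class = "confusion_counts")
}

.safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Per-class accuracy (precision) and coverage (recall)
#'
#' accuracy_effect = TP/(TP+FP) (positive predictive value),
#' coverage_effect = TP/(TP+FN) (sensitivity),
#' accuracy_neutral = TN/(TN+FN) (negative predictive value),
#' coverage_neutral = TN/(TN+FP) (specificity).
#'
#' @param c a `confusion_counts`.
#' @return named numeric vector; NA marks an undefined rate.
#' @export
class_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  c(accuracy_effect = .safe_div(c$TP, c$TP + c$FP),
    coverage_effect = .safe_div(c$TP, c$TP + c$FN),
    accuracy_neutral = .safe_div(c$TN, c$TN + c$FN),
    coverage_neutral = .safe_div(c$TN, c$TN + c$FP))
}

#' Per-class F-measures
#'
#' Harmonic mean of per-class precision and recall. Undefined components
#' propagate as NA.
#'
#' @param c a `confusion_counts`.
#' @return named numeric vector `c(F_effect=, F_neutral=)`.
#' @export
f_measures <- function(c) {
  m <- class_metrics(c)
  f <- function(p, r) {
    if (is.na(p) || is.na(r)) return(NA_real_)
    if (p + r == 0) return(NA_real_)
    2 * p * r / (p + r)
  }
  c(F_effect = f(m[["accuracy_effect"]], m[["coverage_effect"]]),
    F_neutral = f(m[["accuracy_neutral"]], m[["coverage_neutral"]]))
}

#' Two-state accuracy
#'
#' Q2 = (TP + TN) / (TP + FP + TN + FN).
#' @param c a `confusion_counts`.
#' @return number in [0, 1].
#' @export
q2 <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tot <- c$TP + c$FP + c$TN + c$FN
  if (tot == 0) stop("empty confusion table")
  (c$TP + c$TN) / tot
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); NA when any
#' marginal is zero.
#'
#' @param c a `confusion_counts`.
#' @return number in [-1, 1] or NA.
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- as.numeric(c$TP); fp <- as.numeric(c$FP)
  tn <- as.numeric(c$TN); fn <- as.numeric(c$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Tie-corrected rank AUC
#'
#' Mann-Whitney statistic: probability that a random effect variant scores
#' above a random neutral one, ties counted half.
#'
#' @param scores numeric scores (larger = more effect-like).
#' @param labels {"neutral","effect"} or 0/1.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else .label_to01(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)  # mid-ranks handle ties at half credit
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and area
#'
#' Sweeps a decision threshold over the unique scores ("effect" when
#' score >= threshold), traces the (FPR, TPR) curve, and integrates it by
#' the trapezoid rule. With ties handled by the sweep, the trapezoid area
#' equals the tie-corrected rank statistic ([rank_auc()]). AUC is invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (larger = more effect-like).
#' @param labels {"neutral","effect"} or 0/1.
#' @return list with `points` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else .label_to01(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # cumulative counts at each unique threshold
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / n1); fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Bootstrap error estimates for a metric
#'
#' Each bootstrap set is a random 50% subsample of the test set drawn
#' without replacement; the metric is recomputed per set. The standard
#' deviation is the root mean squared deviation of the per-set values from
#' their mean, and the standard error is SD / sqrt(n - 1) over the n sets
#' actually evaluated. Sets on which the metric is undefined (NA) are
#' skipped and counted.
#'
#' @param data data.frame of per-variant rows (predictions plus labels).
#' @param metric function(data_subset) -> number.
#' @param n_sets number of bootstrap sets (default 1000).
#' @param seed integer seed.
#' @return object of class `bootstrap_estimate`: list(mean, sd, se, n_sets,
#'   n_used, n_skipped, values).
#' @export
bootstrap_errors <- function(data, metric, n_sets = 1000L, seed = 1L) {
  stopifnot(nrow(data) >= 2L, n_sets >= 2L)
  m <- floor(nrow(data) / 2)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  vals <- numeric(n_sets)
  ok <- logical(n_sets)
  for (i in seq_len(n_sets)) {
    idx <- sample.int(nrow(data), m)
    v <- metric(data[idx, , drop = FALSE])
    vals[i] <- v
    ok[i] <- is.finite(v)
  }
  x <- vals[ok]
  if (length(x) < 2L) stop("metric undefined on nearly all bootstrap sets")
  mu <- mean(x)
  sd <- sqrt(mean((x - mu)^2))
  structure(list(mean = mu, sd = sd, se = sd / sqrt(length(x) - 1),
                 n_sets = n_sets, n_used = length(x),
                 n_skipped = sum(!ok), values = x),
            class = "bootstrap_estimate")
}

#' @export
print.bootstrap_estimate <- function(x, ...) {
  cat(sprintf("bootstrap_estimate: mean %.4f, SD %.4f, SE %.5f over %d/%d sets\n",
              x$mean, x$sd, x$se, x$n_used, x$n_sets))
  invisible(x)
}

#' Full metric report with bootstrap errors
#'
#' Computes per-class accuracy/coverage, F-measures, Q2, MCC and AUC at the
#' given threshold, each with bootstrap SD and SE.
#'
#' @param scores raw averaged-output differences in [-1, 1] (or any
#'   monotone score) per variant.
#' @param labels {"neutral","effect"} per variant.
#' @param threshold decision threshold on the score scale (default -0.05).
#' @param n_sets bootstrap sets (default 1000).
#' @param seed integer seed.
#' @return data.frame with columns metric, value, sd, se.
#' @export
metric_report <- function(scores, labels, threshold = -0.05,
                          n_sets = 1000L, seed = 1L) {
  df <- data.frame(score = scores, label = labels, stringsAsFactors = FALSE)
  compute <- function(d) {
    cls <- ifelse(d$score > threshold, "effect", "neutral")
    cc <- confusion_counts(cls, d$label)
    auc <- tryCatch(rank_auc(d$score, d$label), error = function(e) NA_real_)
    c(class_metrics(cc), f_measures(cc), Q2 = q2(cc), MCC = mcc(cc), AUC = auc)
  }
  point <- compute(df)
  boots <- lapply(names(point), function(nm)
    bootstrap_errors(df, function(d) compute(d)[[nm]], n_sets = n_sets,
                     seed = .child_seed(seed, match(nm, names(point)))))
  data.frame(metric = names(point), value = unname(point),
             sd = vapply(boots, function(b) b$sd, numeric(1)),
             se = vapply(boots, function(b) b$se, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Accuracy-coverage curves
#'
#' For each threshold, classifies score > threshold as "effect" and reports
#' per-class accuracy (precision) and coverage (recall).
#'
#' @param scores,labels as in [metric_report()].
#' @param thresholds sorted numeric vector of thresholds.
#' @return data.frame(threshold, accuracy_effect, coverage_effect,
#'   accuracy_neutral, coverage_neutral).
#' @export
accuracy_coverage_curve <- function(scores, labels, thresholds) {
  stopifnot(!is.unsorted(thresholds))
  rows <- lapply(thresholds, function(t) {
    cc <- confusion_counts(ifelse(scores > t, "effect", "neutral"), labels)
    as.data.frame(as.list(class_metrics(cc)))
  })
  cbind(data.frame(threshold = thresholds), do.call(rbind, rows))
}

#' Cumulative reliability curves
#'
#' For each reliability-index band r in 0..10, restricts to predictions
#' with RI >= r and reports overall accuracy (Q2), per-class accuracy, and
#' coverage (fraction of all labeled predictions retained).
#'
#' @param results data.frame with columns `class` and `ri` (e.g. from
#'   [predict.vepnet()]).
#' @param labels {"neutral","effect"} per prediction.
#' @return data.frame, one row per RI band.
#' @export
reliability_curve <- function(results, labels) {
  stopifnot(all(c("class", "ri") %in% names(results)))
  keep <- labels %in% c("neutral", "effect")
  results <- results[keep, , drop = FALSE]; labels <- labels[keep]
  n <- length(labels)
  rows <- lapply(0:10, function(r) {
    sel <- results$ri >= r
    if (!any(sel))
      return(data.frame(ri = r, n = 0L, coverage = 0, q2 = NA_real_,
                        accuracy_effect = NA_real_, accuracy_neutral = NA_real_))
    cc <- confusion_counts(results$class[sel], labels[sel])
    m <- class_metrics(cc)
    data.frame(ri = r, n = sum(sel), coverage = sum(sel) / n, q2 = q2(cc),
               accuracy_effect = m[["accuracy_effect"]],
               accuracy_neutral = m[["accuracy_neutral"]])
  })
  do.call(rbind, rows)
}

#' Expected two-state accuracy of a random predictor
#'
#' A predictor that labels each variant "effect" independently with
#' probability `p_background` has expected Q2 of
#' `p_background * p_effect + (1 - p_background) * (1 - p_effect)` on a set
#' whose true effect fraction is `p_effect`.
#'
#' @param p_background probability the random predictor says "effect".
#' @param p_effect true fraction of effect variants in the evaluation set.
#' @return expected Q2 in [0, 1].
#' @export
random_baseline_q2 <- function(p_background, p_effect) {
  stopifnot(p_background >= 0, p_background <= 1, p_effect >= 0, p_effect <= 1)
  p_background * p_effect + (1 - p_background) * (1 - p_effect)
}

#' Multi-method difficulty triage
#'
#' Partitions variants by agreement of a panel of methods: "easy" when all
#' methods agree and are correct, "unsolvable" when all agree and are
#' wrong, "difficult" when any two methods disagree. Reports each method's
#' Q2 on the difficult subset alongside the expected Q2 of a random
#' predictor with the stated class-probability background.
#'
#' @param per_method_predictions named list of class vectors
#'   ({"neutral","effect"}), all over the same variants; NA entries cause
#'   the variant to be excluded (with a logged count).
#' @param labels true classes.
#' @param p_background random predictor's effect probability (default 0.6).
#' @return list(partition = factor over easy/unsolvable/difficult,
#'   difficult_q2 = named numeric per method, random_q2, n_difficult,
#'   n_excluded).
#' @export
triage_difficulty <- function(per_method_predictions, labels, p_background = 0.6) {
  stopifnot(length(per_method_predictions) >= 2L)
  preds <- do.call(cbind, lapply(per_method_predictions, as.character))
  stopifnot(nrow(preds) == length(labels))
  keep <- stats::complete.cases(preds) & labels %in% c("neutral", "effect")
  if (any(!keep))
    message(sprintf("excluding %d variant(s) lacking predictions or labels", sum(!keep)))
  preds <- preds[keep, , drop = FALSE]; labels <- labels[keep]

  agree <- apply(preds, 1L, function(r) length(unique(r)) == 1L)
  correct_all <- agree & preds[, 1] == labels
  part <- ifelse(!agree, "difficult", ifelse(correct_all, "easy", "unsolvable"))
  part <- factor(part, levels = c("easy", "unsolvable", "difficult"))

  diff_idx <- which(part == "difficult")
  dq2 <- vapply(seq_len(ncol(preds)), function(j) {
    if (!length(diff_idx)) return(NA_real_)
    q2(confusion_counts(preds[diff_idx, j], labels[diff_idx]))
  }, numeric(1))
  names(dq2) <- names(per_method_predictions)
  p_eff <- if (length(diff_idx)) mean(labels[diff_idx] == "effect") else NA_real_
  list(partition = part, difficult_q2 = dq2,
       random_q2 = if (is.na(p_eff)) NA_real_ else random_baseline_q2(p_background, p_eff),
       n_difficult = length(diff_idx), n_excluded = sum(!keep))
}

#' Export metric or curve tables to TSV
#' @param df data.frame (e.g. from [metric_report()] or a curve function).
#' @param path output TSV path.
#' @export
write_metric_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
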
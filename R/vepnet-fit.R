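# The main fitting function: a ten-network cross-validated ensemble.

#' Fit a variant-effect prediction ensemble
#'
#' Trains one two-output network per cross-validation rotation and bundles
#' them into an ensemble. The homology-aware folds guarantee that no
#' protein (or detectable homologue) contributes to both the training and
#' the test side of any rotation; each rotation trains on eight folds,
#' early-stops on its cross-training fold, and its predictions for the
#' held-out test fold are stored untouched for evaluation.
#'
#' Feature normalization is fitted per rotation on the training rows only
#' and reused unchanged for cross-training and test rows. For new data,
#' [predict.vepnet()] averages the (neutral, effect) outputs over all
#' members; the final score is
#' `(avg_effect - avg_neutral) * 100` in [-100, +100], classified "effect"
#' when the raw averaged difference exceeds `threshold` (default -0.05 on
#' the [-1, 1] scale, i.e. -5 on the display scale).
#'
#' @param dataset a [variant_dataset()] with labeled variants.
#' @param folds a [assign_folds()] result; when `NULL`, the homology graph
#'   is built with `scorer`, clustered, and partitioned into ten folds with
#'   seed `config$seed`.
#' @param descriptors list of [feature_descriptor()]s
#'   (default [default_descriptors()]).
#' @param registry provider registry (default [default_registry()]).
#' @param config a [network_config()]; per-rotation seeds are derived from
#'   `config$seed`.
#' @param grid optional list of [network_config()]s; when given, each
#'   rotation picks its configuration by [hyperparameter_search()] on its
#'   cross-training fold.
#' @param threshold decision threshold on the raw averaged-output
#'   difference (default -0.05).
#' @param scorer pairwise similarity scorer used only when `folds` is NULL.
#' @return object of class `vepnet`.
#' @export
vepnet <- function(dataset, folds = NULL, descriptors = default_descriptors(),
                   registry = default_registry(), config = network_config(),
                   grid = NULL, threshold = -0.05, scorer = identity_scorer()) {
  stopifnot(inherits(dataset, "variant_dataset"))
  labeled <- dataset$variants$label %in% c("neutral", "effect")
  if (!any(labeled)) stop("no labeled variants to train on")
  train_ds <- structure(list(proteins = dataset$proteins,
                             variants = dataset$variants[labeled, , drop = FALSE]),
                        class = "variant_dataset")

  if (is.null(folds)) {
    graph <- build_homology_graph(dataset$proteins, scorer = scorer)
    folds <- assign_folds(single_linkage_clusters(graph), k = 10L,
                          seed = config$seed)
  }
  if (folds$k != 10L)
    stop("the standard protocol uses ten folds; got k = ", folds$k)

  fm <- assemble_feature_matrix(train_ds, descriptors, registry, normalize = FALSE)
  v <- fm$variants
  y <- .label_to01(v$label)
  row_fold <- unname(folds$protein_fold[v$protein_id])
  if (anyNA(row_fold)) stop("fold assignment missing for some proteins")

  splits <- crossval_splits(folds)
  members <- vector("list", folds$k)
  cv_rows <- list()
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    tr <- which(row_fold %in% sp$train)
    ct <- which(row_fold == sp$crosstrain)
    te <- which(row_fold == sp$test)
    if (length(unique(y[tr])) < 2L)
      stop(sprintf("rotation %d: training set contains a single class", r))
    if (length(unique(y[ct])) < 2L)
      stop(sprintf("rotation %d: cross-training set contains a single class", r))
    norm <- fit_normalization(fm$x, rows = tr, is_pad = fm$layout$is_pad)
    xn <- apply_normalization(fm$x, norm)
    cfg <- config
    cfg$seed <- .child_seed(config$seed, r)
    if (!is.null(grid)) {
      g <- lapply(grid, function(gc) { gc$seed <- cfg$seed; gc })
      cfg_sel <- hyperparameter_search(xn[tr, , drop = FALSE], y[tr],
                                       xn[ct, , drop = FALSE], y[ct], g)
      cfg_sel$seed <- cfg$seed
      cfg <- cfg_sel
    }
    net <- train_network(xn[tr, , drop = FALSE], y[tr],
                         xn[ct, , drop = FALSE], y[ct], cfg)
    members[[r]] <- list(network = net, norm = norm, rotation = sp)
    if (length(te)) {
      out <- predict(net, xn[te, , drop = FALSE])
      cv_rows[[r]] <- cbind(v[te, , drop = FALSE],
                            data.frame(rotation = r,
                                       out_neutral = out[, "neutral"],
                                       out_effect = out[, "effect"]))
    }
  }
  cv <- do.call(rbind, cv_rows)
  rownames(cv) <- NULL
  diff <- cv$out_effect - cv$out_neutral
  cv$score <- diff * 100
  cv$class <- ifelse(diff > threshold, "effect", "neutral")
  ridf <- reliability_index(cv$out_effect, cv$out_neutral)
  cv$ri <- ridf$ri; cv$digit <- ridf$digit

  structure(list(members = members, descriptors = descriptors,
                 registry = registry, layout = fm$layout,
                 threshold = threshold, folds = folds, cv = cv,
                 config = config, n_inputs = ncol(fm$x),
                 call = match.call()),
            class = "vepnet")
}

#' Predict variant effects with a fitted ensemble
#'
#' Encodes the variants with the ensemble's descriptor layout, runs every
#' member network (each with its own stored normalization), and averages
#' the (neutral, effect) outputs over members. The score is the averaged
#' difference scaled to [-100, +100]; class and reliability index follow
#' the ensemble's decision threshold and [reliability_index()].
#'
#' @param object a fitted [vepnet()] model.
#' @param newdata a [variant_dataset()] of variants to predict (labels, if
#'   any, are ignored).
#' @param threshold override the ensemble's decision threshold.
#' @param ... unused.
#' @return data.frame of class `vep_predictions` with columns protein_id,
#'   position, wt, var, avg_neutral, avg_effect, score, class, ri, digit.
#' @export
predict.vepnet <- function(object, newdata, threshold = object$threshold, ...) {
  stopifnot(inherits(newdata, "variant_dataset"))
  fm <- assemble_feature_matrix(newdata, object$descriptors, object$registry,
                                normalize = FALSE)
  if (!identical(fm$layout$column, object$layout$column))
    stop("feature layout mismatch between model and new data")
  acc <- matrix(0, nrow(fm$x), 2L)
  for (m in object$members) {
    xn <- apply_normalization(fm$x, m$norm)
    acc <- acc + predict(m$network, xn)
  }
  avg <- acc / length(object$members)
  diff <- avg[, 2] - avg[, 1]
  ridf <- reliability_index(avg[, 2], avg[, 1])
  out <- cbind(fm$variants[, c("protein_id", "position", "wt", "var")],
               data.frame(avg_neutral = avg[, 1], avg_effect = avg[, 2],
                          score = diff * 100,
                          class = ifelse(diff > threshold, "effect", "neutral"),
                          ri = ridf$ri, digit = ridf$digit))
  rownames(out) <- NULL
  attr(out, "excluded") <- fm$excluded
  class(out) <- c("vep_predictions", "data.frame")
  out
}

#' @export
print.vepnet <- function(x, ...) {
  cat(sprintf("vepnet ensemble: %d networks, %d input features, threshold %.2f\n",
              length(x$members), x$n_inputs, x$threshold))
  cat(sprintf("descriptors: %s\n",
              paste(vapply(x$descriptors, function(d) d$name, character(1)),
                    collapse = ", ")))
  aucs <- vapply(x$members, function(m) m$network$best_auc, numeric(1))
  cat(sprintf("cross-training AUC per rotation: %s\n",
              paste(sprintf("%.2f", aucs), collapse = " ")))
  invisible(x)
}

#' Summarize a fitted ensemble
#'
#' Reports per-rotation cross-training and test AUC, and the pooled
#' cross-validated confusion metrics at the decision threshold.
#'
#' @param object a `vepnet` model.
#' @param ... unused.
#' @return object of class `summary.vepnet`.
#' @export
summary.vepnet <- function(object, ...) {
  cv <- object$cv
  per_rot <- do.call(rbind, lapply(seq_along(object$members), function(r) {
    sub <- cv[cv$rotation == r, , drop = FALSE]
    test_auc <- if (nrow(sub) && length(unique(sub$label)) == 2L)
      rank_auc(sub$score, sub$label) else NA_real_
    data.frame(rotation = r,
               crosstrain_auc = object$members[[r]]$network$best_auc,
               test_auc = test_auc, n_test = nrow(sub))
  }))
  cc <- confusion_counts(cv$class, cv$label)
  overall <- c(class_metrics(cc), f_measures(cc), Q2 = q2(cc), MCC = mcc(cc),
               AUC = rank_auc(cv$score, cv$label))
  structure(list(per_rotation = per_rot, overall = overall,
                 n_variants = nrow(cv), threshold = object$threshold),
            class = "summary.vepnet")
}

#' @export
print.summary.vepnet <- function(x, ...) {
  cat(sprintf("Cross-validated performance over %d variants (threshold %.2f):\n",
              x$n_variants, x$threshold))
  print(round(x$overall, 3))
  cat("\nPer-rotation AUC:\n")
  print(x$per_rotation, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Reliability-curve plot for a fitted ensemble
#'
#' Plots cumulative two-state accuracy against cumulative coverage as the
#' reliability-index cutoff rises from 0 to 10, computed on the stored
#' cross-validated test predictions.
#'
#' @param x a `vepnet` model.
#' @param ... passed to [plot()].
#' @return the curve data.frame, invisibly.
#' @export
plot.vepnet <- function(x, ...) {
  curve <- reliability_curve(x$cv, x$cv$label)
  plot(curve$coverage * 100, curve$q2 * 100, type = "b", pch = 16,
       xlab = "coverage of predictions [%]", ylab = "two-state accuracy Q2 [%]",
       main = "accuracy vs coverage by reliability index", ...)
  text(curve$coverage * 100, curve$q2 * 100, labels = curve$ri, pos = 3, cex = 0.7)
  invisible(curve)
}

#' Save / load a fitted ensemble
#'
#' Serializes the ensemble (weights, descriptor list, normalization
#' parameters, threshold and seeds) as a single versioned file.
#'
#' @param object a `vepnet` model.
#' @param path file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_vepnet <- function(object, path) {
  stopifnot(inherits(object, "vepnet"))
  saveRDS(list(format_version = 1L, model = object), path)
  invisible(path)
}

#' @rdname save_vepnet
#' @export
load_vepnet <- function(path) {
  bundle <- readRDS(path)
  if (is.null(bundle$format_version) || bundle$format_version != 1L)
    stop("unrecognized model file version")
  bundle$model
}
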
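# Greedy bottom-up feature selection with window search, union across
# networks, and backward elimination.

.expand_candidates <- function(candidates, registry,
                               windows = ALLOWED_WINDOWS) {
  out <- list()
  for (cand in candidates) {
    if (inherits(cand, "feature_descriptor")) {
      out[[length(out) + 1L]] <- cand
      next
    }
    prov <- registry[[cand]]
    if (is.null(prov)) stop("unresolved provider: ", cand)
    ws <- if (prov$kind == "per_residue") windows else 1L
    for (w in ws) out[[length(out) + 1L]] <- feature_descriptor(cand, w)
  }
  out
}

# Columns of the precomputed candidate matrix belonging to one descriptor.
.descriptor_columns <- function(layout, name) which(layout$descriptor == name)

#' Greedy forward feature selection for one network
#'
#' Starting from the empty set, repeatedly evaluates every remaining
#' (descriptor, window) candidate by training one freshly initialized
#' network on the rotation's training folds and scoring it on the
#' cross-training fold; the candidate with maximal cross-training AUC is
#' added. Selection stops when no candidate improves the AUC by more than
#' `tolerance`, or after `budget` accepted steps. The rotation's test fold
#' is the held-out fold: it contributes to no AUC used here.
#'
#' @param dataset a [variant_dataset()] with labeled variants.
#' @param folds a [assign_folds()] result.
#' @param rotation one element of [crossval_splits()] (train + crosstrain
#'   fold indices; its `test` fold is held out of the whole procedure).
#' @param candidates provider names (expanded over `windows` for
#'   per-residue providers) and/or explicit [feature_descriptor()]s.
#' @param registry provider registry.
#' @param config [network_config()]; each candidate evaluation derives a
#'   fresh seed from it, so every step uses fresh random initialization.
#' @param budget maximum accepted steps (default 25).
#' @param tolerance minimum AUC improvement to accept a step (default 1e-3).
#' @param windows window sizes searched per per-residue provider.
#' @return object of class `selection_state`: list(selected, history,
#'   candidates_remaining, held_out_fold).
#' @export
greedy_forward_select <- function(dataset, folds, rotation, candidates,
                                  registry, config, budget = 25L,
                                  tolerance = 1e-3,
                                  windows = ALLOWED_WINDOWS) {
  if (budget < 1L) stop("budget must be >= 1")
  cand <- .expand_candidates(candidates, registry, windows)

  labeled <- dataset$variants$label %in% c("neutral", "effect")
  ds <- structure(list(proteins = dataset$proteins,
                       variants = dataset$variants[labeled, , drop = FALSE]),
                  class = "variant_dataset")
  # encode all candidates once; evaluations column-subset this matrix
  all_desc <- cand
  fm <- assemble_feature_matrix(ds, all_desc, registry, normalize = FALSE)
  v <- fm$variants
  y <- .label_to01(v$label)
  row_fold <- unname(folds$protein_fold[v$protein_id])
  tr <- which(row_fold %in% rotation$train)
  ct <- which(row_fold == rotation$crosstrain)
  stopifnot(length(tr) > 0L, length(ct) > 0L)

  selected <- list()
  sel_cols <- integer(0)
  history <- data.frame(step = integer(0), descriptor = character(0),
                        window = integer(0), crosstrain_auc = numeric(0),
                        stringsAsFactors = FALSE)
  best_auc <- -Inf
  step <- 0L
  while (length(cand) > 0L && step < budget) {
    step <- step + 1L
    aucs <- numeric(length(cand))
    for (k in seq_along(cand)) {
      cols <- c(sel_cols, .descriptor_columns(fm$layout, cand[[k]]$name))
      x <- fm$x[, cols, drop = FALSE]
      norm <- fit_normalization(x, rows = tr, is_pad = fm$layout$is_pad[cols])
      xn <- apply_normalization(x, norm)
      cfg <- config
      cfg$seed <- .child_seed(config$seed, step * 1000L + k)
      net <- train_network(xn[tr, , drop = FALSE], y[tr],
                           xn[ct, , drop = FALSE], y[ct], cfg)
      aucs[k] <- net$best_auc
    }
    win <- which.max(aucs)  # ties: which.max takes the lowest index
    if (aucs[win] <= best_auc + tolerance) break
    best_auc <- aucs[win]
    chosen <- cand[[win]]
    selected[[length(selected) + 1L]] <- chosen
    sel_cols <- c(sel_cols, .descriptor_columns(fm$layout, chosen$name))
    history <- rbind(history, data.frame(
      step = step, descriptor = chosen$provider, window = chosen$window,
      crosstrain_auc = best_auc, stringsAsFactors = FALSE))
    cand <- cand[-win]
  }
  structure(list(selected = selected, history = history,
                 candidates_remaining = cand,
                 held_out_fold = rotation$test),
            class = "selection_state")
}

#' Union of per-network feature selections
#'
#' Collects every (provider, window) pair selected by any network into one
#' combined set, preserving first-seen order. The same provider selected
#' at two window sizes yields two distinct entries.
#'
#' @param states list of `selection_state`s.
#' @return list of [feature_descriptor()]s.
#' @export
union_feature_sets <- function(states) {
  stopifnot(length(states) >= 1L)
  out <- list(); seen <- character(0)
  for (st in states) for (d in st$selected) {
    key <- paste(d$provider, d$window, sep = "@")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- d
    }
  }
  out
}

# Mean test-fold Q2 over the given rotations for one descriptor set.
.mean_rotation_q2 <- function(fm, y, row_fold, rotations, cols, config,
                              threshold = -0.05) {
  q2s <- vapply(seq_along(rotations), function(ri) {
    sp <- rotations[[ri]]
    tr <- which(row_fold %in% sp$train)
    ct <- which(row_fold == sp$crosstrain)
    te <- which(row_fold == sp$test)
    x <- fm$x[, cols, drop = FALSE]
    norm <- fit_normalization(x, rows = tr, is_pad = fm$layout$is_pad[cols])
    xn <- apply_normalization(x, norm)
    cfg <- config
    cfg$seed <- .child_seed(config$seed, 500000L + ri)
    net <- train_network(xn[tr, , drop = FALSE], y[tr],
                         xn[ct, , drop = FALSE], y[ct], cfg)
    out <- predict(net, xn[te, , drop = FALSE])
    cls <- ifelse(out[, "effect"] - out[, "neutral"] > threshold, "effect", "neutral")
    lab <- ifelse(y[te] == 1L, "effect", "neutral")
    q2(confusion_counts(cls, lab))
  }, numeric(1))
  mean(q2s)
}

#' Backward elimination of redundant features
#'
#' Starting from the combined feature set, removes every descriptor whose
#' removal changes the mean test-rotation two-state accuracy (Q2) by at
#' most `tolerance`. One pass in fixed (input) order is repeated until a
#' full pass removes nothing.
#'
#' @param dataset a [variant_dataset()] with labeled variants.
#' @param folds a [assign_folds()] result.
#' @param rotations rotations (from [crossval_splits()]) over which the
#'   mean test Q2 is taken.
#' @param selected list of [feature_descriptor()]s to prune.
#' @param registry provider registry.
#' @param config [network_config()].
#' @param tolerance maximal |change in mean Q2| counted as "no change"
#'   (default 1e-3).
#' @param threshold decision threshold for Q2 (default -0.05).
#' @return pruned list of [feature_descriptor()]s (always a subset of
#'   `selected`).
#' @export
backward_eliminate <- function(dataset, folds, rotations, selected, registry,
                               config, tolerance = 1e-3, threshold = -0.05) {
  stopifnot(length(selected) >= 1L)
  labeled <- dataset$variants$label %in% c("neutral", "effect")
  ds <- structure(list(proteins = dataset$proteins,
                       variants = dataset$variants[labeled, , drop = FALSE]),
                  class = "variant_dataset")
  fm <- assemble_feature_matrix(ds, selected, registry, normalize = FALSE)
  y <- .label_to01(fm$variants$label)
  row_fold <- unname(folds$protein_fold[fm$variants$protein_id])

  keep <- selected
  cols_of <- function(set) unlist(lapply(set, function(d)
    .descriptor_columns(fm$layout, d$name)))
  baseline <- .mean_rotation_q2(fm, y, row_fold, rotations, cols_of(keep),
                                config, threshold)
  repeat {
    removed_any <- FALSE
    i <- 1L
    while (i <= length(keep) && length(keep) > 1L) {
      trial <- keep[-i]
      q <- .mean_rotation_q2(fm, y, row_fold, rotations, cols_of(trial),
                             config, threshold)
      if (abs(q - baseline) <= tolerance) {
        keep <- trial
        baseline <- q
        removed_any <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!removed_any || length(keep) <= 1L) break
  }
  keep
}

#' Export a selection history to TSV
#' @param state a `selection_state`.
#' @param path output TSV path.
#' @export
write_selection_report <- function(state, path) {
  utils::write.table(state$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
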
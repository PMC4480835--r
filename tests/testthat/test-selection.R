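# Greedy forward selection, union of per-network sets, backward elimination.

noise_registry <- function() {
  reg <- default_registry()
  reg$noise <- noise_feature_provider(1L)
  reg$noise2 <- noise_feature_provider(2L)
  reg$noise2$name <- "noise2"
  reg
}

test_that("the informative candidate is selected before a noise control", {
  st <- delta_only_study()
  rot <- crossval_splits(st$folds)[[1]]
  sel <- greedy_forward_select(st$dataset, st$folds, rot,
                               candidates = c("biophys_delta", "noise"),
                               registry = noise_registry(),
                               config = quick_config(1L), budget = 2L,
                               tolerance = 0.05, windows = 1L)
  expect_s3_class(sel, "selection_state")
  expect_identical(sel$history$descriptor[1], "biophys_delta")
  expect_identical(sel$held_out_fold, rot$test)
})

test_that("all-noise candidates stop selection after at most one step", {
  st <- delta_only_study()
  rot <- crossval_splits(st$folds)[[1]]
  sel <- greedy_forward_select(st$dataset, st$folds, rot,
                               candidates = c("noise", "noise2"),
                               registry = noise_registry(),
                               config = quick_config(3L), budget = 5L,
                               tolerance = 0.05, windows = 1L)
  expect_lte(nrow(sel$history), 1L)
})

test_that("accepted steps have strictly increasing cross-training AUC", {
  st <- delta_only_study()
  rot <- crossval_splits(st$folds)[[2]]
  sel <- greedy_forward_select(st$dataset, st$folds, rot,
                               candidates = c("biophys_delta", "terminus", "noise"),
                               registry = noise_registry(),
                               config = quick_config(2L), budget = 3L,
                               tolerance = 1e-3, windows = 1L)
  if (nrow(sel$history) > 1L)
    expect_true(all(diff(sel$history$crosstrain_auc) > 0))
  expect_error(greedy_forward_select(st$dataset, st$folds, rot,
                                     candidates = "noise",
                                     registry = noise_registry(),
                                     config = quick_config(1L), budget = 0L),
               "budget")
})

test_that("union of selections preserves first-seen order and window-distinct entries", {
  mk <- function(...) {
    structure(list(selected = list(...), history = NULL,
                   candidates_remaining = list(), held_out_fold = 1L),
              class = "selection_state")
  }
  a <- mk(feature_descriptor("biophys", 5L), feature_descriptor("terminus", 1L))
  b <- mk(feature_descriptor("contact", 1L))
  u <- union_feature_sets(list(a, b))
  expect_length(u, 3L)
  expect_identical(vapply(u, function(d) d$provider, character(1)),
                   c("biophys", "terminus", "contact"))
  # identical sets collapse
  expect_length(union_feature_sets(list(a, a)), 2L)
  # same provider at two windows stays distinct
  c2 <- mk(feature_descriptor("biophys", 5L), feature_descriptor("biophys", 9L))
  expect_length(union_feature_sets(list(c2)), 2L)
})

test_that("backward elimination drops a duplicated descriptor but keeps signal", {
  st <- small_study()
  rots <- crossval_splits(st$folds)[1:2]
  reg <- default_registry()
  reg$biophys_delta_copy <- reg$biophys_delta
  reg$biophys_delta_copy$name <- "biophys_delta_copy"
  sel <- list(feature_descriptor("biophys_delta", 1L),
              feature_descriptor("biophys_delta_copy", 1L),
              feature_descriptor("terminus", 1L))
  kept <- backward_eliminate(st$dataset, st$folds, rots, sel, reg,
                             config = quick_config(5L, reps = 60L),
                             tolerance = 0.02)
  provs <- vapply(kept, function(d) d$provider, character(1))
  # exactly one of the redundant twins survives
  expect_identical(sum(provs %in% c("biophys_delta", "biophys_delta_copy")), 1L)
  # output is always a subset of the input
  expect_true(all(provs %in% vapply(sel, function(d) d$provider, character(1))))
})

test_that("selection reports export and the held-out fold stays out", {
  st <- delta_only_study()
  rot <- crossval_splits(st$folds)[[1]]
  sel <- greedy_forward_select(st$dataset, st$folds, rot,
                               candidates = c("biophys_delta"),
                               registry = noise_registry(),
                               config = quick_config(1L), budget = 1L,
                               windows = 1L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_selection_report(sel, f)
  rep <- read.delim(f)
  expect_identical(nrow(rep), nrow(sel$history))
  # leakage guard: train/crosstrain folds exclude the held-out fold index
  expect_false(sel$held_out_fold %in% c(rot$train, rot$crosstrain))
})
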
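# Homology graph, single-linkage clusters, fold assignment, rotation plan,
# and neutral-variant mining from same-function enzyme pairs.

# Scorer stub backed by a lookup of ordered-pair E-values. The scorer sees
# sequences, so fake proteins encode their id in the first residue.
lookup_scorer <- function(hits, default = 10) {
  function(seq_a, seq_b) {
    key <- paste(tolower(substr(seq_a, 1, 1)), tolower(substr(seq_b, 1, 1)),
                 sep = ">")
    v <- hits[[key]]
    if (is.null(v)) default else v
  }
}

fake_proteins <- function(ids) {
  Biostrings::AAStringSet(setNames(paste0(toupper(ids), "KVLATGC"), ids))
}

test_that("edges follow the either-direction E-value rule", {
  prot <- fake_proteins(c("a", "b", "c"))
  g <- build_homology_graph(prot, lookup_scorer(list(`a>b` = 1e-5)))
  expect_identical(nrow(g$edges), 1L)
  expect_setequal(unlist(g$edges[1, ]), c("a", "b"))

  g0 <- build_homology_graph(prot, lookup_scorer(list()))
  expect_identical(nrow(g0$edges), 0L)

  # asymmetric hit: a->b strong, b->a weak; edge still present
  g1 <- build_homology_graph(prot, lookup_scorer(list(`a>b` = 1e-5, `b>a` = 0.1)))
  expect_identical(nrow(g1$edges), 1L)
  g2 <- build_homology_graph(prot, lookup_scorer(list(`b>a` = 1e-5)))
  expect_identical(nrow(g2$edges), 1L)
})

test_that("a failing scorer yields a warning and no edge", {
  prot <- fake_proteins(c("a", "b"))
  boom <- function(a, b) stop("alignment failed")
  expect_warning(g <- build_homology_graph(prot, boom), "no edge")
  expect_identical(nrow(g$edges), 0L)
})

test_that("single-linkage clusters are the connected components", {
  g <- homology_graph(c("a", "b", "c", "d"),
                      data.frame(from = c("a", "b"), to = c("b", "c")))
  cl <- single_linkage_clusters(g)
  expect_identical(cl[["a"]], cl[["b"]])
  expect_identical(cl[["b"]], cl[["c"]])
  expect_false(cl[["d"]] == cl[["a"]])

  g5 <- homology_graph(letters[1:5])
  expect_identical(length(unique(single_linkage_clusters(g5))), 5L)
})

test_that("clusters match a breadth-first-search oracle on random graphs", {
  for (seed in 1:20) {
    n <- sample(10:50, 1)
    g <- random_graph(n, p = runif(1, 0.01, 0.1), seed = seed)
    cl <- single_linkage_clusters(g)
    oracle <- bfs_components(g$vertices, g$edges)
    # same partition up to relabeling
    expect_identical(length(unique(cl)), length(unique(oracle)))
    expect_true(all(tapply(oracle, unclass(cl), function(z) length(unique(z))) == 1L))
  }
})

test_that("fold assignment is deterministic, total, and keeps clusters intact", {
  g <- random_graph(40, 0.05, seed = 3)
  cl <- single_linkage_clusters(g)
  f1 <- assign_folds(cl, k = 10L, seed = 9L, allow_empty = TRUE)
  f2 <- assign_folds(cl, k = 10L, seed = 9L, allow_empty = TRUE)
  expect_identical(f1$protein_fold, f2$protein_fold)
  expect_identical(sort(names(f1$protein_fold)), sort(g$vertices))
  # no cluster split across folds
  expect_true(all(tapply(f1$protein_fold, unclass(cl),
                         function(z) length(unique(z))) == 1L))
})

test_that("ten singleton clusters spread one per fold; giant clusters stay whole", {
  g <- homology_graph(sprintf("s%02d", 1:10))
  cl <- single_linkage_clusters(g)
  f <- assign_folds(cl, k = 10L, seed = 1L)
  expect_identical(sort(unname(tabulate(f$protein_fold, 10))), rep(1L, 10))

  # one 60-member cluster + 9 singletons: the giant cluster lands intact
  ids <- c(sprintf("g%02d", 1:60), sprintf("s%d", 1:9))
  edges <- data.frame(from = sprintf("g%02d", 1:59), to = sprintf("g%02d", 2:60))
  cl2 <- single_linkage_clusters(homology_graph(ids, edges))
  f2 <- assign_folds(cl2, k = 10L, seed = 1L)
  giant_folds <- unique(f2$protein_fold[sprintf("g%02d", 1:60)])
  expect_length(giant_folds, 1L)
  expect_true(max(tabulate(f2$protein_fold, 10)) == 60L)

  expect_error(assign_folds(cl, k = 11L, seed = 1L), "allow_empty")
})

test_that("rotation plan tests each fold exactly once with disjoint roles", {
  g <- homology_graph(sprintf("s%02d", 1:10))
  f <- assign_folds(single_linkage_clusters(g), k = 10L, seed = 1L)
  splits <- crossval_splits(f)
  expect_length(splits, 10L)
  expect_setequal(vapply(splits, `[[`, integer(1), "test"), 1:10)
  for (sp in splits) {
    expect_identical(sp$crosstrain, (sp$test %% 10L) + 1L)
    expect_length(sp$train, 8L)
    expect_length(intersect(sp$train, c(sp$test, sp$crosstrain)), 0L)
    expect_setequal(c(sp$train, sp$crosstrain, sp$test), 1:10)
  }
})

test_that("no homology edge crosses a fold boundary on random graphs", {
  for (seed in 1:10) {
    g <- random_graph(60, 0.03, seed = 100 + seed)
    cl <- single_linkage_clusters(g)
    f <- assign_folds(cl, k = 10L, seed = seed, allow_empty = TRUE)
    if (nrow(g$edges))
      expect_identical(unname(f$protein_fold[g$edges$from]),
                       unname(f$protein_fold[g$edges$to]))
  }
})

test_that("the homology-threshold curve has the documented shape", {
  expect_gt(hssp_threshold(20), 100)          # short alignments need huge identity
  expect_equal(hssp_threshold(451), 19.5)
  expect_equal(hssp_threshold(1000), 19.5)
  expect_true(all(diff(hssp_threshold(10:450)) < 0))  # monotone decreasing
})

test_that("enzyme-pair mining gates on identity and HSSP-value, skips gaps", {
  tail_a <- strrep("A", 494)   # long alignments sit on the flat 19.5 threshold
  aligns <- function(a, b) {
    list(
      `e1|e2` = list(a = paste0("MKVLAT", tail_a),        # one mismatch at 3
                     b = paste0("MKSLAT", tail_a)),
      `e3|e4` = list(a = paste0("MKV-AT", tail_a),        # gap column skipped
                     b = paste0("MKSLAT", tail_a)),
      NULL)[[paste(a, b, sep = "|")]]
  }
  pairs <- data.frame(id_a = c("e1", "e3", "e5", "e7"),
                      id_b = c("e2", "e4", "e6", "e8"),
                      ec = "1.1.1.1",
                      identity = c(95, 95, 35, 41))
  # e5/e6 fails the identity gate; e7/e8 fails the HSSP gate (41% identity
  # over a 20-residue alignment falls far below the short-length threshold)
  aligns2 <- function(a, b) {
    r <- aligns(a, b)
    if (!is.null(r)) return(r)
    list(a = "MKVLATMKVLATMKVLATMK", b = "MKSLATMKSLATMKSLATMK")
  }
  out <- mine_ec_neutral_variants(pairs, aligns2)
  expect_identical(unique(out$label), "neutral")
  e1 <- out[out$protein_id == "e1", ]
  expect_identical(nrow(e1), 1L)
  expect_identical(e1$position, 3L)
  expect_identical(e1$wt, "V"); expect_identical(e1$var, "S")
  # gap column: e3 alignment has mismatch only where both aligned
  e3 <- out[out$protein_id == "e3", ]
  expect_identical(nrow(e3), 1L)
  expect_identical(e3$position, 3L)  # ungapped position on protein 1
  # gates: nothing mined from e5 or e7
  expect_false(any(out$protein_id %in% c("e5", "e7")))
  # 41% identity over aligned length 20: hssp_threshold(20) >> 41
  expect_gt(hssp_threshold(20), 41)

  missing <- data.frame(id_a = "x", id_b = "y", ec = "9.9.9.9", identity = 99)
  expect_warning(out2 <- mine_ec_neutral_variants(missing, function(a, b) NULL),
                 "skipped")
  expect_identical(nrow(out2), 0L)
})
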
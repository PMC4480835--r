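# Shared fixtures, built in code and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Three tiny proteins used across IO and feature tests.
tiny_proteins <- function() {
  p <- Biostrings::AAStringSet(c(p1 = "MKVLAT", p2 = "MKDEWYRH", p3 = "ACDEFGHIKLMNPQRSTVWY"))
  p
}

# Default study conditions: 10 families x 3 proteins, 2,000 variants,
# 60:40 effect:neutral, 5% label noise, seed 42.
demo_study <- function() memo("demo_study", function() {
  generate_study(synthetic_config(seed = 42L))
})

demo_fit <- function() memo("demo_fit", function() {
  st <- demo_study()
  vepnet(st$dataset, folds = st$folds, config = network_config(seed = 42L))
})

# Independent evaluation set drawn from fresh proteins (seed 43).
demo_eval <- function() memo("demo_eval", function() {
  cfg <- synthetic_config(seed = 43L, n_variants = 10000L)
  generate_variants(cfg, generate_proteins(cfg))
})

# Small study used by selection and module tests (seed 7, 600 variants).
small_study <- function() memo("small_study", function() {
  cfg <- synthetic_config(seed = 7L, n_variants = 600L)
  prot <- generate_proteins(cfg)
  ds <- generate_variants(cfg, prot)
  graph <- build_homology_graph(prot$proteins)
  folds <- assign_folds(single_linkage_clusters(graph), seed = 7L)
  list(dataset = ds, folds = folds, families = prot$families)
})

# Same generator but with every position critical: labels depend only on
# the hydropathy delta, the crisp two-candidate selection fixture.
delta_only_study <- function() memo("delta_only_study", function() {
  cfg <- synthetic_config(seed = 7L, n_variants = 600L,
                          critical_position_fraction = 1)
  prot <- generate_proteins(cfg)
  ds <- generate_variants(cfg, prot)
  graph <- build_homology_graph(prot$proteins)
  folds <- assign_folds(single_linkage_clusters(graph), seed = 7L)
  list(dataset = ds, folds = folds)
})

quick_config <- function(seed, reps = 40L) {
  network_config(seed = seed, max_stagnant_rounds = 10L, max_repetitions = reps)
}

# --- independent oracles -------------------------------------------------

# Connected components by breadth-first search over an adjacency list.
bfs_components <- function(vertices, edges) {
  adj <- setNames(vector("list", length(vertices)), vertices)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(vertices)), vertices)
  cid <- 0L
  for (v in vertices) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, adj[[u]])
    }
  }
  comp
}

# Pairwise Mann-Whitney AUC, ties at half credit; O(n^2).
pairwise_auc <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else as.integer(labels == "effect")
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Erdos-Renyi-style random labeled graph.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("v%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  homology_graph(ids, data.frame(from = ids[pairs[keep, 1]],
                                 to = ids[pairs[keep, 2]]))
}

# Per-class precision/recall etc. by direct arithmetic (independent of the
# package implementations).
direct_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  pe <- div(tp, tp + fp); re <- div(tp, tp + fn)
  pn <- div(tn, tn + fn); rn <- div(tn, tn + fp)
  fm <- function(p, r) if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else 2 * p * r / (p + r)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(accuracy_effect = pe, coverage_effect = re,
       accuracy_neutral = pn, coverage_neutral = rn,
       F_effect = fm(pe, re), F_neutral = fm(pn, rn),
       Q2 = (tp + tn) / (tp + fp + tn + fn),
       MCC = if (den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(den))
}
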
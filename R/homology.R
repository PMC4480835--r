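# Homology graph, single-linkage clusters, leakage-free cross-validation
# folds, and neutral-variant mining from same-function enzyme pairs.

#' Built-in pairwise similarity scorer
#'
#' Returns a scorer function usable with [build_homology_graph()]. The
#' scorer computes global pairwise alignment percent identity
#' (via [Biostrings::pairwiseAlignment()], BLOSUM62) and converts it to a
#' pseudo-E-value proxy: pairs with identity >= `min_identity` percent over
#' at least `min_length` aligned residues score well below any sensible
#' E-value threshold, all other pairs well above it. This lets the module
#' run with no external search binary; precomputed all-vs-all search output
#' can be supplied instead via [read_edge_list()].
#'
#' @param min_identity percent identity required for an edge (default 30).
#' @param min_length minimum aligned length (default 50).
#' @return function(seq_a, seq_b) -> pseudo E-value; carries attribute
#'   `symmetric = TRUE` so each unordered pair is scored once.
#' @export
identity_scorer <- function(min_identity = 30, min_length = 50) {
  f <- function(seq_a, seq_b) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    pid <- Biostrings::pid(al, type = "PID4")  # identity over mean sequence length
    alen <- Biostrings::nmatch(al) + Biostrings::nmismatch(al)
    if (pid >= min_identity && alen >= min_length) 1e-10 else 10
  }
  attr(f, "symmetric") <- TRUE
  f
}

#' Build the protein homology graph
#'
#' Vertices are proteins; an undirected edge joins two proteins when the
#' scorer reports an E-value below `e_threshold` in either direction
#' (symmetric closure of the hit list). Scorer failures on a pair are
#' recorded as missing evidence (no edge) with a warning.
#'
#' @param proteins [Biostrings::AAStringSet].
#' @param scorer function(seq_a, seq_b) -> E-value-like number; if it carries
#'   attribute `symmetric = TRUE` each unordered pair is scored once.
#' @param e_threshold inclusion threshold (default 1e-3).
#' @return object of class `homology_graph`: list(vertices, edges) where
#'   edges is a data.frame(from, to).
#' @export
build_homology_graph <- function(proteins, scorer = identity_scorer(),
                                 e_threshold = 1e-3) {
  stopifnot(e_threshold > 0)
  ids <- names(proteins)
  seqs <- as.character(proteins)
  edges_from <- character(0); edges_to <- character(0)
  n <- length(ids)
  if (n >= 2L) {
    sym <- isTRUE(attr(scorer, "symmetric"))
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      hit <- tryCatch({
        e1 <- scorer(seqs[[i]], seqs[[j]])
        if (!sym && e1 >= e_threshold) {
          e2 <- scorer(seqs[[j]], seqs[[i]])
          min(e1, e2) < e_threshold
        } else e1 < e_threshold
      }, error = function(e) {
        warning(sprintf("scorer failed on pair (%s, %s): %s — no edge recorded",
                        ids[i], ids[j], conditionMessage(e)))
        FALSE
      })
      if (isTRUE(hit)) {
        edges_from <- c(edges_from, ids[i]); edges_to <- c(edges_to, ids[j])
      }
    }
  }
  structure(list(vertices = ids,
                 edges = data.frame(from = edges_from, to = edges_to,
                                    stringsAsFactors = FALSE)),
            class = "homology_graph")
}

#' Homology graph from an explicit edge list
#'
#' @param vertices character vector of protein ids.
#' @param edges data.frame(from, to); self-edges dropped.
#' @return `homology_graph`.
#' @export
homology_graph <- function(vertices, edges = data.frame(from = character(0),
                                                        to = character(0))) {
  stopifnot(all(edges$from %in% vertices), all(edges$to %in% vertices))
  edges <- edges[edges$from != edges$to, c("from", "to"), drop = FALSE]
  structure(list(vertices = as.character(vertices),
                 edges = data.frame(from = as.character(edges$from),
                                    to = as.character(edges$to),
                                    stringsAsFactors = FALSE)),
            class = "homology_graph")
}

#' Read a precomputed all-vs-all search result as a homology graph
#'
#' TSV columns: `id_a`, `id_b`, `evalue`. An edge is kept when the best
#' E-value over both directions is below `e_threshold`.
#'
#' @param path TSV path.
#' @param vertices all protein ids (isolated proteins must still be vertices).
#' @param e_threshold inclusion threshold (default 1e-3).
#' @return `homology_graph`.
#' @export
read_edge_list <- function(path, vertices, e_threshold = 1e-3) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id_a", "id_b", "evalue") %in% names(df)))
  keep <- df$evalue < e_threshold & df$id_a != df$id_b
  df <- df[keep, , drop = FALSE]
  key <- ifelse(df$id_a < df$id_b, paste(df$id_a, df$id_b), paste(df$id_b, df$id_a))
  df <- df[!duplicated(key), , drop = FALSE]
  homology_graph(vertices, data.frame(from = df$id_a, to = df$id_b))
}

#' Single-linkage clustering of the homology graph
#'
#' Clusters are exactly the connected components: any chain of pairwise
#' similarity places proteins in the same cluster, so no two proteins in
#' different clusters share an edge.
#'
#' @param graph a `homology_graph`.
#' @return object of class `cluster_partition`: named integer vector
#'   mapping protein id -> cluster id (1-based, ordered by first member).
#' @export
single_linkage_clusters <- function(graph) {
  stopifnot(inherits(graph, "homology_graph"))
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = data.frame(name = graph$vertices))
  comp <- igraph::components(g)$membership
  out <- as.integer(comp[graph$vertices])
  names(out) <- graph$vertices
  structure(out, class = "cluster_partition")
}

#' Assign clusters to cross-validation folds
#'
#' Clusters are placed greedily, largest first (ties broken in seeded random
#' order), onto whichever fold currently holds the fewest proteins. Whole
#' clusters are never split, so no homology edge can cross a fold boundary.
#' Large clusters are kept intact even when that leaves folds imbalanced.
#'
#' @param partition a `cluster_partition`.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling tie order.
#' @param allow_empty allow fewer clusters than folds? Default `FALSE`.
#' @return object of class `fold_assignment`: list with `protein_fold`
#'   (named integer, folds 1..k), `cluster_fold`, and `k`.
#' @export
assign_folds <- function(partition, k = 10L, seed = 1L, allow_empty = FALSE) {
  stopifnot(inherits(partition, "cluster_partition"), k >= 2L)
  sizes <- table(partition)
  if (length(sizes) < k && !allow_empty)
    stop(sprintf("only %d clusters for %d folds; set allow_empty = TRUE to proceed",
                 length(sizes), k))
  cl_ids <- as.integer(names(sizes))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  ord <- order(-as.integer(sizes), sample.int(length(sizes)))
  fold_load <- integer(k)
  cluster_fold <- integer(length(sizes))
  names(cluster_fold) <- as.character(cl_ids)
  for (idx in ord) {
    f <- which.min(fold_load)  # first smallest fold: deterministic
    cluster_fold[idx] <- f
    fold_load[f] <- fold_load[f] + as.integer(sizes[idx])
  }
  protein_fold <- cluster_fold[as.character(unclass(partition))]
  names(protein_fold) <- names(partition)
  structure(list(protein_fold = protein_fold, cluster_fold = cluster_fold, k = k),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  sizes <- tabulate(x$protein_fold, nbins = x$k)
  cat(sprintf("fold_assignment: %d proteins in %d folds (sizes: %s; max/mean = %.2f)\n",
              length(x$protein_fold), x$k, paste(sizes, collapse = ", "),
              max(sizes) / mean(sizes)))
  invisible(x)
}

#' Ten-fold rotation plan
#'
#' For k folds, produces k rotations: in rotation r, fold r is the test
#' fold, fold (r mod k) + 1 cross-trains (stops training and picks models),
#' and the remaining k-2 folds train. Each fold tests exactly once.
#'
#' @param folds a `fold_assignment`.
#' @return list of k lists with elements `test`, `crosstrain`, `train`
#'   (fold indices).
#' @export
crossval_splits <- function(folds) {
  stopifnot(inherits(folds, "fold_assignment"))
  k <- folds$k
  lapply(seq_len(k), function(r) {
    ct <- (r %% k) + 1L
    list(test = r, crosstrain = ct, train = setdiff(seq_len(k), c(r, ct)))
  })
}

#' Export a fold assignment to TSV
#' @param folds `fold_assignment`; `path` output file.
#' @param path output TSV path.
#' @export
write_fold_assignment <- function(folds, path) {
  utils::write.table(
    data.frame(protein_id = names(folds$protein_fold),
               fold = unname(folds$protein_fold)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Length-dependent homology threshold curve
#'
#' Percent-identity threshold above which two aligned sequences are
#' considered homologous, as a function of aligned length: `480 * L^-0.32`
#' for L <= 450, and 19.5 beyond. The difference
#' `identity - hssp_threshold(L)` is the HSSP-value of a pair; positive
#' values indicate identity above the curve.
#'
#' @param length aligned length(s).
#' @return numeric vector of identity thresholds (percent).
#' @export
hssp_threshold <- function(length) {
  stopifnot(all(length >= 1))
  ifelse(length <= 450, 480 * length^(-0.32), 19.5)
}

#' Mine neutral variants from same-function enzyme pairs
#'
#' If two enzymes independently carry the same experimentally assigned EC
#' number and are highly sequence similar, residues differing between them
#' are very likely neutral with respect to that function. For every pair
#' with percent identity > 40 and a positive HSSP-value
#' (`identity - hssp_curve(alignment length) > 0`), each aligned mismatch
#' column yields one neutral variant on the first protein of the pair
#' (wild-type = residue of protein 1, variant = residue of protein 2);
#' gap columns are skipped.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `ec`, `identity`
#'   (percent).
#' @param alignments function(id_a, id_b) returning
#'   `list(a = <aligned seq with gaps>, b = <aligned seq>)` or `NULL` when
#'   no alignment is available (pair skipped with a warning).
#' @param hssp_curve length -> identity-threshold function
#'   (default [hssp_threshold()]).
#' @return data.frame of neutral variants (protein_id, position, wt, var,
#'   label, source).
#' @export
mine_ec_neutral_variants <- function(pairs, alignments, hssp_curve = hssp_threshold) {
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    al <- alignments(p$id_a, p$id_b)
    if (is.null(al)) {
      warning(sprintf("no alignment for pair (%s, %s); skipped", p$id_a, p$id_b))
      next
    }
    a <- strsplit(al$a, "")[[1]]; b <- strsplit(al$b, "")[[1]]
    stopifnot(length(a) == length(b))
    alen <- sum(a != "-" & b != "-")
    if (alen < 1L) next
    if (!(p$identity > 40 && p$identity - hssp_curve(alen) > 0)) next
    pos_a <- cumsum(a != "-")
    keep <- which(a != "-" & b != "-" & a != b)
    if (length(keep))
      out[[length(out) + 1L]] <- data.frame(
        protein_id = p$id_a, position = pos_a[keep],
        wt = a[keep], var = b[keep],
        label = "neutral", source = paste0("EC:", p$ec),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(protein_id = character(0), position = integer(0),
                      wt = character(0), var = character(0),
                      label = character(0), source = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
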
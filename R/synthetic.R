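# Synthetic proteins, homology families, and labeled variants with a
# planted, feature-expressible effect signal.
#
# The planted rule drives labels through quantities the built-in feature
# providers actually compute: a substitution is "effect" exactly when its
# position is critical (interior of the chain, as measured by the terminus
# proximity feature) AND its Kyte-Doolittle hydropathy change exceeds a
# threshold. Labels are then flipped independently at a configured noise
# rate, and the class mix is rebalanced toward the configured effect
# fraction (default 60:40 effect:neutral, mirroring the composition of
# experimentally annotated variant collections).

#' Synthetic-data configuration
#'
#' @param seed master seed; every downstream draw derives from it.
#' @param n_families number of homologous protein families.
#' @param family_size proteins per family.
#' @param protein_length_range (min, max) protein lengths.
#' @param n_variants labeled variants to generate.
#' @param effect_fraction target fraction of "effect" labels (default 0.6).
#' @param noise_rate independent label-flip probability in [0, 0.5).
#' @param critical_position_fraction fraction of interior positions whose
#'   substitutions can have an effect.
#' @param delta_threshold hydropathy-change magnitude (Kyte-Doolittle
#'   units) above which a substitution at a critical position is an effect.
#' @param mutation_rate per-residue mutation rate when deriving family
#'   members from the founder (0.1-0.3 keeps within-family identity above,
#'   and cross-family identity below, the default homology edge threshold).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 42L, n_families = 10L, family_size = 3L,
                             protein_length_range = c(80L, 150L),
                             n_variants = 2000L, effect_fraction = 0.6,
                             noise_rate = 0.05,
                             critical_position_fraction = 0.5,
                             delta_threshold = 2, mutation_rate = 0.2) {
  stopifnot(n_families >= 1L, family_size >= 1L,
            length(protein_length_range) == 2L,
            protein_length_range[1] >= 30L,
            protein_length_range[2] >= protein_length_range[1],
            n_variants >= 1L,
            effect_fraction > 0, effect_fraction < 1,
            noise_rate >= 0, noise_rate < 0.5,
            critical_position_fraction > 0, critical_position_fraction <= 1,
            delta_threshold >= 0,
            mutation_rate >= 0.1, mutation_rate <= 0.3)
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 family_size = as.integer(family_size),
                 protein_length_range = as.integer(protein_length_range),
                 n_variants = as.integer(n_variants),
                 effect_fraction = effect_fraction, noise_rate = noise_rate,
                 critical_position_fraction = critical_position_fraction,
                 delta_threshold = delta_threshold,
                 mutation_rate = mutation_rate),
            class = "synthetic_config")
}

#' Generate synthetic protein families
#'
#' Each family starts from a random founder sequence; members are derived
#' by substituting each residue independently with probability
#' `mutation_rate`. Within-family pairs therefore stay well above the
#' built-in homology edge threshold, while unrelated families fall below
#' it, so single-linkage clustering recovers the families.
#'
#' @param config a [synthetic_config()].
#' @return list with `proteins` ([Biostrings::AAStringSet]) and `families`
#'   (named integer vector protein id -> family).
#' @export
generate_proteins <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.child_seed(config$seed, 1L))
  seqs <- character(0); fam <- integer(0)
  for (f in seq_len(config$n_families)) {
    L <- sample(seq.int(config$protein_length_range[1],
                        config$protein_length_range[2]), 1L)
    founder <- sample(AA_ALPHABET, L, replace = TRUE)
    for (m in seq_len(config$family_size)) {
      s <- founder
      mut <- which(stats::runif(L) < config$mutation_rate)
      if (length(mut))
        s[mut] <- vapply(s[mut], function(a) sample(setdiff(AA_ALPHABET, a), 1L),
                         character(1))
      id <- sprintf("fam%02d_p%d", f, m)
      seqs[id] <- paste(s, collapse = "")
      fam[id] <- f
    }
  }
  proteins <- Biostrings::AAStringSet(seqs)
  names(proteins) <- names(seqs)
  list(proteins = proteins, families = fam)
}

# The planted ground-truth rule for one substitution.
.planted_effect <- function(seq_chars, position, wt, var, config) {
  L <- length(seq_chars)
  terminus <- min(position, L - position + 1) / ((L + 1) / 2)
  critical <- terminus > (1 - config$critical_position_fraction)
  dh <- abs(.AA_HYDROPATHY[wt] - .AA_HYDROPATHY[var])
  critical && dh > config$delta_threshold
}

#' Generate labeled synthetic variants
#'
#' Draws substitutions uniformly over proteins, positions and variant
#' residues, labels them by the planted rule (effect iff the position is
#' critical and the hydropathy change exceeds the threshold), flips each
#' label independently with probability `noise_rate`, and rebalances the
#' class mix toward `effect_fraction` by rejection sampling. Duplicate
#' substitutions are never emitted.
#'
#' @param config a [synthetic_config()].
#' @param proteins result of [generate_proteins()] (or compatible
#'   `AAStringSet`).
#' @return a [variant_dataset()] with the true (pre-noise) labels stored
#'   in the `true_label` column of `$variants`.
#' @export
generate_variants <- function(config, proteins) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.list(proteins) && !is.null(proteins$proteins))
    proteins <- proteins$proteins
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.child_seed(config$seed, 2L))
  ids <- names(proteins)
  chars <- lapply(as.character(proteins), function(s) strsplit(s, "")[[1]])
  n_eff <- round(config$n_variants * config$effect_fraction)
  n_neu <- config$n_variants - n_eff
  got_eff <- 0L; got_neu <- 0L
  seen <- character(0)
  rows <- vector("list", config$n_variants)
  n_rows <- 0L
  max_tries <- 500L * config$n_variants
  tries <- 0L
  while ((got_eff < n_eff || got_neu < n_neu) && tries < max_tries) {
    tries <- tries + 1L
    id <- ids[sample.int(length(ids), 1L)]
    s <- chars[[id]]
    pos <- sample.int(length(s), 1L)
    wt <- s[pos]
    var <- sample(setdiff(AA_ALPHABET, wt), 1L)
    key <- paste(id, pos, var, sep = "|")
    if (key %in% seen) next
    true_eff <- .planted_effect(s, pos, wt, var, config)
    obs_eff <- if (stats::runif(1) < config$noise_rate) !true_eff else true_eff
    if (obs_eff) {
      if (got_eff >= n_eff) next
      got_eff <- got_eff + 1L
    } else {
      if (got_neu >= n_neu) next
      got_neu <- got_neu + 1L
    }
    seen <- c(seen, key)
    n_rows <- n_rows + 1L
    rows[[n_rows]] <- data.frame(
      protein_id = id, position = pos, wt = wt, var = var,
      label = if (obs_eff) "effect" else "neutral",
      source = "synthetic",
      true_label = if (true_eff) "effect" else "neutral",
      stringsAsFactors = FALSE)
  }
  if (got_eff < n_eff || got_neu < n_neu)
    stop(sprintf(paste0("could not reach effect fraction %.2f: drew %d effect ",
                        "and %d neutral variants in %d tries; adjust the rule ",
                        "parameters or n_variants"),
                 config$effect_fraction, got_eff, got_neu, tries))
  variants <- do.call(rbind, rows[seq_len(n_rows)])
  ds <- variant_dataset(proteins, variants)
  ds
}

#' One-call synthetic study
#'
#' Generates proteins and variants and the matching homology-aware fold
#' assignment in one step.
#'
#' @param config a [synthetic_config()].
#' @return list(dataset, folds, families).
#' @export
generate_study <- function(config = synthetic_config()) {
  prot <- generate_proteins(config)
  ds <- generate_variants(config, prot)
  graph <- build_homology_graph(prot$proteins)
  folds <- assign_folds(single_linkage_clusters(graph), k = 10L,
                        seed = config$seed)
  list(dataset = ds, folds = folds, families = prot$families)
}

#' Worked confusion tables with independently computed metrics
#'
#' Emits fixture confusion tables — including the canonical
#' TP=40/FP=20/TN=30/FN=10 case, the perfect table and the fully symmetric
#' table — each carrying metric values computed here by direct arithmetic
#' on the counts, independent of the metric implementations they are used
#' to check.
#'
#' @param seed seed for the additional random tables.
#' @param n_random number of extra random tables.
#' @return list of entries: list(counts = confusion table, expected =
#'   named metric values).
#' @export
worked_confusion_tables <- function(seed = 1L, n_random = 10L) {
  direct <- function(tp, fp, tn, fn) {
    pe <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    re <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    pn <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    rn <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    fe <- if (!is.na(pe) && !is.na(re) && pe + re > 0) 2 * pe * re / (pe + re) else NA_real_
    fnu <- if (!is.na(pn) && !is.na(rn) && pn + rn > 0) 2 * pn * rn / (pn + rn) else NA_real_
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    m <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else NA_real_
    c(accuracy_effect = pe, coverage_effect = re, accuracy_neutral = pn,
      coverage_neutral = rn, F_effect = fe, F_neutral = fnu,
      Q2 = (tp + tn) / (tp + fp + tn + fn), MCC = m)
  }
  make <- function(tp, fp, tn, fn)
    list(counts = confusion_table(tp, fp, tn, fn),
         expected = direct(tp, fp, tn, fn))
  out <- list(canonical = make(40, 20, 30, 10),
              perfect = make(50, 0, 50, 0),
              symmetric = make(25, 25, 25, 25))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  for (i in seq_len(n_random)) {
    cts <- stats::rpois(4, lambda = 25) + 1L
    out[[sprintf("random%02d", i)]] <- make(cts[1], cts[2], cts[3], cts[4])
  }
  out
}

#' Pure-noise control feature provider
#'
#' A per-residue provider whose value is a deterministic pseudo-random hash
#' of (protein, position): reproducible, bounded, and independent of any
#' biological signal. Used as the uninformative control when validating
#' feature selection.
#'
#' @param seed integer mixed into the hash.
#' @return a per-residue feature provider.
#' @export
noise_feature_provider <- function(seed = 1L) {
  .provider("noise", "per_residue", "noise",
            function(s, pos) {
              id <- attr(s, "protein_id")
              if (is.null(id)) id <- paste(s[1:min(5, length(s))], collapse = "")
              h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) +
                pos * 2654435761 + seed * 97
              (h %% 100003) / 100003 - 0.5
            })
}
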
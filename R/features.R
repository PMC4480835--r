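# Feature providers, sliding-window encoding, delta features, and assembly
# of per-variant feature matrices.
#
# A provider computes raw numeric values; a descriptor names a provider
# together with a window size. Three provider kinds exist:
#   per_residue: f(seq_chars, position) -> numeric; windowed around the
#                variant position with zero-padding plus explicit per-cell
#                padding indicators
#   pairwise:    f(seq_chars, position, wt, var) -> numeric; one value set
#                per substitution (delta features live here)
#   global:      f(seq_chars) -> numeric; whole-protein features
# Providers signal a missing value with NA; rows containing NA are excluded
# from the assembled matrix (never imputed) with a logged count.

ALLOWED_WINDOWS <- c(1L, 5L, 9L, 13L, 17L, 21L)

.aa_lookup <- function(values) {
  stopifnot(setequal(names(values), AA_ALPHABET))
  values[AA_ALPHABET]
}

.provider <- function(name, kind, value_names, fn) {
  structure(list(name = name, kind = kind, value_names = value_names,
                 n_values = length(value_names), fn = fn),
            class = "feature_provider")
}

.biophys_values <- function(aa) {
  c(charge = unname(.AA_CHARGE[aa]),
    hydropathy = unname(.AA_HYDROPATHY[aa]),
    volume = unname(.AA_VOLUME[aa]))
}

.aaindex_values <- function(aa) {
  c(mw = unname(.AA_MW[aa]),
    aromatic = unname(.AA_AROMATIC[aa]),
    aliphatic = unname(.AA_ALIPHATIC[aa]))
}

.onehot <- function(aa) as.numeric(AA_ALPHABET == aa)

#' Contact-potential feature for a substitution
#'
#' Given a symmetric 20x20 residue-pair potential, returns the wild-type
#' residue's row, the variant residue's row, and their difference
#' (native minus variant): 60 values.
#'
#' @param wt,var amino-acid letters.
#' @param potential_table symmetric 20x20 matrix with residue dimnames
#'   (default the package's synthetic hydropathy-derived surrogate,
#'   [contact_potential_matrix()]).
#' @return numeric vector of length 60.
#' @export
contact_potential_feature <- function(wt, var,
                                      potential_table = contact_potential_matrix()) {
  if (!isTRUE(all.equal(potential_table, t(potential_table))))
    stop("contact potential table must be symmetric")
  stopifnot(wt %in% AA_ALPHABET, var %in% AA_ALPHABET)
  wrow <- potential_table[wt, AA_ALPHABET]
  vrow <- potential_table[var, AA_ALPHABET]
  out <- c(wrow, vrow, wrow - vrow)
  names(out) <- c(paste0("wt.", AA_ALPHABET), paste0("var.", AA_ALPHABET),
                  paste0("delta.", AA_ALPHABET))
  out
}

#' Elementwise delta feature
#'
#' Difference between a feature's values for the native residue and the
#' variant residue (native minus variant).
#'
#' @param feature_native,feature_variant equal-length numeric vectors.
#' @return numeric vector.
#' @export
compute_delta <- function(feature_native, feature_variant) {
  if (length(feature_native) != length(feature_variant))
    stop("delta inputs differ in length")
  feature_native - feature_variant
}

#' Global protein features
#'
#' 20-bin amino-acid composition (sums to 1), protein length scaled to
#' `min(L, 1000)/1000`, and — when per-residue structure states are
#' supplied — 3-state secondary-structure and 2-state accessibility
#' compositions. Without a structure provider those cells are absent
#' (NA markers), never zero.
#'
#' @param protein character scalar sequence or `AAString`.
#' @param structure_states optional data.frame with columns `ss`
#'   (H/E/C per residue) and `acc` (b/e per residue).
#' @return named numeric vector.
#' @export
global_features <- function(protein, structure_states = NULL) {
  s <- strsplit(toupper(as.character(protein)), "")[[1]]
  comp <- as.numeric(table(factor(s, levels = AA_ALPHABET))) / length(s)
  names(comp) <- paste0("comp.", AA_ALPHABET)
  out <- c(comp, length = min(length(s), 1000) / 1000)
  if (is.null(structure_states)) {
    ss <- rep(NA_real_, 5)
  } else {
    stopifnot(nrow(structure_states) == length(s))
    ss3 <- as.numeric(table(factor(structure_states$ss, levels = c("H", "E", "C")))) / length(s)
    acc2 <- as.numeric(table(factor(structure_states$acc, levels = c("b", "e")))) / length(s)
    ss <- c(ss3, acc2)
  }
  names(ss) <- c("ss.H", "ss.E", "ss.C", "acc.b", "acc.e")
  c(out, ss)
}

#' Built-in provider registry
#'
#' Maps provider names to feature providers. Built-ins:
#' \describe{
#'   \item{biophys}{per-residue charge, hydropathy, volume}
#'   \item{aaindex}{per-residue molecular weight, aromatic and aliphatic
#'     indicators (a small curated index subset)}
#'   \item{onehot}{per-residue 20-way sequence identity}
#'   \item{terminus}{per-residue proximity to the nearest chain terminus,
#'     `min(i, L-i+1)` scaled to (0, 1]}
#'   \item{biophys_delta, aaindex_delta}{native-minus-variant deltas of the
#'     corresponding per-residue scales}
#'   \item{onehot_pair}{40-way one-hot encoding of (wild-type, variant)}
#'   \item{contact}{wild-type row, variant row and delta of a symmetric
#'     contact-potential table}
#'   \item{composition}{global amino-acid composition plus scaled length}
#'   \item{effect_matrix}{derived effect-probability of the substitution
#'     (present only when `effect_matrix` is supplied)}
#' }
#' Precomputed per-residue profiles (evolutionary or structural) plug in
#' through `profiles`: one provider per distinct `feature_name`, returning
#' NA for proteins/positions without a value (those variant rows are then
#' excluded at assembly).
#'
#' @param effect_matrix optional [derive_effect_matrix()] result.
#' @param profiles optional data.frame(protein_id, position, feature_name,
#'   value) of precomputed per-residue features (see [read_profile_table()]).
#' @param contact_table symmetric 20x20 potential for the `contact` provider.
#' @return named list of providers (class `provider_registry`).
#' @export
default_registry <- function(effect_matrix = NULL, profiles = NULL,
                             contact_table = contact_potential_matrix()) {
  reg <- list(
    biophys = .provider("biophys", "per_residue",
                        c("charge", "hydropathy", "volume"),
                        function(s, pos) .biophys_values(s[pos])),
    aaindex = .provider("aaindex", "per_residue",
                        c("mw", "aromatic", "aliphatic"),
                        function(s, pos) .aaindex_values(s[pos])),
    onehot = .provider("onehot", "per_residue", paste0("aa.", AA_ALPHABET),
                       function(s, pos) .onehot(s[pos])),
    terminus = .provider("terminus", "per_residue", "terminus",
                         function(s, pos) {
                           L <- length(s)
                           min(pos, L - pos + 1) / ((L + 1) / 2)
                         }),
    biophys_delta = .provider("biophys_delta", "pairwise",
                              c("d.charge", "d.hydropathy", "d.volume"),
                              function(s, pos, wt, var)
                                compute_delta(.biophys_values(wt), .biophys_values(var))),
    aaindex_delta = .provider("aaindex_delta", "pairwise",
                              c("d.mw", "d.aromatic", "d.aliphatic"),
                              function(s, pos, wt, var)
                                compute_delta(.aaindex_values(wt), .aaindex_values(var))),
    onehot_pair = .provider("onehot_pair", "pairwise",
                            c(paste0("wt.", AA_ALPHABET), paste0("var.", AA_ALPHABET)),
                            function(s, pos, wt, var) c(.onehot(wt), .onehot(var))),
    contact = .provider("contact", "pairwise",
                        names(contact_potential_feature("A", "C", contact_table)),
                        local({
                          tbl <- contact_table
                          function(s, pos, wt, var) contact_potential_feature(wt, var, tbl)
                        })),
    composition = .provider("composition", "global",
                            c(paste0("comp.", AA_ALPHABET), "length"),
                            function(s) {
                              g <- global_features(paste(s, collapse = ""))
                              g[1:21]
                            })
  )
  if (!is.null(effect_matrix)) {
    em <- effect_matrix
    reg$effect_matrix <- .provider("effect_matrix", "pairwise", "effect_prob",
                                   function(s, pos, wt, var) matrix_feature(em, wt, var))
  }
  if (!is.null(profiles)) {
    stopifnot(all(c("protein_id", "position", "feature_name", "value") %in% names(profiles)))
    for (fname in unique(profiles$feature_name)) {
      sub <- profiles[profiles$feature_name == fname, , drop = FALSE]
      lut <- stats::setNames(sub$value, paste(sub$protein_id, sub$position, sep = "@"))
      reg[[paste0("profile.", fname)]] <- local({
        lut0 <- lut
        .provider(paste0("profile.", fname), "per_residue", fname,
                  function(s, pos) {
                    v <- lut0[paste(attr(s, "protein_id"), pos, sep = "@")]
                    unname(v)  # NA when absent
                  })
      })
    }
  }
  class(reg) <- "provider_registry"
  reg
}

#' Read a per-residue profile table
#'
#' TSV with columns protein_id, position, feature_name, value — one row per
#' (protein, position, feature) cell of a precomputed evolutionary or
#' structural profile.
#'
#' @param path TSV path.
#' @return data.frame usable as the `profiles` argument of
#'   [default_registry()].
#' @export
read_profile_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "position", "feature_name", "value") %in% names(df)))
  df$position <- as.integer(df$position)
  df$value <- as.numeric(df$value)
  df
}

#' Feature descriptor
#'
#' Names one provider at one window size. Only per-residue providers are
#' windowed; pairwise and global providers always use window 1.
#'
#' @param provider provider name (must resolve in the registry at assembly).
#' @param window odd window size in {1, 5, 9, 13, 17, 21}.
#' @param name optional display name; defaults to `provider.wN`.
#' @return object of class `feature_descriptor`.
#' @export
feature_descriptor <- function(provider, window = 1L, name = NULL) {
  window <- as.integer(window)
  if (!window %in% ALLOWED_WINDOWS)
    stop("window must be one of ", paste(ALLOWED_WINDOWS, collapse = ", "))
  if (is.null(name)) name <- sprintf("%s.w%d", provider, window)
  structure(list(name = name, provider = provider, window = window),
            class = "feature_descriptor")
}

#' Default descriptor set
#'
#' The compact feature set used by [vepnet()] unless told otherwise:
#' per-residue biophysical triple at the variant position, its
#' native-minus-variant delta, and proximity to the nearest terminus.
#'
#' @return list of [feature_descriptor()]s.
#' @export
default_descriptors <- function() {
  list(feature_descriptor("biophys", 1L),
       feature_descriptor("biophys_delta", 1L),
       feature_descriptor("terminus", 1L))
}

#' Alignment-free descriptor profile
#'
#' The candidate set for the alignment-free mode: global composition and
#' length, wild-type/variant identity, contact-potential profile and delta,
#' biophysical scales and deltas, curated index scales, and — when a
#' derived effect-probability matrix is available in the registry — the
#' substitution's effect probability. No evolutionary-profile provider
#' appears here.
#'
#' @param with_effect_matrix include the `effect_matrix` descriptor?
#' @return list of [feature_descriptor()]s.
#' @export
noali_descriptors <- function(with_effect_matrix = TRUE) {
  d <- list(feature_descriptor("composition", 1L),
            feature_descriptor("onehot_pair", 1L),
            feature_descriptor("contact", 1L),
            feature_descriptor("biophys", 1L),
            feature_descriptor("biophys_delta", 1L),
            feature_descriptor("aaindex", 1L),
            feature_descriptor("aaindex_delta", 1L),
            feature_descriptor("terminus", 1L))
  if (with_effect_matrix) d <- c(d, list(feature_descriptor("effect_matrix", 1L)))
  d
}

#' Sliding-window encoding of a per-residue feature
#'
#' Collects the provider's values for the `w` residues centred on
#' `position`. Cells falling outside the sequence are zero-filled, and one
#' explicit padding indicator per window cell records which cells were
#' padded. The result always has length `w * n_values + w`.
#'
#' @param protein sequence (character scalar or `AAString`).
#' @param position 1-based centre position.
#' @param w window size in {1, 5, 9, 13, 17, 21}.
#' @param per_residue_feature a per-residue provider.
#' @return numeric vector: `w` blocks of provider values followed by `w`
#'   padding indicators.
#' @export
encode_window <- function(protein, position, w, per_residue_feature) {
  w <- as.integer(w)
  if (!w %in% ALLOWED_WINDOWS) stop("invalid window size: ", w)
  s <- strsplit(toupper(as.character(protein)), "")[[1]]
  stopifnot(position >= 1L, position <= length(s))
  half <- (w - 1L) %/% 2L
  offs <- seq.int(position - half, position + half)
  p <- per_residue_feature$n_values
  vals <- numeric(w * p)
  pad <- numeric(w)
  for (i in seq_len(w)) {
    if (offs[i] < 1L || offs[i] > length(s)) {
      pad[i] <- 1
    } else {
      vals[((i - 1L) * p + 1L):(i * p)] <- per_residue_feature$fn(s, offs[i])
    }
  }
  c(vals, pad)
}

# Column layout for a descriptor list: data.frame(column, descriptor,
# provider, window_offset, subfeature, is_pad). A pure function of the
# descriptor list and registry.
feature_layout <- function(descriptors, registry) {
  rows <- list()
  for (d in descriptors) {
    prov <- registry[[d$provider]]
    if (is.null(prov)) stop("unresolved provider: ", d$provider)
    if (prov$kind == "per_residue") {
      half <- (d$window - 1L) %/% 2L
      offsets <- seq.int(-half, half)
      for (o in offsets) for (v in prov$value_names)
        rows[[length(rows) + 1L]] <- data.frame(
          descriptor = d$name, provider = d$provider, window_offset = o,
          subfeature = v, is_pad = FALSE, stringsAsFactors = FALSE)
      for (o in offsets)
        rows[[length(rows) + 1L]] <- data.frame(
          descriptor = d$name, provider = d$provider, window_offset = o,
          subfeature = "pad", is_pad = TRUE, stringsAsFactors = FALSE)
    } else {
      if (d$window != 1L)
        stop(sprintf("descriptor '%s': %s providers take window 1", d$name, prov$kind))
      for (v in prov$value_names)
        rows[[length(rows) + 1L]] <- data.frame(
          descriptor = d$name, provider = d$provider, window_offset = 0L,
          subfeature = v, is_pad = FALSE, stringsAsFactors = FALSE)
    }
  }
  lay <- do.call(rbind, rows)
  lay$column <- sprintf("%s.o%+d.%s", lay$descriptor, lay$window_offset, lay$subfeature)
  lay
}

# Encode one variant against a layout. seq_chars carries attr protein_id for
# profile providers.
.encode_variant <- function(seq_chars, position, wt, var, descriptors, registry) {
  out <- numeric(0)
  L <- length(seq_chars)
  for (d in descriptors) {
    prov <- registry[[d$provider]]
    if (prov$kind == "per_residue") {
      w <- d$window; half <- (w - 1L) %/% 2L
      offs <- seq.int(position - half, position + half)
      vals <- numeric(w * prov$n_values); pad <- numeric(w)
      for (i in seq_len(w)) {
        if (offs[i] < 1L || offs[i] > L) pad[i] <- 1
        else vals[((i - 1L) * prov$n_values + 1L):(i * prov$n_values)] <-
            prov$fn(seq_chars, offs[i])
      }
      out <- c(out, vals, pad)
    } else if (prov$kind == "pairwise") {
      out <- c(out, prov$fn(seq_chars, position, wt, var))
    } else {
      out <- c(out, prov$fn(seq_chars))
    }
  }
  out
}

#' Assemble the per-variant feature matrix
#'
#' Encodes every variant of the dataset against the descriptor list with a
#' deterministic column layout (descriptor order, then window position,
#' then sub-feature, padding indicators last within each windowed block).
#' Rows containing a missing value from any provider (e.g. an absent
#' external profile) are excluded — never imputed — with a logged count.
#'
#' When `normalize = TRUE`, per-column z-score parameters are fitted on
#' `fit_rows` only (default: all kept rows) and stored; padding-indicator
#' columns are left on their raw 0/1 scale. Use [apply_normalization()] to
#' reuse stored parameters on new rows.
#'
#' @param dataset a [variant_dataset()].
#' @param descriptors list of [feature_descriptor()]s.
#' @param registry a [default_registry()] (or compatible).
#' @param normalize fit and apply z-score parameters? Default `TRUE`.
#' @param fit_rows indices (into the kept rows) used to fit normalization.
#' @return object of class `feature_matrix`: list(x, layout, norm,
#'   variants, excluded).
#' @export
assemble_feature_matrix <- function(dataset, descriptors, registry,
                                    normalize = TRUE, fit_rows = NULL) {
  stopifnot(inherits(dataset, "variant_dataset"))
  lay <- feature_layout(descriptors, registry)
  v <- dataset$variants
  seq_cache <- lapply(as.character(dataset$proteins), function(s) strsplit(s, "")[[1]])
  for (id in names(seq_cache)) attr(seq_cache[[id]], "protein_id") <- id

  x <- matrix(NA_real_, nrow = nrow(v), ncol = nrow(lay),
              dimnames = list(NULL, lay$column))
  for (i in seq_len(nrow(v)))
    x[i, ] <- .encode_variant(seq_cache[[v$protein_id[i]]], v$position[i],
                              v$wt[i], v$var[i], descriptors, registry)

  bad <- which(apply(x, 1L, function(r) any(!is.finite(r))))
  if (length(bad)) {
    message(sprintf("excluding %d variant row(s) with missing feature values", length(bad)))
    x <- x[-bad, , drop = FALSE]
    v <- v[-bad, , drop = FALSE]
  }

  norm <- NULL
  if (normalize) {
    norm <- fit_normalization(x, rows = fit_rows, is_pad = lay$is_pad)
    x <- apply_normalization(x, norm)
  }
  structure(list(x = x, layout = lay, norm = norm, variants = v,
                 descriptors = descriptors, excluded = bad),
            class = "feature_matrix")
}

#' Fit per-column z-score parameters
#'
#' @param x numeric matrix.
#' @param rows row indices to fit on (default all).
#' @param is_pad logical vector flagging padding-indicator columns, which
#'   are left unscaled.
#' @return list(center, scale) with one entry per column.
#' @export
fit_normalization <- function(x, rows = NULL, is_pad = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(x))
  if (is.null(is_pad)) is_pad <- rep(FALSE, ncol(x))
  xs <- x[rows, , drop = FALSE]
  center <- colMeans(xs)
  scale <- apply(xs, 2L, stats::sd)
  center[is_pad] <- 0; scale[is_pad] <- 1
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

#' Apply stored z-score parameters
#' @param x numeric matrix with the layout the parameters were fitted on.
#' @param norm list(center, scale) from [fit_normalization()].
#' @return normalized matrix.
#' @export
apply_normalization <- function(x, norm) {
  stopifnot(ncol(x) == length(norm$center))
  sweep(sweep(x, 2L, norm$center, "-"), 2L, norm$scale, "/")
}
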
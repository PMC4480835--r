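# In-silico saturation mutagenesis and the derived effect-probability
# substitution matrix backing the alignment-free mode.

#' Saturation mutagenesis predictions
#'
#' Predicts all 19 possible substitutions at every residue position of the
#' given proteins, in deterministic order (protein order, then position,
#' then variant residue alphabetically).
#'
#' @param ensemble a fitted [vepnet()] model.
#' @param proteins [Biostrings::AAStringSet].
#' @return `vep_predictions` data.frame, 19 rows per residue.
#' @export
saturation_predict <- function(ensemble, proteins) {
  stopifnot(inherits(ensemble, "vepnet"))
  rows <- list()
  for (id in names(proteins)) {
    s <- strsplit(as.character(proteins[[id]]), "")[[1]]
    for (pos in seq_along(s)) {
      vars <- setdiff(AA_ALPHABET, s[pos])
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, position = pos, wt = s[pos], var = vars,
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)
  ds <- variant_dataset(proteins, variants)
  predict(ensemble, ds)
}

#' Derive the effect-probability substitution matrix
#'
#' For every ordered residue pair (wt, var), the cell holds the fraction of
#' wt->var predictions classified "effect" at the given threshold, with a
#' companion support count. Cells without any supporting prediction are
#' undefined (NA), never 0; the diagonal is undefined by construction.
#'
#' @param results `vep_predictions` (e.g. from [saturation_predict()]).
#' @param threshold decision threshold on the raw averaged-output
#'   difference (default -0.05).
#' @return object of class `effect_matrix`: list(prob, support), both
#'   20x20 matrices with residue dimnames.
#' @export
derive_effect_matrix <- function(results, threshold = -0.05) {
  if (is.null(results) || nrow(results) == 0L) stop("no predictions supplied")
  stopifnot(all(c("wt", "var", "avg_neutral", "avg_effect") %in% names(results)))
  eff <- (results$avg_effect - results$avg_neutral) > threshold
  prob <- matrix(NA_real_, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  support <- matrix(0L, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  agg <- stats::aggregate(eff, by = list(wt = results$wt, var = results$var),
                          FUN = function(z) c(mean(z), length(z)))
  for (i in seq_len(nrow(agg))) {
    w <- agg$wt[i]; v <- agg$var[i]
    prob[w, v] <- agg$x[i, 1]
    support[w, v] <- as.integer(agg$x[i, 2])
  }
  structure(list(prob = prob, support = support), class = "effect_matrix")
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat(sprintf("effect_matrix: %d/380 cells supported (mean effect probability %.3f)\n",
              sum(!is.na(x$prob)), mean(x$prob, na.rm = TRUE)))
  invisible(x)
}

#' Effect-probability feature for one substitution
#'
#' Looks up the derived matrix cell for (wt, var); undefined cells yield
#' NA, which the feature-assembly missing-value policy then excludes
#' rather than imputes.
#'
#' @param matrix an `effect_matrix`.
#' @param wt,var amino-acid letters.
#' @return probability in [0, 1] or NA.
#' @export
matrix_feature <- function(matrix, wt, var) {
  stopifnot(inherits(matrix, "effect_matrix"),
            wt %in% AA_ALPHABET, var %in% AA_ALPHABET)
  unname(matrix$prob[wt, var])
}

#' Write / read an effect matrix as TSV
#'
#' The probability matrix is written to `path` and the support counts to
#' `paste0(path, ".support")`, both as 20x20 tables with residue headers.
#'
#' @param matrix an `effect_matrix`.
#' @param path output TSV path.
#' @export
write_effect_matrix <- function(matrix, path) {
  utils::write.table(matrix$prob, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(matrix$support, paste0(path, ".support"), sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_effect_matrix
#' @export
read_effect_matrix <- function(path) {
  prob <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  support <- as.matrix(utils::read.delim(paste0(path, ".support"),
                                         row.names = 1, check.names = FALSE))
  stopifnot(identical(rownames(prob), AA_ALPHABET),
            identical(colnames(prob), AA_ALPHABET))
  storage.mode(support) <- "integer"
  structure(list(prob = prob, support = support), class = "effect_matrix")
}
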
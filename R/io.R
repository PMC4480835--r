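# Readers/writers and the variant data model.
#
# Positions are 1-based everywhere, matching the compact substitution token
# style (e.g. "R109Q": arginine at position 109 replaced by glutamine).

VALID_LABELS <- c("neutral", "effect", "unlabeled")

#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()]. Identifiers are the first
#' whitespace-delimited token of each header; sequences are upper-cased.
#'
#' In strict mode (default) any character outside the canonical 20-letter
#' alphabet is an error naming the offending record and position. In lenient
#' mode non-canonical residues (B, Z, X, U, O, ...) are mapped to `X`;
#' variants at such positions are rejected downstream at validation.
#'
#' @param path FASTA file path.
#' @param strict reject non-canonical residues? Default `TRUE`.
#' @return [Biostrings::AAStringSet] named by identifier.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate sequence identifiers in ", path)
  chars <- toupper(as.character(seqs))
  for (i in seq_along(chars)) {
    bad <- which(!strsplit(chars[i], "")[[1]] %in% AA_ALPHABET)
    if (length(bad)) {
      if (strict)
        stop(sprintf("non-canonical residue in '%s' at position %d", ids[i], bad[1]))
      s <- strsplit(chars[i], "")[[1]]
      s[bad] <- "X"
      chars[i] <- paste(s, collapse = "")
    }
  }
  out <- Biostrings::AAStringSet(chars)
  names(out) <- ids
  out
}

#' Parse a substitution token
#'
#' Decomposes a token of the form `<wt><position><var>`, e.g. `"R109Q"`,
#' into its parts. Positions are 1-based.
#'
#' @param token character scalar like `"R109Q"`.
#' @return list with elements `wt`, `position` (integer), `var`.
#' @examples
#' parse_variant_token("R109Q")
#' @export
parse_variant_token <- function(token) {
  if (length(token) != 1L || !is.character(token))
    stop("token must be a single character string")
  m <- regmatches(token, regexec("^([A-Z])([0-9]+)([A-Z])$", token))[[1]]
  if (length(m) != 4L)
    stop("malformed substitution token: ", deparse(token))
  wt <- m[2]; pos <- as.integer(m[3]); var <- m[4]
  if (!wt %in% AA_ALPHABET || !var %in% AA_ALPHABET)
    stop("non-canonical residue in token: ", token)
  if (is.na(pos) || pos < 1L) stop("position must be >= 1 in token: ", token)
  if (wt == var) stop("degenerate substitution (wild-type equals variant): ", token)
  list(wt = wt, position = pos, var = var)
}

#' Format a substitution token
#'
#' Inverse of [parse_variant_token()].
#' @param wt,position,var substitution parts.
#' @return character vector of tokens.
#' @export
format_variant_token <- function(wt, position, var) {
  paste0(wt, position, var)
}

#' Construct a variant dataset
#'
#' Bundles a set of protein sequences with a table of single amino-acid
#' substitutions, validating every variant against its sequence and
#' collapsing duplicate (protein, position, wt, var) rows.
#'
#' @param proteins [Biostrings::AAStringSet] named by protein id.
#' @param variants data.frame with columns `protein_id`, `position`, `wt`,
#'   `var` and optionally `label` (one of neutral/effect/unlabeled) and
#'   `source`.
#' @return object of class `variant_dataset`: a list with elements
#'   `proteins` and `variants`.
#' @export
variant_dataset <- function(proteins, variants) {
  stopifnot(methods::is(proteins, "AAStringSet"))
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("proteins must be uniquely named")
  need <- c("protein_id", "position", "wt", "var")
  if (!all(need %in% names(variants)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  variants$protein_id <- as.character(variants$protein_id)
  variants$position <- as.integer(variants$position)
  if (is.null(variants$label)) variants$label <- "unlabeled"
  variants$label[is.na(variants$label) | variants$label == ""] <- "unlabeled"
  bad_lab <- !variants$label %in% VALID_LABELS
  if (any(bad_lab))
    stop("invalid label(s): ", paste(unique(variants$label[bad_lab]), collapse = ", "))
  if (is.null(variants$source)) variants$source <- ""

  seqs <- as.character(proteins)
  unknown <- which(!variants$protein_id %in% names(seqs))
  if (length(unknown))
    stop(sprintf("row %d: unknown protein_id '%s'",
                 unknown[1], variants$protein_id[unknown[1]]))
  lens <- nchar(seqs)[variants$protein_id]
  oob <- which(variants$position < 1L | variants$position > lens)
  if (length(oob))
    stop(sprintf("row %d: position %d outside 1..%d for '%s'",
                 oob[1], variants$position[oob[1]], lens[oob[1]],
                 variants$protein_id[oob[1]]))
  at <- substr(seqs[variants$protein_id], variants$position, variants$position)
  bad <- which(at != variants$wt)
  if (length(bad))
    stop(sprintf("row %d: wild-type mismatch for %s %s%d (sequence has %s)",
                 bad[1], variants$protein_id[bad[1]], variants$wt[bad[1]],
                 variants$position[bad[1]], at[bad[1]]))
  degen <- which(variants$wt == variants$var)
  if (length(degen))
    stop(sprintf("row %d: degenerate substitution %s%d%s", degen[1],
                 variants$wt[degen[1]], variants$position[degen[1]],
                 variants$var[degen[1]]))
  key <- with(variants, paste(protein_id, position, wt, var, sep = "|"))
  variants <- variants[!duplicated(key), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(proteins = proteins, variants = variants),
            class = "variant_dataset")
}

#' @export
print.variant_dataset <- function(x, ...) {
  tab <- table(factor(x$variants$label, levels = VALID_LABELS))
  cat(sprintf("variant_dataset: %d proteins, %d variants (%d effect, %d neutral, %d unlabeled)\n",
              length(x$proteins), nrow(x$variants),
              tab[["effect"]], tab[["neutral"]], tab[["unlabeled"]]))
  invisible(x)
}

#' Load a variant table from TSV
#'
#' Expects a tab-separated file with a header and columns `protein_id`,
#' `variant_token` and optionally `label` and `source`. Every row is
#' validated against the protein sequences (wild-type letter must match the
#' sequence at the 1-based token position); duplicate substitutions are
#' collapsed.
#'
#' @param path TSV path.
#' @param proteins [Biostrings::AAStringSet] of reference sequences.
#' @return a [variant_dataset()].
#' @export
load_variant_table <- function(path, proteins) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "variant_token") %in% names(df)))
    stop("variant table needs columns protein_id, variant_token")
  parts <- lapply(df$variant_token, parse_variant_token)
  variants <- data.frame(
    protein_id = df$protein_id,
    position = vapply(parts, function(p) p$position, integer(1)),
    wt = vapply(parts, function(p) p$wt, character(1)),
    var = vapply(parts, function(p) p$var, character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(df$label)) variants$label <- df$label
  if (!is.null(df$source)) variants$source <- df$source
  variant_dataset(proteins, variants)
}

#' Write a variant dataset table to TSV
#'
#' @param dataset a [variant_dataset()].
#' @param path output TSV path.
#' @export
write_variant_table <- function(dataset, path) {
  v <- dataset$variants
  out <- data.frame(
    protein_id = v$protein_id,
    variant_token = format_variant_token(v$wt, v$position, v$var),
    label = v$label,
    source = v$source,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map graded functional annotations to a class label
#'
#' Functional-effect databases grade substitutions as unchanged (`"="`) or
#' as any level of increase (`"+"`, `"++"`, `"+++"`) or decrease (`"-"`,
#' `"- -"`, `"- - -"`) in function. A variant is `"neutral"` only when every
#' annotation in its set is `"="`; any graded change — including a set of
#' conflicting annotations — maps to `"effect"`.
#'
#' @param raw character vector: the set of annotation codes observed for one
#'   substitution. Decrease grades may be written with or without internal
#'   spaces (`"- -"` or `"--"`).
#' @return `"neutral"` or `"effect"`.
#' @examples
#' map_pmd_annotation("=")          # neutral
#' map_pmd_annotation("++")         # effect
#' map_pmd_annotation(c("+", "-"))  # conflict -> effect
#' @export
map_pmd_annotation <- function(raw) {
  if (length(raw) < 1L) stop("empty annotation set")
  norm <- gsub(" ", "", raw)
  valid <- c("=", "+", "++", "+++", "-", "--", "---")
  bad <- !norm %in% valid
  if (any(bad))
    stop("unrecognized annotation code(s): ", paste(unique(raw[bad]), collapse = ", "))
  if (all(norm == "=")) "neutral" else "effect"
}

#' Write predictions to TSV
#'
#' Columns: protein_id, variant_token, score (-100..+100), predicted class,
#' reliability index (0-10) and display digit (0-9).
#'
#' @param results a `vep_predictions` data.frame as returned by
#'   [predict.vepnet()].
#' @param path output path.
#' @export
write_predictions <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L) stop("empty result list")
  need <- c("protein_id", "position", "wt", "var", "score", "class", "ri", "digit")
  if (!all(need %in% names(results)))
    stop("results must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(
    protein_id = results$protein_id,
    variant_token = format_variant_token(results$wt, results$position, results$var),
    score = sprintf("%.4f", results$score),
    class = results$class,
    ri = results$ri,
    digit = results$digit,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write predictions to ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#' @param path TSV path.
#' @return data.frame with parsed token columns.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  parts <- lapply(df$variant_token, parse_variant_token)
  df$position <- vapply(parts, function(p) p$position, integer(1))
  df$wt <- vapply(parts, function(p) p$wt, character(1))
  df$var <- vapply(parts, function(p) p$var, character(1))
  df$score <- as.numeric(df$score)
  df
}
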
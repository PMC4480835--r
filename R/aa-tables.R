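# Amino-acid constants and physicochemical scales used by the feature providers.

#' Canonical amino-acid alphabet
#'
#' The 20 standard residues in alphabetical one-letter order. All feature
#' tables, one-hot encodings and substitution matrices in this package use
#' this ordering.
#'
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Kyte-Doolittle hydropathy (dimensionless, positive = hydrophobic)
.AA_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Formal side-chain charge at physiological pH
.AA_CHARGE <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0, K = 1,
  L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0,
  W = 0, Y = 0
)

# Residue volumes in cubic Angstroms (Zamyatnin)
.AA_VOLUME <- c(
  A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G = 60.1,
  H = 153.2, I = 166.7, K = 168.6, L = 166.7, M = 162.9, N = 114.1,
  P = 112.7, Q = 143.8, R = 173.4, S = 89.0, T = 116.1, V = 140.0,
  W = 227.8, Y = 193.6
)

# Average molecular weight of the free amino acid (Da)
.AA_MW <- c(
  A = 89.09, C = 121.16, D = 133.10, E = 147.13, F = 165.19, G = 75.07,
  H = 155.16, I = 131.17, K = 146.19, L = 131.17, M = 149.21, N = 132.12,
  P = 115.13, Q = 146.15, R = 174.20, S = 105.09, T = 119.12, V = 117.15,
  W = 204.23, Y = 181.19
)

.AA_AROMATIC  <- ifelse(AA_ALPHABET %in% c("F", "W", "Y"), 1, 0)
.AA_ALIPHATIC <- ifelse(AA_ALPHABET %in% c("A", "V", "L", "I"), 1, 0)
names(.AA_AROMATIC) <- names(.AA_ALIPHATIC) <- AA_ALPHABET

#' Biophysical feature triple for one residue
#'
#' Returns the (charge, hydropathy, volume) triple for a canonical residue:
#' integer formal charge at physiological pH, Kyte-Doolittle hydropathy and
#' the Zamyatnin side-chain volume in cubic Angstroms.
#'
#' @param aa single upper-case amino-acid letter.
#' @return named numeric vector `c(charge=, hydropathy=, volume=)`.
#' @examples
#' biophysical_features("K")  # positive charge
#' @export
biophysical_features <- function(aa) {
  if (length(aa) != 1L || !aa %in% AA_ALPHABET)
    stop("unknown amino-acid letter: ", deparse(aa))
  c(charge = unname(.AA_CHARGE[aa]),
    hydropathy = unname(.AA_HYDROPATHY[aa]),
    volume = unname(.AA_VOLUME[aa]))
}

#' Hydropathy lookup
#'
#' Kyte-Doolittle hydropathy for a vector of residues.
#' @param aa character vector of amino-acid letters.
#' @return numeric vector.
#' @export
aa_hydropathy <- function(aa) {
  bad <- !aa %in% AA_ALPHABET
  if (any(bad)) stop("unknown amino-acid letter(s): ", paste(unique(aa[bad]), collapse = ", "))
  unname(.AA_HYDROPATHY[aa])
}

#' Synthetic contact-propensity matrix
#'
#' A symmetric 20x20 residue-pair contact propensity table derived from the
#' Kyte-Doolittle hydropathy scale: more hydrophobic pairs receive more
#' negative (more favourable) values, mimicking the dominant additive trend
#' of statistical contact potentials. This table is constructed in code and
#' is a synthetic surrogate, not a published potential; any user-supplied
#' symmetric 20x20 matrix can be used in its place via
#' [contact_potential_feature()].
#'
#' @return 20x20 symmetric numeric matrix with residue dimnames.
#' @export
contact_potential_matrix <- function() {
  h <- .AA_HYDROPATHY[AA_ALPHABET] / max(abs(.AA_HYDROPATHY))
  m <- -outer(h, h, function(a, b) (a + b) / 2)
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}
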
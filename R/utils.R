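## Monoisotopic residue masses (Da); C is listed unmodified, the fixed
## carbamidomethyl (+57.02146) is added in peptide_mono_mass().
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
.MASS_WATER <- 18.0105646863
.MASS_PROTON <- 1.00727646688
.MASS_CAM <- 57.02146

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass of a peptide, with fixed carbamidomethylation of
#' cysteine included by default.
#'
#' @param sequence Character vector of plain uppercase peptide sequences.
#' @param carbamidomethyl Apply the fixed +57.02146 Da on every C?
#' @return Numeric vector of masses (Da); `NA` for sequences containing
#'   residues outside the 20 standard amino acids.
#' @export
peptide_mono_mass <- function(sequence, carbamidomethyl = TRUE) {
  vapply(strsplit(sequence, ""), function(ch) {
    m <- .AA_MONO[ch]
    if (anyNA(m)) return(NA_real_)
    tot <- sum(m) + .MASS_WATER
    if (carbamidomethyl) tot <- tot + .MASS_CAM * sum(ch == "C")
    tot
  }, numeric(1))
}

## m/z of a singly protonated b- or y-ion of `sequence`
fragment_mz <- function(sequence, annotation) {
  stopifnot(length(sequence) == 1L)
  ch <- strsplit(sequence, "")[[1]]
  res <- .AA_MONO[ch] + ifelse(ch == "C", .MASS_CAM, 0)
  type <- substr(annotation, 1L, 1L)
  len <- as.integer(substring(annotation, 2L))
  out <- rep(NA_real_, length(annotation))
  ok <- type %in% c("b", "y") & !is.na(len) & len >= 1L & len <= length(ch)
  for (i in which(ok)) {
    out[i] <- if (type[i] == "y") {
      sum(res[(length(res) - len[i] + 1L):length(res)]) + .MASS_WATER + .MASS_PROTON
    } else {
      sum(res[seq_len(len[i])]) + .MASS_PROTON
    }
  }
  out
}

precursor_mz_of <- function(sequence, charge) {
  (peptide_mono_mass(sequence) + charge * .MASS_PROTON) / charge
}

## strip modification annotations like "C(cam)" or "(UniMod:4)" from a
## modified-peptide string, leaving the plain residue sequence
strip_sequence <- function(modified_sequence) {
  gsub("[^A-Z]", "", gsub("\\([^)]*\\)|\\[[^]]*\\]", "", modified_sequence))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of positive vs negative scores.
#'
#' @param pos,neg Numeric score vectors for positives and negatives.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

## deterministic small integer hash of a string (for per-run seed offsets)
string_seed <- function(x) {
  sum(utf8ToInt(x) * (seq_along(utf8ToInt(x)) %% 7L + 1L)) %% 10000L
}
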
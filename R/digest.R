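#' In-silico tryptic digestion of a FASTA database
#'
#' Digests every protein with strict trypsin specificity (cleavage after K or
#' R, including before proline), allowing up to `missed_cleavages` missed
#' cleavage sites, and filters peptides on length and monoisotopic mass (with
#' fixed carbamidomethyl-C included in the mass). Peptides containing
#' non-standard residues (B, J, O, U, X, Z) are skipped with one warning per
#' protein.
#'
#' @param fasta_path Path to a protein FASTA file; the accession is the first
#'   whitespace-delimited token of the header.
#' @param missed_cleavages Maximum number of missed cleavage sites (>= 0).
#' @param min_len,max_len Peptide length bounds (residues, inclusive).
#' @param min_mass,max_mass Monoisotopic mass bounds (Da, inclusive).
#' @return Named list mapping each peptide sequence to the sorted character
#'   vector of accessions of its source proteins.
#' @export
in_silico_digest <- function(fasta_path, missed_cleavages = 2L,
                             min_len = 7L, max_len = 50L,
                             min_mass = 500, max_mass = 5000) {
  stopifnot(missed_cleavages >= 0L, min_len >= 1L, max_len >= min_len,
            min_mass >= 0, max_mass >= min_mass)
  aa <- Biostrings::readAAStringSet(fasta_path)
  acc <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  seqs <- as.character(aa)
  pep_list <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    peps <- digest_sequence(seqs[i], missed_cleavages, min_len, max_len)
    if (attr(peps, "skipped") > 0L)
      warning(sprintf("protein %s: %d peptide(s) with non-standard residues skipped",
                      acc[i], attr(peps, "skipped")), call. = FALSE)
    pep_list[[i]] <- peps
  }
  dt <- data.table::data.table(
    peptide = unlist(pep_list, use.names = FALSE),
    accession = rep(acc, lengths(pep_list)))
  if (nrow(dt) == 0L) return(structure(list(), names = character()))
  dt <- unique(dt)
  if (min_mass > 0 || is.finite(max_mass)) {
    uni <- unique(dt$peptide)
    m <- peptide_mono_mass(uni)
    ok <- !is.na(m) & m >= min_mass & m <= max_mass
    dt <- dt[peptide %in% uni[ok]]
  }
  if (nrow(dt) == 0L) return(structure(list(), names = character()))
  split(dt$accession, dt$peptide) |> lapply(function(x) sort(unique(x)))
}

## tryptic peptides (with missed cleavages) of one protein sequence;
## attr "skipped" counts peptides dropped for non-standard residues
digest_sequence <- function(sequence, missed_cleavages, min_len, max_len) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  ## cleavage after every K/R ("stricttrypsin": also before P)
  cut_after <- which(ch %in% c("K", "R"))
  bounds <- c(0L, cut_after[cut_after < n], n)  # segment boundaries
  bounds <- unique(bounds)
  nseg <- length(bounds) - 1L
  peps <- character(0)
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + missed_cleavages)) {
      start <- bounds[i] + 1L; end <- bounds[j + 1L]
      len <- end - start + 1L
      if (len >= min_len && len <= max_len)
        peps <- c(peps, substr(sequence, start, end))
    }
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", peps)
  structure(unique(peps[!bad]), skipped = sum(bad))
}
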
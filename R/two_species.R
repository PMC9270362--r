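#' Two-species entrapment counts
#'
#' Container for the entrapment FDR arithmetic: `A_id` / `H_id` are the
#' entrapment- and target-species calls at a score threshold, `A_lib` /
#' `H_lib` the species' library sizes (after any m/z range filtering), and
#' `H_id_05` the target-species calls at q = 0.05 used by the pi0 (percentage
#' of incorrect targets) correction.
#'
#' @param A_id,H_id,A_lib,H_lib,H_id_05 Non-negative counts.
#' @return Object of class `two_species_counts`.
#' @export
two_species_counts <- function(A_id, H_id, A_lib, H_lib, H_id_05) {
  x <- list(A_id = A_id, H_id = H_id, A_lib = A_lib, H_lib = H_lib,
            H_id_05 = H_id_05)
  if (any(unlist(x) < 0)) stop("counts must be non-negative")
  if (A_lib + H_lib <= 0) stop("empty library")
  class(x) <- "two_species_counts"
  x
}

#' Prior probability of incorrect identification (pi0 / PIT)
#'
#' `pi0 = (A_lib + H_lib - 0.95 * H_id_05) / (A_lib + H_lib)`: the fraction
#' of library candidates not accounted for by confident (q <= 0.05)
#' target-species identifications, 95% of which are assumed correct.
#'
#' @param counts A [two_species_counts()].
#' @return pi0 in (0, 1].
#' @export
pi0 <- function(counts) {
  stopifnot(inherits(counts, "two_species_counts"))
  v <- (counts$A_lib + counts$H_lib - 0.95 * counts$H_id_05) /
    (counts$A_lib + counts$H_lib)
  if (v <= 0)
    stop("pi0 <= 0: more confident identifications than library candidates")
  v
}

#' Experimental (entrapment) FDR
#'
#' `FDR = [A_id / (A_id + H_id)] * [(A_lib + H_lib) / A_lib] * pi0`: the
#' entrapment-species call fraction, scaled up by the inverse library share
#' of the entrapment species and corrected by pi0.
#'
#' @param counts A [two_species_counts()].
#' @param pi0_value Optional pi0 override; default [pi0()] of `counts`.
#' @return The experimental FDR (>= 0).
#' @export
experimental_fdr <- function(counts, pi0_value = pi0(counts)) {
  stopifnot(inherits(counts, "two_species_counts"))
  if (counts$A_lib == 0) stop("A_lib = 0: no entrapment species in library")
  if (counts$A_id + counts$H_id == 0) stop("no calls at threshold")
  (counts$A_id / (counts$A_id + counts$H_id)) *
    ((counts$A_lib + counts$H_lib) / counts$A_lib) * pi0_value
}

#' Species of a protein group
#'
#' Maps protein groups to species via the accession prefix (the token before
#' the first underscore), e.g. `c(HUM = "human", YST = "yeast")`.
#'
#' @param protein_group Character vector of protein group ids.
#' @param species_map Named character vector, prefix -> species label.
#' @return Character vector of species labels (`NA` for unmapped prefixes).
#' @export
annotate_species <- function(protein_group, species_map) {
  prefix <- sub("_.*$", "", protein_group)
  unname(species_map[prefix])
}

#' Entrapment FDR curve
#'
#' Evaluates the experimental FDR at every distinct reported q-value
#' threshold of an analysis report searched with a mixed-species library.
#' Library sizes are counted within `mz_range` (closed); `H_id_05` is fixed
#' at the q = 0.05 threshold.
#'
#' @param report Analysis report `data.frame` with columns `Protein.Group`,
#'   `Q.Value` (one row per accepted precursor candidate).
#' @param library The searched [spectral_library()] (targets; decoys are
#'   ignored).
#' @param species_map Named prefix -> species map, see [annotate_species()].
#' @param target_species,entrapment_species Species labels in `species_map`.
#' @param mz_range Length-2 numeric, closed precursor m/z range for library
#'   counting.
#' @return `data.frame` with `q_threshold`, `A_id`, `H_id`, `experimental_fdr`
#'   (attributes `A_lib`, `H_lib`, `H_id_05`, `pi0`).
#' @export
entrapment_curve <- function(report, library, species_map,
                             target_species = "target",
                             entrapment_species = "entrapment",
                             mz_range = c(400, 1000)) {
  prec <- library$precursors[!library$precursors$decoy, , drop = FALSE]
  in_range <- prec$precursor_mz >= mz_range[1] & prec$precursor_mz <= mz_range[2]
  lib_species <- annotate_species(prec$protein_group, species_map)
  A_lib <- sum(in_range & lib_species == entrapment_species, na.rm = TRUE)
  H_lib <- sum(in_range & lib_species == target_species, na.rm = TRUE)
  if (A_lib == 0) stop("no entrapment-species precursors in library range")
  sp <- annotate_species(report$Protein.Group, species_map)
  if (anyNA(sp))
    stop("missing species annotation for protein group(s): ",
         paste(head(unique(report$Protein.Group[is.na(sp)]), 3), collapse = ", "))
  q <- report$Q.Value
  H_id_05 <- sum(q <= 0.05 & sp == target_species)
  p0 <- pi0(two_species_counts(0, 0, A_lib, H_lib, H_id_05))
  thresholds <- sort(unique(q))
  rows <- lapply(thresholds, function(t) {
    A_id <- sum(q <= t & sp == entrapment_species)
    H_id <- sum(q <= t & sp == target_species)
    fdr <- if (A_id + H_id == 0) NA_real_ else
      (A_id / (A_id + H_id)) * ((A_lib + H_lib) / A_lib) * p0
    data.frame(q_threshold = t, A_id = A_id, H_id = H_id,
               experimental_fdr = fdr)
  })
  out <- do.call(rbind, rows)
  attr(out, "A_lib") <- A_lib; attr(out, "H_lib") <- H_lib
  attr(out, "H_id_05") <- H_id_05; attr(out, "pi0") <- p0
  out
}

#' Species-aware library filtering
#'
#' Retains library entries whose stripped peptide sequence occurs in the
#' in-silico tryptic digest of the "keep" database and not in the digest of
#' the "exclude" database (shared peptides are removed from both sides of a
#' two-proteome benchmark).
#'
#' @param library A [spectral_library()].
#' @param fasta_keep,fasta_exclude FASTA paths.
#' @param cam_only Also drop entries whose modified sequence carries
#'   modifications other than carbamidomethyl-C (default TRUE).
#' @param ... Digestion parameters passed to [in_silico_digest()].
#' @return The filtered [spectral_library()]; attribute `n_removed` reports
#'   the number of precursors dropped. Warns (not errors) when empty.
#' @export
filter_library_by_species <- function(library, fasta_keep, fasta_exclude,
                                      cam_only = TRUE, ...) {
  keep_map <- in_silico_digest(fasta_keep, ...)
  excl_map <- in_silico_digest(fasta_exclude, ...)
  prec <- library$precursors
  stripped <- strip_sequence(prec$modified_sequence)
  ok <- stripped %in% names(keep_map) & !(stripped %in% names(excl_map))
  if (cam_only) {
    mods <- gsub("C\\(cam\\)|C\\[\\+57[0-9.]*\\]", "C", prec$modified_sequence)
    ok <- ok & !grepl("[^A-Z]", mods)
  }
  if (!any(ok)) {
    warning("species filter removed every library entry", call. = FALSE)
    out <- spectral_library(prec[integer(0), ],
                            library$fragments[integer(0), ],
                            library$metadata)
  } else {
    kept_ids <- prec$precursor_id[ok]
    out <- spectral_library(
      prec[ok, , drop = FALSE],
      library$fragments[library$fragments$precursor_id %in% kept_ids, ,
                        drop = FALSE],
      library$metadata)
  }
  attr(out, "n_removed") <- sum(!ok)
  out
}
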
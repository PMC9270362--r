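## Spectral library container and tab-separated I/O.

LIBRARY_COLUMNS <- c("ModifiedPeptide", "PrecursorCharge", "PrecursorMz",
                     "ProteinGroup", "Proteotypic", "Decoy", "ReferenceRT",
                     "ReferenceIM", "FragmentMz", "FragmentRelIntensity",
                     "FragmentAnnotation")

#' Spectral library
#'
#' In-memory spectral library: one row per precursor in `$precursors`
#' (columns `precursor_id`, `modified_sequence`, `charge`, `precursor_mz`,
#' `ref_rt`, `ref_inv_k0`, `protein_group`, `proteotypic`, `decoy`) and one
#' row per fragment in `$fragments` (`precursor_id`, `mz`, `rel_intensity`,
#' `annotation`). Fragment relative intensities are rescaled so each
#' precursor's most intense fragment is 1.
#'
#' @param precursors,fragments Data frames as described above.
#' @param metadata Named list of provenance strings.
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(precursors, fragments, metadata = list()) {
  precursors <- as.data.frame(precursors)
  fragments <- as.data.frame(fragments)
  key <- paste(precursors$modified_sequence, precursors$charge,
               precursors$decoy, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (modified_sequence, charge, decoy) precursor keys")
  if (any(precursors$precursor_mz <= 0)) stop("precursor_mz must be > 0")
  if (!all(fragments$precursor_id %in% precursors$precursor_id))
    stop("fragment rows referencing unknown precursor_id")
  nfr <- table(factor(fragments$precursor_id, levels = precursors$precursor_id))
  if (any(nfr == 0L)) stop("every precursor needs at least one fragment")
  ## max-1 rescaling per precursor
  fr <- data.table::as.data.table(fragments)
  fr[, rel_intensity := as.numeric(rel_intensity)]
  fr[, rel_intensity := rel_intensity / max(rel_intensity), by = precursor_id]
  if (any(fr$rel_intensity < 0)) stop("negative fragment intensity")
  x <- list(precursors = precursors, fragments = as.data.frame(fr),
            metadata = metadata)
  class(x) <- "spectral_library"
  x
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("spectral_library: %d precursors (%d decoys), %d fragments, %d protein groups\n",
              nrow(x$precursors), sum(x$precursors$decoy),
              nrow(x$fragments), length(unique(x$precursors$protein_group))))
  invisible(x)
}

#' Number of target precursors
#' @param library A [spectral_library()].
#' @return Integer count of non-decoy precursors.
#' @export
n_targets <- function(library) sum(!library$precursors$decoy)

#' Read / write a spectral library in tab-separated text
#'
#' The format has one row per fragment with the precursor-level columns
#' repeated: `ModifiedPeptide`, `PrecursorCharge`, `PrecursorMz`,
#' `ProteinGroup`, `Proteotypic`, `Decoy`, `ReferenceRT`, `ReferenceIM`,
#' `FragmentMz`, `FragmentRelIntensity`, `FragmentAnnotation`.
#'
#' @param path File path.
#' @param library A [spectral_library()].
#' @return `read_spectral_library()` returns a [spectral_library()].
#' @export
read_spectral_library <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("ModifiedPeptide", "ProteinGroup", "FragmentAnnotation")))
  missing_cols <- setdiff(LIBRARY_COLUMNS, names(dt))
  if (length(missing_cols))
    stop("spectral library format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (col in c("PrecursorMz", "FragmentMz", "FragmentRelIntensity",
                "ReferenceRT", "ReferenceIM")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("spectral library format error: non-numeric %s at data row %d",
                   col, bad))
    }
  }
  dt[, key := paste(ModifiedPeptide, PrecursorCharge, as.logical(Decoy), sep = "|")]
  ## precursor-level fields must be constant within a key
  chk <- dt[, .(n = data.table::uniqueN(PrecursorMz)), by = key]
  if (any(chk$n > 1L))
    stop("conflicting PrecursorMz for precursor ", chk$key[chk$n > 1L][1])
  prec <- dt[, .(
    modified_sequence = ModifiedPeptide[1], charge = as.integer(PrecursorCharge[1]),
    precursor_mz = PrecursorMz[1], protein_group = ProteinGroup[1],
    proteotypic = as.logical(Proteotypic[1]), decoy = as.logical(Decoy[1]),
    ref_rt = ReferenceRT[1], ref_inv_k0 = ReferenceIM[1]
  ), by = key]
  prec[, precursor_id := seq_len(.N)]
  frag <- dt[, .(key, mz = FragmentMz, rel_intensity = FragmentRelIntensity,
                 annotation = FragmentAnnotation)]
  frag <- merge(frag, prec[, .(key, precursor_id)], by = "key", sort = FALSE)
  prec[, key := NULL]
  spectral_library(
    precursors = as.data.frame(prec)[, c("precursor_id", "modified_sequence",
      "charge", "precursor_mz", "ref_rt", "ref_inv_k0", "protein_group",
      "proteotypic", "decoy")],
    fragments = as.data.frame(frag)[, c("precursor_id", "mz", "rel_intensity",
                                        "annotation")],
    metadata = list(source = path)
  )
}

#' @rdname read_spectral_library
#' @export
write_spectral_library <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  p <- data.table::as.data.table(library$precursors)
  f <- data.table::as.data.table(library$fragments)
  out <- merge(f, p, by = "precursor_id", sort = FALSE)
  out <- out[, .(
    ModifiedPeptide = modified_sequence, PrecursorCharge = charge,
    PrecursorMz = precursor_mz, ProteinGroup = protein_group,
    Proteotypic = proteotypic, Decoy = decoy, ReferenceRT = ref_rt,
    ReferenceIM = ref_inv_k0, FragmentMz = mz,
    FragmentRelIntensity = rel_intensity, FragmentAnnotation = annotation)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
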
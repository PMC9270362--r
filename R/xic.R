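#' Mass-ordered run index
#'
#' Organizes picked spectra for fast chromatogram extraction: one sorted peak
#' list per (window, cycle), addressable in O(1), with peaks stored ordered
#' by mass so binary search locates the m/z tolerance bounds.
#'
#' @param picked_spectra List of [picked_spectrum()] objects; at most one per
#'   (window, cycle).
#' @param spec A [frame_spec()].
#' @param n_cycles Number of cycles in the run; default inferred from the
#'   largest cycle index present.
#' @return Object of class `run_index`.
#' @export
build_index <- function(picked_spectra, spec, n_cycles = NULL) {
  wid <- vapply(picked_spectra, `[[`, integer(1), "window_id")
  cyc <- vapply(picked_spectra, `[[`, integer(1), "cycle")
  if (anyDuplicated(paste(wid, cyc)))
    stop("duplicate (window, cycle) spectrum in index input")
  if (is.null(n_cycles))
    n_cycles <- if (length(cyc)) max(cyc) + 1L else 0L
  idx <- list()
  for (i in seq_along(picked_spectra)) {
    w <- as.character(wid[i])
    if (is.null(idx[[w]])) idx[[w]] <- vector("list", n_cycles)
    p <- picked_spectra[[i]]$peaks
    o <- order(p$mz, p$inv_k0)
    idx[[w]][[cyc[i] + 1L]] <- list(mz = p$mz[o], inv_k0 = p$inv_k0[o],
                                    intensity = p$intensity[o])
  }
  x <- list(spectra = idx, spec = spec, n_cycles = as.integer(n_cycles))
  class(x) <- "run_index"
  x
}

## sorted peak list (list of mz/inv_k0/intensity vectors) or NULL
index_spectrum <- function(index, window_id, cycle) {
  w <- index$spectra[[as.character(window_id)]]
  if (is.null(w) || cycle < 0L || cycle + 1L > length(w)) return(NULL)
  w[[cycle + 1L]]
}

#' Extract the best matching peak from one spectrum
#'
#' Finds, by binary search on the mass-ordered peak list, all peaks within
#' `mass_tol_ppm` of `query_mz`; of those within the ion mobility window
#' around `predicted_im`, the most intense peak is returned (ties broken by
#' smaller m/z deviation, then smaller m/z). Returns `NULL` when no peak
#' qualifies.
#'
#' @param spectrum A sorted peak list as stored by [build_index()] (list with
#'   numeric `mz`, `inv_k0`, `intensity`), or a [picked_spectrum()].
#' @param query_mz Query m/z (Th).
#' @param mass_tol_ppm Mass tolerance (ppm).
#' @param predicted_im Predicted 1/K0 (Vs/cm2).
#' @param im_window Ion mobility half-window (Vs/cm2); `Inf` disables the
#'   mobility gate.
#' @return `list(mz, inv_k0, intensity)` or `NULL`.
#' @export
extract_point <- function(spectrum, query_mz, mass_tol_ppm, predicted_im,
                          im_window) {
  if (inherits(spectrum, "picked_spectrum")) {
    p <- spectrum$peaks
    spectrum <- list(mz = p$mz, inv_k0 = p$inv_k0, intensity = p$intensity)
  }
  mzv <- spectrum$mz
  n <- length(mzv)
  if (n == 0L) return(NULL)
  dm <- query_mz * mass_tol_ppm * 1e-6
  lo <- query_mz - dm; hi <- query_mz + dm
  i1 <- findInterval(lo, mzv)            # last index with mz <= lo
  if (i1 >= 1L && mzv[i1] >= lo) i1 <- i1 - 1L  # include exact boundary
  i2 <- findInterval(hi, mzv)            # last index with mz <= hi
  if (i2 <= i1) return(NULL)
  j <- (i1 + 1L):i2
  keep <- abs(mzv[j] - query_mz) <= dm &
    abs(spectrum$inv_k0[j] - predicted_im) <= im_window
  j <- j[keep]
  if (!length(j)) return(NULL)
  iv <- spectrum$intensity[j]
  best <- j[order(-iv, abs(mzv[j] - query_mz), mzv[j])][1]
  list(mz = mzv[best], inv_k0 = spectrum$inv_k0[best],
       intensity = spectrum$intensity[best])
}

## Vectorized variant over a set of query ions against one spectrum.
## Returns a matrix with rows (intensity, inv_k0, mz), NA where missing.
extract_ions <- function(spectrum, query_mzs, mass_tol_ppm, predicted_im,
                         im_window) {
  nq <- length(query_mzs)
  out <- matrix(NA_real_, nrow = 3L, ncol = nq)
  if (is.null(spectrum) || length(spectrum$mz) == 0L) return(out)
  mzv <- spectrum$mz; imv <- spectrum$inv_k0; iv <- spectrum$intensity
  dm <- query_mzs * mass_tol_ppm * 1e-6
  i1 <- findInterval(query_mzs - dm, mzv)
  i2 <- findInterval(query_mzs + dm, mzv)
  for (q in seq_len(nq)) {
    a <- i1[q]
    if (a >= 1L && mzv[a] >= query_mzs[q] - dm[q]) a <- a - 1L
    if (i2[q] <= a) next
    j <- (a + 1L):i2[q]
    keep <- abs(mzv[j] - query_mzs[q]) <= dm[q] &
      abs(imv[j] - predicted_im) <= im_window
    j <- j[keep]
    if (!length(j)) next
    best <- j[order(-iv[j], abs(mzv[j] - query_mzs[q]), mzv[j])][1]
    out[, q] <- c(iv[best], imv[best], mzv[best])
  }
  out
}

#' Extract chromatograms for a library precursor
#'
#' For every cycle in the retention-time search region, extracts (via
#' [extract_point()] semantics) the precursor trace from MS1 spectra (window
#' 0, when present in the index) and each fragment trace from the spectra of
#' the isolation window containing the precursor m/z. Mass queries are
#' corrected by the calibration's ppm offset and gated by the calibrated ion
#' mobility window around the mapped library 1/K0.
#'
#' @param index A [build_index()] result.
#' @param entry One-row precursor data.frame from a [spectral_library()]
#'   (fields `precursor_id`, `precursor_mz`, `ref_rt`, `ref_inv_k0`) plus its
#'   fragment table, or a `precursor_id` to look up in `library`.
#' @param calib A [fit_calibration()] result.
#' @param library The [spectral_library()] (used to fetch fragments).
#' @param cycles Optional explicit cycle vector; default is the calibrated
#'   retention-time search region.
#' @return Object of class `chromatogram_set`: list with `precursor_id`,
#'   `window_id`, `cycles`, `ions` (data.frame: `mz`, `is_precursor`,
#'   `annotation`), and matrices `intensity`, `inv_k0`, `obs_mz`
#'   (ions x cycles, `NA` = missing). Empty (zero-cycle) set with a
#'   `diagnostic` attribute when the precursor falls outside all windows.
#' @export
extract_chromatograms <- function(index, entry, calib, library,
                                  cycles = NULL) {
  if (!is.data.frame(entry))
    entry <- library$precursors[library$precursors$precursor_id == entry, ]
  stopifnot(nrow(entry) == 1L)
  spec <- index$spec
  w <- spec$windows
  hit <- which(entry$precursor_mz >= w$mz_low & entry$precursor_mz <= w$mz_high)
  frags <- library$fragments[library$fragments$precursor_id ==
                               entry$precursor_id, ]
  if (!length(hit)) {
    out <- list(precursor_id = entry$precursor_id, window_id = NA_integer_,
                cycles = integer(0),
                ions = data.frame(mz = numeric(), is_precursor = logical(),
                                  annotation = character()),
                intensity = matrix(numeric(), 0, 0),
                inv_k0 = matrix(numeric(), 0, 0),
                obs_mz = matrix(numeric(), 0, 0))
    attr(out, "diagnostic") <- "precursor m/z outside all isolation windows"
    class(out) <- "chromatogram_set"
    return(out)
  }
  wid <- w$window_id[hit[1]]
  if (is.null(cycles)) {
    center <- rt_to_cycle(calib, entry$ref_rt)
    half <- 3 * calib$rt_resid_q95
    cycles <- max(0L, floor(center - half)):min(index$n_cycles - 1L,
                                                ceiling(center + half))
    cycles <- cycles[cycles >= 0L]
  }
  pred_im <- calib$im_slope * entry$ref_inv_k0 + calib$im_intercept
  has_ms1 <- !is.null(index$spectra[["0"]])
  ions <- data.frame(
    mz = c(if (has_ms1) entry$precursor_mz, frags$mz),
    is_precursor = c(if (has_ms1) TRUE, rep(FALSE, nrow(frags))),
    annotation = c(if (has_ms1) "MS1", frags$annotation))
  qmz <- ions$mz * (1 + calib$mass_correction_ppm * 1e-6)
  nc <- length(cycles)
  intensity <- inv_k0 <- obs_mz <- matrix(NA_real_, nrow(ions), nc)
  frag_rows <- which(!ions$is_precursor)
  for (ci in seq_len(nc)) {
    sp2 <- index_spectrum(index, wid, cycles[ci])
    if (!is.null(sp2) && length(frag_rows)) {
      m <- extract_ions(sp2, qmz[frag_rows], calib$mass_tol_ppm, pred_im,
                        calib$im_window)
      intensity[frag_rows, ci] <- m[1, ]; inv_k0[frag_rows, ci] <- m[2, ]
      obs_mz[frag_rows, ci] <- m[3, ]
    }
    if (has_ms1) {
      sp1 <- index_spectrum(index, 0L, cycles[ci])
      m1 <- extract_ions(sp1, qmz[1], calib$mass_tol_ppm, pred_im,
                         calib$im_window)
      intensity[1, ci] <- m1[1, ]; inv_k0[1, ci] <- m1[2, ]
      obs_mz[1, ci] <- m1[3, ]
    }
  }
  out <- list(precursor_id = entry$precursor_id, window_id = wid,
              cycles = cycles, ions = ions, intensity = intensity,
              inv_k0 = inv_k0, obs_mz = obs_mz)
  if (!has_ms1) attr(out, "precursor_trace") <- "no MS1 spectra in index"
  class(out) <- "chromatogram_set"
  out
}
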
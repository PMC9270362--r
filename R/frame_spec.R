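#' Acquisition geometry of a dia-PASEF-like run
#'
#' A `frame_spec` describes the frame geometry: the affine map between TIMS
#' scan number and inverse ion mobility (1/K0), the affine map between mass
#' bin index and sqrt(m/z) (TOF digitizers are linear in time of flight, hence
#' in sqrt(m/z)), the precursor isolation window scheme, and the number of
#' identical repeated frames per cycle.
#'
#' @param n_scans Number of TIMS scans per frame (>= 2).
#' @param im_begin,im_end 1/K0 (Vs/cm2) at scan 0 and scan `n_scans - 1`.
#' @param n_bins Number of mass bins (>= 2).
#' @param mz_min,mz_max m/z (Th) at bin 0 and bin `n_bins - 1`.
#' @param windows `data.frame` with columns `mz_low`, `mz_high` (Th, closed
#'   precursor-isolation bounds), `scan_low`, `scan_high` (half-open scan
#'   interval \[low, high)), `window_id` (positive integers; 0 is reserved for
#'   MS1 spectra).
#' @param frames_per_window Identical repeated frames per cycle (>= 1); these
#'   are summed before peak picking.
#' @param cycle_time Seconds per dia-PASEF cycle.
#' @return An object of class `frame_spec`.
#' @export
frame_spec <- function(n_scans, im_begin, im_end, n_bins, mz_min, mz_max,
                       windows, frames_per_window = 1L, cycle_time = 1.0) {
  n_scans <- as.integer(n_scans); n_bins <- as.integer(n_bins)
  stopifnot(n_scans >= 2L, n_bins >= 2L, im_begin != im_end,
            mz_min > 0, mz_max > mz_min, frames_per_window >= 1L)
  windows <- as.data.frame(windows)
  need <- c("mz_low", "mz_high", "scan_low", "scan_high", "window_id")
  if (!all(need %in% names(windows)) || nrow(windows) == 0L)
    stop("windows must be a non-empty data.frame with columns ",
         paste(need, collapse = ", "))
  if (any(windows$window_id <= 0L)) stop("window_id must be positive (0 is MS1)")
  if (anyDuplicated(windows$window_id)) stop("duplicate window_id")
  x <- list(
    n_scans = n_scans, im_begin = im_begin, im_end = im_end,
    n_bins = n_bins, mz_min = mz_min, mz_max = mz_max,
    sqrt0 = sqrt(mz_min),
    dsqrt = (sqrt(mz_max) - sqrt(mz_min)) / (n_bins - 1),
    windows = windows,
    frames_per_window = as.integer(frames_per_window),
    cycle_time = cycle_time
  )
  class(x) <- "frame_spec"
  x
}

#' @export
print.frame_spec <- function(x, ...) {
  cat(sprintf(
    "frame_spec: %d scans (1/K0 %.3f-%.3f), %d mass bins (%.1f-%.1f Th),\n  %d windows, %d frame(s) per window, cycle time %.2f s\n",
    x$n_scans, x$im_begin, x$im_end, x$n_bins, x$mz_min, x$mz_max,
    nrow(x$windows), x$frames_per_window, x$cycle_time))
  invisible(x)
}

#' Coordinate maps of a frame_spec
#'
#' Convert between mass bin index and m/z (affine in sqrt(m/z)) and between
#' scan index and 1/K0 (affine). Bin and scan indices are 0-based;
#' `mz_to_bin()` and `im_to_scan()` return real values, round to the nearest
#' integer for an index.
#'
#' @param spec A [frame_spec()].
#' @param bin,scan 0-based indices (may be fractional).
#' @param mz m/z values (Th).
#' @param im 1/K0 values (Vs/cm2).
#' @return Numeric vector of converted coordinates.
#' @export
bin_to_mz <- function(spec, bin) (spec$sqrt0 + bin * spec$dsqrt)^2

#' @rdname bin_to_mz
#' @export
mz_to_bin <- function(spec, mz) (sqrt(mz) - spec$sqrt0) / spec$dsqrt

#' @rdname bin_to_mz
#' @export
scan_to_im <- function(spec, scan)
  spec$im_begin + scan * (spec$im_end - spec$im_begin) / (spec$n_scans - 1)

#' @rdname bin_to_mz
#' @export
im_to_scan <- function(spec, im)
  (im - spec$im_begin) / (spec$im_end - spec$im_begin) * (spec$n_scans - 1)

#' Default scaled-down dia-PASEF window scheme
#'
#' An 8-window scheme covering 400-1000 Th with 120 TIMS scans over 1/K0
#' 0.7-1.43 Vs/cm2, mirroring a 32 x 25 Th production scheme at desk scale.
#' The mass axis uses 262144 bins (about 3.7 ppm per bin at mid-range) so
#' that ppm-level mass tolerances remain meaningful on the binned axis.
#'
#' @param frames_per_window Identical repeated frames per cycle.
#' @return A [frame_spec()].
#' @export
default_frame_spec <- function(frames_per_window = 1L) {
  edges <- seq(400, 1000, by = 75)
  frame_spec(
    n_scans = 120L, im_begin = 0.7, im_end = 1.43,
    n_bins = 262144L, mz_min = 395, mz_max = 1005,
    windows = data.frame(
      mz_low = edges[-length(edges)], mz_high = edges[-1],
      scan_low = 0L, scan_high = 120L,
      window_id = seq_len(length(edges) - 1L)
    ),
    frames_per_window = frames_per_window, cycle_time = 1.0
  )
}

#' A sparse dia-PASEF frame
#'
#' One frame: the sparse 2D (scan x mass bin) point cloud acquired for one
#' isolation window in one cycle. `window_id` 0 denotes an MS1 frame.
#'
#' @param window_id Integer window id (0 = MS1).
#' @param cycle 0-based cycle index.
#' @param points `data.frame` with 0-based integer `scan`, `bin` and
#'   non-negative `intensity`; duplicate (scan, bin) pairs are summed.
#' @param spec Optional [frame_spec()] for bounds checking.
#' @return An object of class `im_frame`.
#' @export
im_frame <- function(window_id, cycle, points, spec = NULL) {
  points <- as.data.frame(points)
  stopifnot(all(c("scan", "bin", "intensity") %in% names(points)))
  if (any(points$intensity < 0)) stop("negative intensity")
  if (!is.null(spec)) {
    if (any(points$scan < 0L | points$scan >= spec$n_scans))
      stop("scan out of range")
    if (any(points$bin < 0L | points$bin >= spec$n_bins))
      stop("bin out of range")
  }
  dt <- data.table::as.data.table(points)
  dt <- dt[intensity > 0, .(intensity = sum(intensity)), by = .(scan, bin)]
  x <- list(window_id = as.integer(window_id), cycle = as.integer(cycle),
            points = as.data.frame(dt))
  class(x) <- "im_frame"
  x
}

#' A picked 2D spectrum
#'
#' Output of the 2D peak picker for one (window, cycle): peak triples
#' (m/z, 1/K0, summed intensity), stored sorted by m/z.
#'
#' @param window_id,cycle As in [im_frame()].
#' @param peaks `data.frame` with `mz`, `inv_k0`, `intensity`.
#' @return An object of class `picked_spectrum`.
#' @export
picked_spectrum <- function(window_id, cycle, peaks) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("mz", "inv_k0", "intensity") %in% names(peaks)))
  if (any(peaks$intensity <= 0)) stop("picked peak with non-positive intensity")
  o <- order(peaks$mz, peaks$inv_k0)
  x <- list(window_id = as.integer(window_id), cycle = as.integer(cycle),
            peaks = peaks[o, , drop = FALSE])
  rownames(x$peaks) <- NULL
  class(x) <- "picked_spectrum"
  x
}
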
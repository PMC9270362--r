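#' Scanning-window tolerances for 2D peak picking
#'
#' The 2D scanning window in the 1/K0 x m/z plane is defined by three
#' tolerances: (i) the ion mobility tolerance in TOF scans,
#' `10 * (n_scans / 900) / im_range`, kept real-valued; (ii) the m/z
#' tolerance in mass bins, fixed at 2; (iii) a mixed criterion: a point at
#' offsets (dscan, dbin) from the window center contributes to the window
#' only when `|dscan| + 2 * |dbin| * im_scale < im_tol_scans`, with
#' `im_scale = (n_scans / 900) / im_range`. The window size is deliberately
#' independent of the TIMS ramp time.
#'
#' @param spec A [frame_spec()].
#' @param mz_tol_bins m/z tolerance in bins (default 2).
#' @param im_tol_scans Optional override of the ion mobility tolerance.
#' @return Object of class `window_tolerances` with fields `im_tol_scans`,
#'   `mz_tol_bins`, `im_scale`.
#' @export
scan_window_tolerances <- function(spec, mz_tol_bins = 2L, im_tol_scans = NULL) {
  im_range <- abs(spec$im_end - spec$im_begin)
  if (im_range == 0) stop("degenerate mobility axis: 1/K0 range is zero")
  im_scale <- (spec$n_scans / 900) / im_range
  tol <- list(
    im_tol_scans = if (is.null(im_tol_scans)) 10 * im_scale else im_tol_scans,
    mz_tol_bins = as.integer(mz_tol_bins),
    im_scale = im_scale
  )
  stopifnot(tol$im_tol_scans > 0, tol$mz_tol_bins >= 0L)
  class(tol) <- "window_tolerances"
  tol
}

## scan/bin offsets belonging to the scanning window (criteria i-iii)
mask_offsets <- function(tol) {
  smax <- ceiling(tol$im_tol_scans)
  grid <- expand.grid(ds = -smax:smax, db = -tol$mz_tol_bins:tol$mz_tol_bins)
  keep <- abs(grid$ds) <= tol$im_tol_scans &
    (abs(grid$ds) + 2 * abs(grid$db) * tol$im_scale) < tol$im_tol_scans
  grid[keep, , drop = FALSE]
}

#' Sum of signals within the scanning window
#'
#' Sum of point intensities of `frame` whose offsets from
#' (`center_scan`, `center_bin`) satisfy the three window criteria of
#' [scan_window_tolerances()]. An empty neighborhood sums to 0.
#'
#' @param frame An [im_frame()].
#' @param center_scan,center_bin Window center (0-based indices).
#' @param tol A [scan_window_tolerances()] object.
#' @return The summed intensity (>= 0).
#' @export
window_sum <- function(frame, center_scan, center_bin, tol) {
  p <- frame$points
  if (nrow(p) == 0L) return(0)
  ds <- abs(p$scan - center_scan)
  db <- abs(p$bin - center_bin)
  sum(p$intensity[db <= tol$mz_tol_bins & ds <= tol$im_tol_scans &
                    (ds + 2 * db * tol$im_scale) < tol$im_tol_scans])
}

#' Sum identical repeated frames of one cycle
#'
#' When several identical dia-PASEF frames are acquired per cycle (to raise
#' the duty cycle), their profile data are summed per (scan, bin) before 2D
#' peak picking.
#'
#' @param frames List of [im_frame()]s sharing `window_id` and `cycle`.
#' @param spec A [frame_spec()] (bounds check).
#' @return One merged [im_frame()].
#' @export
merge_identical_frames <- function(frames, spec = NULL) {
  stopifnot(length(frames) >= 1L)
  wid <- vapply(frames, `[[`, integer(1), "window_id")
  cyc <- vapply(frames, `[[`, integer(1), "cycle")
  if (length(unique(wid)) != 1L)
    stop("cannot merge frames with mismatched window_id")
  if (length(unique(cyc)) != 1L)
    stop("cannot merge frames with mismatched cycle")
  if (length(frames) == 1L) return(frames[[1]])
  pts <- data.table::rbindlist(lapply(frames, `[[`, "points"))
  im_frame(wid[1], cyc[1], as.data.frame(pts), spec = spec)
}

#' Two-step 2D peak picking
#'
#' Step 1 selects local maxima of the scanning-window sum: a window center is
#' a local maximum when its [window_sum()] beats the sum at every neighboring
#' center position (neighborhood = the scanning window itself; exact ties are
#' broken deterministically in favor of the center with the higher raw
#' intensity at the center coordinate itself, then the lower mass bin, then
#' the lower scan — so an isolated point is reported at its own
#' coordinates). Step 2 discards a candidate maximum when any more intense candidate
#' maximum lies within its scanning window at a mass difference of at most
#' one bin; suppression uses the candidate set before discarding, so a
#' suppressed maximum can still suppress a weaker one. Each surviving peak is
#' reported as the triple (m/z, 1/K0, window sum) at its center coordinates,
#' sorted by m/z.
#'
#' @param frame An [im_frame()].
#' @param spec A [frame_spec()].
#' @param tol Tolerances; default [scan_window_tolerances()] of `spec`.
#' @return A [picked_spectrum()] (empty frame gives an empty spectrum).
#' @export
pick_peaks_2d <- function(frame, spec, tol = scan_window_tolerances(spec)) {
  pts <- data.table::as.data.table(frame$points)
  if (nrow(pts) == 0L)
    return(picked_spectrum(frame$window_id, frame$cycle,
                           data.frame(mz = numeric(), inv_k0 = numeric(),
                                      intensity = numeric())))
  pts[, fid := 0]
  pk <- pick_peaks_engine(pts, spec, tol)
  picked_spectrum(frame$window_id, frame$cycle,
                  pk[, c("mz", "inv_k0", "intensity")])
}

## Vectorized multi-frame picking engine. `pts` has columns fid (numeric
## frame index), scan, bin, intensity (> 0). Returns a data.frame with
## fid, scan, bin, mz, inv_k0, intensity of surviving peaks.
pick_peaks_engine <- function(pts, spec, tol = scan_window_tolerances(spec)) {
  offs <- mask_offsets(tol)
  n_scans <- spec$n_scans; n_bins <- spec$n_bins
  np <- nrow(pts); K <- nrow(offs)
  idx <- rep.int(seq_len(np), K)
  k <- rep(seq_len(K), each = np)
  cs <- pts$scan[idx] + offs$ds[k]
  cb <- pts$bin[idx] + offs$db[k]
  ok <- cs >= 0L & cs < n_scans & cb >= 0L & cb < n_bins
  cent <- data.table::data.table(fid = pts$fid[idx][ok], cs = cs[ok],
                                 cb = cb[ok], ssum = pts$intensity[idx][ok])
  cent <- cent[, .(ssum = sum(ssum)), by = .(fid, cs, cb)]
  cent <- cent[ssum > 0]
  ## raw intensity at the center coordinate itself (tie-break key)
  pkey <- (pts$fid * n_bins + pts$bin) * n_scans + pts$scan
  if (nrow(cent) == 0L)
    return(data.frame(fid = numeric(), scan = integer(), bin = integer(),
                      mz = numeric(), inv_k0 = numeric(), intensity = numeric()))
  ckey <- (cent$fid * n_bins + cent$cb) * n_scans + cent$cs
  mp <- match(ckey, pkey)
  cpi <- ifelse(is.na(mp), 0, pts$intensity[mp])
  ## step 1: beat every neighboring center position; surviving candidates
  ## shrink with each offset, so later offsets test fewer centers
  alive <- seq_len(nrow(cent))
  offs1 <- offs[!(offs$ds == 0L & offs$db == 0L), , drop = FALSE]
  offs1 <- offs1[order(abs(offs1$ds) + abs(offs1$db)), , drop = FALSE]
  for (j in seq_len(nrow(offs1))) {
    if (!length(alive)) break
    ds <- offs1$ds[j]; db <- offs1$db[j]
    ns <- cent$cs[alive] + ds; nb <- cent$cb[alive] + db
    valid <- ns >= 0L & ns < n_scans & nb >= 0L & nb < n_bins
    m <- match((cent$fid[alive] * n_bins + nb) * n_scans + ns, ckey)
    nsum <- ifelse(is.na(m) | !valid, 0, cent$ssum[m])
    ncpi <- ifelse(is.na(m) | !valid, 0, cpi[m])
    ## exact ties fall to the higher raw center intensity, then to the
    ## lower (bin, scan): for this offset the neighbor precedes the center
    ## in that order iff db < 0 or (db == 0 and ds < 0)
    nb_tie_wins <- db < 0L || (db == 0L && ds < 0L)
    s0 <- cent$ssum[alive]; c0 <- cpi[alive]
    beaten <- nsum > s0 | (nsum == s0 & ncpi > c0)
    if (nb_tie_wins) beaten <- beaten | (nsum == s0 & ncpi == c0)
    alive <- alive[!beaten]
  }
  cand <- cent[alive]
  if (nrow(cand) == 0L)
    return(data.frame(fid = numeric(), scan = integer(), bin = integer(),
                      mz = numeric(), inv_k0 = numeric(), intensity = numeric()))
  ## step 2: suppress by more intense candidate maxima within the scanning
  ## window at <= 1 bin mass difference (pre-discard candidate set)
  dkey <- (cand$fid * n_bins + cand$cb) * n_scans + cand$cs
  offs2 <- offs[abs(offs$db) <= 1L & !(offs$ds == 0L & offs$db == 0L), ,
                drop = FALSE]
  keep2 <- rep(TRUE, nrow(cand))
  for (j in seq_len(nrow(offs2))) {
    ds <- offs2$ds[j]; db <- offs2$db[j]
    ns <- cand$cs + ds; nb <- cand$cb + db
    valid <- ns >= 0L & ns < n_scans & nb >= 0L & nb < n_bins
    m <- match((cand$fid * n_bins + nb) * n_scans + ns, dkey)
    nsum <- ifelse(is.na(m) | !valid, 0, cand$ssum[m])
    keep2 <- keep2 & !(nsum > cand$ssum)
  }
  out <- cand[keep2]
  out <- out[order(out$cb, out$cs)]
  data.frame(fid = out$fid, scan = out$cs, bin = out$cb,
             mz = bin_to_mz(spec, out$cb), inv_k0 = scan_to_im(spec, out$cs),
             intensity = out$ssum)
}

#' Pick peaks for a whole run
#'
#' Groups frames by (window, cycle), sums identical repeated frames, and
#' runs the 2D picker on every merged frame in one vectorized pass.
#'
#' @param frames List of [im_frame()]s (may contain `frames_per_window`
#'   repeats per (window, cycle)).
#' @param spec A [frame_spec()].
#' @param tol Tolerances; default from `spec`.
#' @return List of [picked_spectrum()], one per (window, cycle) present.
#' @export
pick_run <- function(frames, spec, tol = scan_window_tolerances(spec)) {
  if (length(frames) == 0L) return(list())
  pts <- data.table::rbindlist(lapply(frames, function(f) {
    if (nrow(f$points) == 0L) return(NULL)
    data.table::data.table(window_id = f$window_id, cycle = f$cycle, f$points)
  }))
  keys <- unique(data.table::data.table(
    window_id = vapply(frames, `[[`, integer(1), "window_id"),
    cycle = vapply(frames, `[[`, integer(1), "cycle")))
  data.table::setorder(keys, window_id, cycle)
  keys[, fid := as.numeric(seq_len(.N) - 1L)]
  if (is.null(pts) || nrow(pts) == 0L) {
    pk <- data.frame(fid = numeric(), mz = numeric(), inv_k0 = numeric(),
                     intensity = numeric())
  } else {
    ## summing repeated frames == aggregating duplicate (scan, bin) here
    pts <- merge(pts, keys, by = c("window_id", "cycle"))
    pts <- pts[intensity > 0, .(intensity = sum(intensity)),
               by = .(fid, scan, bin)]
    pk <- pick_peaks_engine(pts, spec, tol)
  }
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- pk[pk$fid == keys$fid[i], c("mz", "inv_k0", "intensity")]
    picked_spectrum(keys$window_id[i], keys$cycle[i], sub)
  })
}
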
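#' Fit run calibration from confident identifications
#'
#' Aligns a run against the spectral library: an affine ion-mobility map
#' (library 1/K0 -> observed 1/K0) by trimmed least squares, a data-driven
#' ion mobility window, a monotone piecewise-linear retention-time map
#' (reference retention index -> cycle), and a median ppm mass correction
#' with a data-driven ppm tolerance capped at `ppm_cap`.
#'
#' With fewer than `min_ids` identifications the calibration falls back to
#' identity maps with default windows (with a warning), so downstream
#' extraction still works on sparse data.
#'
#' @param ids `data.frame` of confident identifications with columns
#'   `ref_im`, `obs_im`, `ref_rt`, `obs_cycle`, `ppm_err` (observed-vs-library
#'   mass error in ppm; may be `NA`).
#' @param spec A [frame_spec()] (supplies the fallback retention range).
#' @param n_cycles Cycles in the run (fallback RT map range).
#' @param min_ids Minimum identifications before falling back (default 20).
#' @param im_floor Ion mobility window floor, Vs/cm2 (default 0.02).
#' @param ppm_floor,ppm_cap Mass tolerance floor / cap in ppm (3 / 10).
#' @param trim Fraction of worst residuals trimmed in the robust IM fit.
#' @return Object of class `im_calibration` with fields `im_slope`,
#'   `im_intercept`, `im_window`, `rt_x`, `rt_y` (monotone knots),
#'   `rt_resid_q95`, `mass_correction_ppm`, `mass_tol_ppm`, `fallback`.
#' @export
fit_calibration <- function(ids, spec, n_cycles, min_ids = 20L,
                            im_floor = 0.02, ppm_floor = 3, ppm_cap = 10,
                            trim = 0.2) {
  default_cal <- function() {
    x <- list(im_slope = 1, im_intercept = 0, im_window = 0.05,
              rt_x = c(0, 1), rt_y = c(0, n_cycles - 1),
              rt_resid_q95 = n_cycles / 3,
              mass_correction_ppm = 0, mass_tol_ppm = ppm_cap,
              fallback = TRUE)
    class(x) <- "im_calibration"
    x
  }
  if (is.null(ids) || nrow(ids) < min_ids) {
    warning(sprintf("calibration: only %d confident identification(s) (< %d); using identity maps with default windows",
                    if (is.null(ids)) 0L else nrow(ids), min_ids), call. = FALSE)
    return(default_cal())
  }
  ## --- ion mobility: trimmed least-squares line
  fit1 <- lm(obs_im ~ ref_im, data = ids)
  r <- abs(residuals(fit1))
  keep <- r <= quantile(r, 1 - trim)
  fit2 <- lm(obs_im ~ ref_im, data = ids[keep, , drop = FALSE])
  im_slope <- unname(coef(fit2)[2]); im_intercept <- unname(coef(fit2)[1])
  im_res <- abs(ids$obs_im[keep] - (im_slope * ids$ref_im[keep] + im_intercept))
  im_window <- max(unname(quantile(im_res, 0.95)), im_floor)
  ## --- retention time: monotone piecewise-linear map
  nb <- max(2L, min(8L, floor(nrow(ids) / 10)))
  brk <- unique(quantile(ids$ref_rt, probs = seq(0, 1, length.out = nb + 1L)))
  grp <- cut(ids$ref_rt, breaks = brk, include.lowest = TRUE)
  rt_x <- tapply(ids$ref_rt, grp, median)
  rt_y <- tapply(ids$obs_cycle, grp, median)
  ok <- !is.na(rt_x) & !is.na(rt_y)
  rt_x <- as.numeric(rt_x[ok]); rt_y <- cummax(as.numeric(rt_y[ok]))
  if (length(rt_x) < 2L) { rt_x <- c(0, 1); rt_y <- c(0, n_cycles - 1) }
  rt_fun <- approxfun(rt_x, rt_y, rule = 2)
  rt_resid_q95 <- max(unname(quantile(abs(ids$obs_cycle - rt_fun(ids$ref_rt)),
                                      0.95)), 1)
  ## --- mass: median ppm offset, q95 residual tolerance
  ppm <- ids$ppm_err[is.finite(ids$ppm_err)]
  if (length(ppm) >= min_ids / 2) {
    corr <- median(ppm)
    tol <- min(ppm_cap, max(unname(quantile(abs(ppm - corr), 0.95)), ppm_floor))
  } else {
    corr <- 0; tol <- ppm_cap
  }
  x <- list(im_slope = im_slope, im_intercept = im_intercept,
            im_window = im_window, rt_x = rt_x, rt_y = rt_y,
            rt_resid_q95 = rt_resid_q95, mass_correction_ppm = corr,
            mass_tol_ppm = tol, fallback = FALSE)
  class(x) <- "im_calibration"
  x
}

#' Map a reference retention index to a cycle
#' @param calib An `im_calibration`.
#' @param ref_rt Reference retention index values.
#' @return Predicted apex cycle (real-valued).
#' @export
rt_to_cycle <- function(calib, ref_rt)
  approxfun(calib$rt_x, calib$rt_y, rule = 2)(ref_rt)

#' Wide-open calibration for the first search pass
#'
#' Identity IM and RT maps with wide windows, used to collect the confident
#' identifications from which [fit_calibration()] derives the run-specific
#' tolerances.
#'
#' @param n_cycles Number of cycles in the run.
#' @param im_window Wide ion mobility half-window (default 0.1 Vs/cm2).
#' @param mass_tol_ppm Wide-open mass tolerance (default 10 ppm).
#' @return An `im_calibration`.
#' @export
wide_calibration <- function(n_cycles, im_window = 0.1, mass_tol_ppm = 10) {
  x <- list(im_slope = 1, im_intercept = 0, im_window = im_window,
            rt_x = c(0, 1), rt_y = c(0, n_cycles - 1),
            rt_resid_q95 = n_cycles, mass_correction_ppm = 0,
            mass_tol_ppm = mass_tol_ppm, fallback = TRUE)
  class(x) <- "im_calibration"
  x
}
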
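#' Ion-mobility-filtered precursor quantity
#'
#' Integrates each fragment trace over apex +/- `width` cycles and sums over
#' the retained signals. With the ion mobility filter enabled, the consensus
#' 1/K0 is the median of the fragment apex mobilities, and every extracted
#' point whose 1/K0 deviates from it by more than half the ion mobility
#' window is excluded from the integral (so an interfering peptide that
#' hijacks part of a trace contributes nothing); a fragment whose points are
#' all excluded contributes 0. When every fragment is excluded the quantity
#' is `NA` with attribute `all_im_filtered = TRUE`.
#'
#' @param chrom A [extract_chromatograms()] result.
#' @param apex_cycle Accepted candidate apex (absolute cycle).
#' @param im_window Ion mobility window (Vs/cm2); the gate is `im_window / 2`.
#' @param width Integration half-width in cycles (default 2).
#' @param im_filter Apply the ion mobility gate? (ablation toggle).
#' @return Numeric quantity (>= 0) or `NA`.
#' @export
quantify_precursor <- function(chrom, apex_cycle, im_window, width = 2L,
                               im_filter = TRUE) {
  fr <- which(!chrom$ions$is_precursor)
  a <- match(apex_cycle, chrom$cycles)
  if (is.na(a) || !length(fr)) return(NA_real_)
  nc <- length(chrom$cycles)
  lo <- max(1L, a - width); hi <- min(nc, a + width)
  x <- chrom$intensity[fr, , drop = FALSE]
  imx <- chrom$inv_k0[fr, , drop = FALSE]
  apex_im <- imx[, a]
  ## fall back to the nearest integrated cycle for fragments missing at apex
  for (i in which(is.na(apex_im))) {
    seg <- imx[i, lo:hi]
    if (!all(is.na(seg))) apex_im[i] <- seg[which(!is.na(seg))[1]]
  }
  seg_x <- x[, lo:hi, drop = FALSE]
  if (!im_filter) return(sum(seg_x, na.rm = TRUE))
  med <- median(apex_im, na.rm = TRUE)
  keep_cell <- !is.na(seg_x) &
    abs(imx[, lo:hi, drop = FALSE] - med) <= im_window / 2
  if (!any(keep_cell, na.rm = TRUE)) {
    out <- NA_real_
    attr(out, "all_im_filtered") <- TRUE
    return(out)
  }
  sum(seg_x[keep_cell])
}

#' Median-ratio run normalization
#'
#' Scales each run (column) by the median of its feature-wise ratios to the
#' per-feature median profile, so the median per-run log-ratio is zero after
#' normalization. A run with no usable features is left unscaled with a
#' warning.
#'
#' @param mat Numeric matrix, features x runs, `NA` = missing.
#' @return The normalized matrix (attribute `size_factors` holds the per-run
#'   scale factors).
#' @export
normalize_runs <- function(mat) {
  mat <- as.matrix(mat)
  ref <- apply(mat, 1, median, na.rm = TRUE)
  sf <- rep(1, ncol(mat))
  for (r in seq_len(ncol(mat))) {
    ratio <- mat[, r] / ref
    ratio <- ratio[is.finite(ratio) & ratio > 0]
    if (!length(ratio)) {
      warning(sprintf("run %d has no usable features; left unscaled", r),
              call. = FALSE)
      next
    }
    sf[r] <- median(ratio)
  }
  out <- sweep(mat, 2, sf, "/")
  attr(out, "size_factors") <- sf
  out
}

#' MaxLFQ-style protein quantities
#'
#' For one protein group: the median log-ratio between every pair of runs is
#' computed over their shared precursors, and per-run log-quantities are the
#' least-squares solution of the pairwise ratio system, determined up to one
#' additive constant per connected component of the run-pair graph; the
#' constant is fixed so the total protein intensity matches the total
#' precursor intensity of the component. Single-precursor groups pass
#' through; runs in different components are solved separately and flagged.
#'
#' @param mat Numeric matrix, precursors x runs, raw quantities, `NA` =
#'   missing.
#' @return Numeric vector of per-run protein quantities (`NA` where no
#'   precursor was quantified); attribute `n_components` gives the number of
#'   connected components among runs with data.
#' @export
maxlfq_protein <- function(mat) {
  mat <- as.matrix(mat)
  nr <- ncol(mat)
  has_data <- colSums(!is.na(mat) & mat > 0) > 0L
  out <- rep(NA_real_, nr)
  if (nrow(mat) == 1L) {            # single-precursor group passes through
    out[has_data] <- mat[1, has_data]
    attr(out, "n_components") <- as.integer(sum(has_data) > 0)
    return(out)
  }
  lmat <- log2(mat)
  lmat[!is.finite(lmat)] <- NA
  ## pairwise median log-ratios over shared precursors
  pairs <- list()
  for (r in seq_len(nr - 1L)) for (s in (r + 1L):nr) {
    sh <- which(!is.na(lmat[, r]) & !is.na(lmat[, s]))
    if (length(sh) >= 1L)
      pairs[[length(pairs) + 1L]] <- c(r, s, median(lmat[sh, r] - lmat[sh, s]))
  }
  ## connected components over runs with data
  comp <- seq_len(nr)
  for (p in pairs) {
    cr <- comp[p[1]]; cs <- comp[p[2]]
    if (cr != cs) comp[comp == cs] <- cr
  }
  ncomp <- 0L
  for (cc in unique(comp[has_data])) {
    runs <- which(comp == cc & has_data)
    ncomp <- ncomp + 1L
    if (length(runs) == 1L) {
      out[runs] <- sum(mat[, runs], na.rm = TRUE)
      next
    }
    sub <- Filter(function(p) p[1] %in% runs && p[2] %in% runs, pairs)
    ## least squares on x_r - x_s = m_rs with a zero-mean gauge constraint
    k <- length(runs)
    A <- matrix(0, length(sub) + 1L, k)
    b <- numeric(length(sub) + 1L)
    for (i in seq_along(sub)) {
      A[i, match(sub[[i]][1], runs)] <- 1
      A[i, match(sub[[i]][2], runs)] <- -1
      b[i] <- sub[[i]][3]
    }
    A[length(sub) + 1L, ] <- 1                 # gauge: mean(x) = 0
    x <- qr.solve(crossprod(A), crossprod(A, b))
    q <- 2^as.numeric(x)
    total <- sum(mat[, runs], na.rm = TRUE)
    out[runs] <- q * total / sum(q)
  }
  attr(out, "n_components") <- ncomp
  if (ncomp > 1L) attr(out, "disconnected") <- TRUE
  out
}

#' Coefficients of variation across replicates
#'
#' CV = sd/mean on raw (unlogged) quantities per replicate group. The
#' summary `median_cv` covers only features quantified in every replicate of
#' the group.
#'
#' @param mat Numeric matrix, features x runs.
#' @param groups Character/factor of length `ncol(mat)` assigning runs to
#'   replicate groups.
#' @return List with `per_feature` (`data.frame`: feature, group, cv,
#'   complete) and `median_cv` (named by group, complete features only).
#' @export
cv_report <- function(mat, groups) {
  mat <- as.matrix(mat)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(mat))
  res <- list()
  for (g in unique(groups)) {
    sub <- mat[, groups == g, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1, sd, na.rm = TRUE)
    complete <- rowSums(is.na(sub)) == 0L
    res[[g]] <- data.frame(
      feature = if (is.null(rownames(mat))) seq_len(nrow(mat)) else rownames(mat),
      group = g, cv = s / m, complete = complete)
  }
  per_feature <- do.call(rbind, res)
  rownames(per_feature) <- NULL
  med <- vapply(unique(groups), function(g) {
    d <- res[[g]]
    median(d$cv[d$complete & is.finite(d$cv)])
  }, numeric(1))
  list(per_feature = per_feature, median_cv = med)
}
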
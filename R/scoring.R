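#' Generate pseudo-reversed decoys
#'
#' One decoy per target precursor: the sequence is reversed with the
#' C-terminal residue kept in place (preserving the tryptic terminus and the
#' precursor mass), fragment m/z values are recomputed from the decoy
#' sequence for b/y annotations, and reference RT / 1/K0 are inherited. A
#' decoy colliding with a target sequence (palindromic peptide) is repaired
#' by swapping its first two residues.
#'
#' @param library A target [spectral_library()].
#' @return A [spectral_library()] of decoys (`decoy = TRUE`, protein groups
#'   prefixed `DECOY_`), same precursor count as the targets.
#' @export
generate_decoys <- function(library) {
  prec <- library$precursors[!library$precursors$decoy, , drop = FALSE]
  frag <- library$fragments
  target_seqs <- unique(prec$modified_sequence)
  dseqs <- character(nrow(prec))
  for (i in seq_len(nrow(prec))) {
    s <- strsplit(prec$modified_sequence[i], "")[[1]]
    n <- length(s)
    d <- c(rev(s[-n]), s[n])
    if (paste(d, collapse = "") %in% target_seqs && n >= 3L)
      d[c(1L, 2L)] <- d[c(2L, 1L)]
    dseqs[i] <- paste(d, collapse = "")
  }
  dprec <- prec
  dprec$modified_sequence <- dseqs
  dprec$decoy <- TRUE
  dprec$protein_group <- paste0("DECOY_", prec$protein_group)
  max_id <- max(library$precursors$precursor_id)
  dprec$precursor_id <- max_id + seq_len(nrow(dprec))
  dfr <- vector("list", nrow(prec))
  for (i in seq_len(nrow(prec))) {
    fr <- frag[frag$precursor_id == prec$precursor_id[i], , drop = FALSE]
    newmz <- fragment_mz(dseqs[i], fr$annotation)
    fr$mz <- ifelse(is.na(newmz), fr$mz + 11.0, newmz)
    fr$precursor_id <- dprec$precursor_id[i]
    dfr[[i]] <- fr
  }
  spectral_library(dprec, data.table::rbindlist(dfr),
                   metadata = c(library$metadata, decoys = "pseudo-reverse"))
}

#' Combine target and decoy libraries
#' @param targets,decoys [spectral_library()] objects.
#' @return A merged [spectral_library()].
#' @export
combine_libraries <- function(targets, decoys) {
  spectral_library(rbind(targets$precursors, decoys$precursors),
                   rbind(targets$fragments, decoys$fragments),
                   metadata = targets$metadata)
}

#' Find candidate elution peaks
#'
#' Local maxima of the 3-point-smoothed summed fragment trace at which at
#' least `min_fragments` different fragments have signal (non-missing points
#' within one cycle of the apex). Maxima must strictly exceed both
#' neighbors of the smoothed trace.
#'
#' @param chrom A [extract_chromatograms()] result.
#' @param min_fragments Minimum co-detected fragments (default 2).
#' @return `data.frame` with `apex_cycle` (absolute cycle index),
#'   `n_fragments_detected`, `total_intensity`; zero rows when nothing
#'   qualifies.
#' @export
find_candidate_peaks <- function(chrom, min_fragments = 2L) {
  empty <- data.frame(apex_cycle = integer(), n_fragments_detected = integer(),
                      total_intensity = numeric())
  nc <- length(chrom$cycles)
  if (nc < 3L) return(empty)
  fr <- which(!chrom$ions$is_precursor)
  if (length(fr) < min_fragments) return(empty)
  x <- chrom$intensity[fr, , drop = FALSE]
  tot <- colSums(x, na.rm = TRUE)
  sm <- (c(tot[1], tot[-nc]) + tot + c(tot[-1], tot[nc])) / 3
  is_max <- c(FALSE, sm[2:(nc - 1)] > sm[1:(nc - 2)] &
                sm[2:(nc - 1)] > sm[3:nc], FALSE)
  apex <- which(is_max)
  if (!length(apex)) return(empty)
  res <- lapply(apex, function(a) {
    lo <- max(1L, a - 1L); hi <- min(nc, a + 1L)
    det <- rowSums(!is.na(x[, lo:hi, drop = FALSE])) > 0L
    if (sum(det) < min_fragments) return(NULL)
    data.frame(apex_cycle = chrom$cycles[a], n_fragments_detected = sum(det),
               total_intensity = tot[a])
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  do.call(rbind, res)
}

#' Ion-mobility-aware feature vector of a candidate peak
#'
#' Computes the peptide-spectrum-match features: cosine similarity of
#' (outlier-down-weighted) fragment apex intensities to the library
#' intensities, mean pairwise-style profile correlation of each fragment to
#' the consensus of the others, ion mobility consistency (robust spread of
#' the fragment apex 1/K0 values: their mean absolute deviation from the
#' median, which stays informative although apex mobilities are quantized
#' to scan positions), ion mobility deviation of the median
#' fragment 1/K0 from the calibrated library value, retention-time deviation,
#' mean absolute ppm error, fraction of library fragments detected, and log
#' apex intensity. Fragments whose apex 1/K0 deviates from the fragment
#' median by more than half the ion mobility window are down-weighted by
#' `outlier_weight` before the intensity similarity is computed.
#'
#' @param chrom A [extract_chromatograms()] result.
#' @param apex_cycle Candidate apex (absolute cycle index).
#' @param entry One-row precursor data.frame (see
#'   [extract_chromatograms()]).
#' @param calib An `im_calibration`.
#' @param library The [spectral_library()].
#' @param outlier_weight Down-weight factor for IM-outlier fragments (0.25).
#' @return List with `features` (named numeric vector) and `fragments`
#'   (per-fragment data.frame: `mz`, `rel_intensity`, `apex_intensity`,
#'   `apex_inv_k0`, `detected`, `im_outlier`, `weight`, `ppm_err`).
#' @export
score_candidate <- function(chrom, apex_cycle, entry, calib, library,
                            outlier_weight = 0.25) {
  if (!is.data.frame(entry))
    entry <- library$precursors[library$precursors$precursor_id == entry, ]
  fr_rows <- which(!chrom$ions$is_precursor)
  frags <- library$fragments[library$fragments$precursor_id ==
                               entry$precursor_id, , drop = FALSE]
  a <- match(apex_cycle, chrom$cycles)
  nc <- length(chrom$cycles)
  lo <- max(1L, a - 1L); hi <- min(nc, a + 1L)
  x <- chrom$intensity[fr_rows, , drop = FALSE]
  imx <- chrom$inv_k0[fr_rows, , drop = FALSE]
  mzx <- chrom$obs_mz[fr_rows, , drop = FALSE]
  ## per-fragment apex stats: the most intense non-missing point in apex +- 1
  nfr <- length(fr_rows)
  apex_int <- apex_im <- apex_mz <- rep(NA_real_, nfr)
  for (i in seq_len(nfr)) {
    seg <- x[i, lo:hi]
    if (all(is.na(seg))) next
    jj <- lo:hi
    best <- jj[which.max(ifelse(is.na(seg), -Inf, seg))]
    apex_int[i] <- x[i, best]; apex_im[i] <- imx[i, best]
    apex_mz[i] <- mzx[i, best]
  }
  detected <- !is.na(apex_int)
  med_im <- median(apex_im[detected])
  im_outlier <- detected & abs(apex_im - med_im) > calib$im_window / 2
  weight <- ifelse(im_outlier, outlier_weight, 1)
  ## cosine of down-weighted apex intensities vs library intensities
  obs <- ifelse(is.na(apex_int), 0, apex_int) * weight
  libint <- frags$rel_intensity
  cosine <- if (sum(obs^2) > 0)
    sum(obs * libint) / sqrt(sum(obs^2) * sum(libint^2)) else 0
  ## profile correlation to the consensus of the other fragments
  wlo <- max(1L, a - 3L); whi <- min(nc, a + 3L)
  seg <- x[, wlo:whi, drop = FALSE]; seg[is.na(seg)] <- 0
  totseg <- colSums(seg)
  corr <- vapply(seq_len(nfr), function(i) {
    other <- totseg - seg[i, ]
    if (sd(seg[i, ]) == 0 || sd(other) == 0) return(0)
    cor(seg[i, ], other)
  }, numeric(1))
  mean_corr <- mean(corr[detected])
  ppm <- (apex_mz / (frags$mz * (1 + calib$mass_correction_ppm * 1e-6)) - 1) * 1e6
  mean_ppm <- if (any(detected)) mean(abs(ppm[detected])) else calib$mass_tol_ppm
  pred_im <- calib$im_slope * entry$ref_inv_k0 + calib$im_intercept
  feats <- c(
    cosine = cosine,
    mean_corr = mean_corr,
    im_spread = mean(abs(apex_im[detected] - med_im)),
    im_dev = abs(med_im - pred_im),
    rt_dev = abs(apex_cycle - rt_to_cycle(calib, entry$ref_rt)),
    mean_ppm = mean_ppm,
    frac_detected = mean(detected),
    log_intensity = log1p(sum(apex_int[detected]))
  )
  feats[!is.finite(feats)] <- 0
  list(features = feats,
       fragments = data.frame(mz = frags$mz, rel_intensity = libint,
                              apex_intensity = apex_int, apex_inv_k0 = apex_im,
                              detected = detected, im_outlier = im_outlier,
                              weight = weight, ppm_err = ppm))
}

## fixed label-free linear score used for candidate pre-selection and as the
## small-sample fallback of the classifier
fallback_scores <- function(X) {
  z <- function(col, w) {
    if (!col %in% colnames(X)) return(0)
    v <- X[, col]
    s <- sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, nrow(X)))
    w * (v - mean(v)) / s
  }
  z("cosine", 1) + z("mean_corr", 1) + z("frac_detected", 1) +
    z("log_intensity", 0.5) + z("im_spread", -1) + z("im_dev", -1) +
    z("rt_dev", -1) + z("mean_ppm", -0.5)
}

#' Train the classifier ensemble and score candidates
#'
#' Trains an ensemble of small feed-forward neural networks (single hidden
#' layer, 8 units, `nnet`) to separate target from decoy feature vectors,
#' with 2-fold cross-scoring: each candidate is scored only by ensemble
#' members that were not trained on it. The final score is the mean member
#' output. Fully deterministic given `seed`. With fewer than `min_n` targets
#' or decoys (or degenerate features) a fixed linear combination of the
#' features is used instead.
#'
#' @param features_targets,features_decoys Numeric feature matrices with
#'   identical column sets (rows = candidates).
#' @param seed Integer seed controlling fold split and weight init.
#' @param n_members Ensemble members (default 8).
#' @param min_n Minimum class size before falling back (default 50).
#' @return List with `target` and `decoy` score vectors (input order) and
#'   `method` ("ensemble" or "linear").
#' @export
train_and_score <- function(features_targets, features_decoys, seed = 1L,
                            n_members = 8L, min_n = 50L) {
  Xt <- as.matrix(features_targets); Xd <- as.matrix(features_decoys)
  stopifnot(identical(colnames(Xt), colnames(Xd)))
  X <- rbind(Xt, Xd)
  y <- c(rep(1, nrow(Xt)), rep(0, nrow(Xd)))
  sds <- apply(X, 2, sd)
  if (all(!is.finite(sds) | sds == 0)) {
    warning("degenerate features (no variance); using fixed linear score",
            call. = FALSE)
    s <- fallback_scores(X)
    return(list(target = s[seq_len(nrow(Xt))], decoy = s[-seq_len(nrow(Xt))],
                method = "linear"))
  }
  if (nrow(Xt) < min_n || nrow(Xd) < min_n) {
    s <- fallback_scores(X)
    return(list(target = s[seq_len(nrow(Xt))], decoy = s[-seq_len(nrow(Xt))],
                method = "linear"))
  }
  Xs <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  Xs[!is.finite(Xs)] <- 0
  ## stratified 2-fold split
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0, 1)) {
    i <- which(y == cls)
    fold[i] <- sample(rep(1:2, length.out = length(i)))
  }
  scores <- matrix(0, nrow(X), n_members)
  for (m in seq_len(n_members)) {
    for (f in 1:2) {
      tr <- fold != f
      set.seed(seed * 1000L + m * 10L + f)
      net <- nnet::nnet(x = Xs[tr, , drop = FALSE], y = y[tr], size = 8,
                        decay = 0.05, maxit = 120, entropy = TRUE,
                        trace = FALSE, rang = 0.5, MaxNWts = 2000)
      scores[!tr, m] <- predict(net, Xs[!tr, , drop = FALSE])
    }
  }
  s <- rowMeans(scores)
  list(target = s[seq_len(nrow(Xt))], decoy = s[-seq_len(nrow(Xt))],
       method = "ensemble")
}
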
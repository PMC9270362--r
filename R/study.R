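## Run calibration from a wide first search pass: sampled target precursors
## are extracted over the whole run with identity maps and wide windows,
## scored by cosine similarity to the library intensities, and the top
## (up to 100, cosine > 0.5) non-redundant hits become the confident
## identifications fed to fit_calibration().
calibrate_run <- function(index, library, spec, n_cycles, config, run_id) {
  targets <- library$precursors[!library$precursors$decoy, , drop = FALSE]
  wide <- wide_calibration(n_cycles, mass_tol_ppm = config$mass_tol_cap_ppm)
  set.seed(config$classifier_seed + string_seed(run_id))
  cal_rows <- if (nrow(targets) > config$calibration_n)
    sort(sample(nrow(targets), config$calibration_n))
  else seq_len(nrow(targets))
  ids <- list()
  for (i in cal_rows) {
    entry <- targets[i, ]
    ch <- extract_chromatograms(index, entry, wide, library,
                                cycles = 0:(n_cycles - 1L))
    cand <- find_candidate_peaks(ch)
    if (!nrow(cand)) next
    best <- NULL
    for (k in seq_len(nrow(cand))) {
      sc <- score_candidate(ch, cand$apex_cycle[k], entry, wide, library)
      if (is.null(best) || sc$features["cosine"] > best$cos) {
        fr <- sc$fragments[sc$fragments$detected, ]
        best <- list(cos = sc$features["cosine"],
                     row = data.frame(
                       ref_im = entry$ref_inv_k0,
                       obs_im = median(fr$apex_inv_k0),
                       ref_rt = entry$ref_rt, obs_cycle = cand$apex_cycle[k],
                       ppm_err = median(fr$ppm_err, na.rm = TRUE)))
      }
    }
    if (!is.null(best) && best$cos > 0.5)
      ids[[length(ids) + 1L]] <- cbind(best$row, cos = best$cos)
  }
  ids <- if (length(ids)) do.call(rbind, ids) else NULL
  if (!is.null(ids) && nrow(ids) > 100L)
    ids <- ids[order(-ids$cos)[1:100], ]
  calib <- fit_calibration(ids, spec, n_cycles,
                           ppm_cap = config$mass_tol_cap_ppm)
  attr(calib, "n_ids") <- if (is.null(ids)) 0L else nrow(ids)
  calib
}

#' Study-condition presets for the synthetic benchmarks
#'
#' Fixed simulation conditions used by the package's validation studies:
#' \describe{
#'   \item{default}{200 precursors, 40 cycles: sensitivity / identification.}
#'   \item{two_species}{Human + yeast spike-in (45:15 between conditions A
#'     and B) with interference, 120 precursors, 32 cycles: quantification
#'     accuracy.}
#'   \item{entrapment}{Human + Arabidopsis-style mixed library in which the
#'     entrapment species is present in the library but never planted in the
#'     runs, 160 precursors, 32 cycles: experimental FDR.}
#'   \item{interference}{Interference-rich single-species runs, 120
#'     precursors, 32 cycles: IM feature ablation.}
#'   \item{null}{Detector noise only, nothing planted, 200 library
#'     precursors, 32 cycles: null calibration of the q-value estimator.}
#' }
#'
#' @param type Condition name.
#' @param seed Base seed.
#' @return A [simulation_config()].
#' @export
study_config <- function(type = c("default", "two_species", "entrapment",
                                  "interference", "null"), seed = 1L) {
  type <- match.arg(type)
  switch(type,
    default = simulation_config(seed = seed, n_precursors = 200L,
                                n_cycles = 40L),
    two_species = simulation_config(
      seed = seed, n_precursors = 150L, n_cycles = 32L,
      species_prefix = c("HUM", "YST"), species_weights = c(0.8, 0.2),
      interference_density = 4, interference_intensity = c(2, 10),
      interference_im_shift = c(0.011, 0.02),
      interference_rt_shift = c(0, 2)),
    entrapment = simulation_config(
      seed = seed, n_precursors = 160L, n_cycles = 32L,
      species_prefix = c("HUM", "ATH"),
      spike = c(HUM = 1, ATH = 0)),
    interference = simulation_config(
      seed = seed, n_precursors = 150L, n_cycles = 32L,
      species_prefix = c("REA", "MIM"), species_weights = c(0.6, 0.4),
      spike = c(REA = 1, MIM = 0), mimic_im_shift = c(0.006, 0.02),
      interference_density = 2),
    null = simulation_config(seed = seed, n_precursors = 200L,
                             n_cycles = 32L, noise_only = TRUE))
}

#' Ion-mobility feature ablation on one run
#'
#' Labels every candidate elution peak of every target precursor by ground
#' truth (apex within `apex_tol` cycles of the planted apex = correct match;
#' interference- or noise-induced candidates = incorrect), trains the
#' classifier ensemble with and without the two ion mobility features (IM
#' consistency and IM deviation), and reports the held-out (cross-scored)
#' AUROC of both variants on the same labels.
#'
#' @param run A [simulate_run()] result.
#' @param library The target [spectral_library()] the run was built from.
#' @param config A [pipeline_config()].
#' @param seed Classifier seed.
#' @param apex_tol Cycles within which a candidate apex counts as correct.
#' @return Named numeric: `auroc_full`, `auroc_no_im`, `n_true`, `n_false`.
#' @export
im_feature_ablation <- function(run, library, config = pipeline_config(),
                                seed = 1L, apex_tol = 2) {
  spec <- run$spec
  n_cycles <- max(vapply(run$frames, `[[`, integer(1), "cycle")) + 1L
  index <- build_index(pick_run(run$frames, spec), spec,
                       n_cycles = n_cycles)
  calib <- calibrate_run(index, library, spec, n_cycles, config, "ablation")
  targets <- library$precursors[!library$precursors$decoy, , drop = FALSE]
  feats <- list(); labels <- logical(0)
  for (i in seq_len(nrow(targets))) {
    entry <- targets[i, ]
    tr <- run$truth[run$truth$precursor_id == entry$precursor_id, ]
    ch <- extract_chromatograms(index, entry, calib, library,
                                cycles = 0:(n_cycles - 1L))
    cand <- find_candidate_peaks(ch)
    if (!nrow(cand)) next
    for (k in seq_len(nrow(cand))) {
      sc <- score_candidate(ch, cand$apex_cycle[k], entry, calib, library)
      feats[[length(feats) + 1L]] <- sc$features
      labels <- c(labels,
                  nrow(tr) == 1L && tr$abundance > 0 &&
                    abs(cand$apex_cycle[k] - tr$apex_cycle) <= apex_tol)
    }
  }
  F <- do.call(rbind, feats)
  if (sum(labels) < 10L || sum(!labels) < 10L)
    stop("too few labelled candidates for an ablation comparison")
  full <- train_and_score(F[labels, , drop = FALSE],
                          F[!labels, , drop = FALSE],
                          seed = seed, min_n = 10L)
  Fn <- F[, setdiff(colnames(F), c("im_spread", "im_dev")), drop = FALSE]
  noim <- train_and_score(Fn[labels, , drop = FALSE],
                          Fn[!labels, , drop = FALSE],
                          seed = seed, min_n = 10L)
  c(auroc_full = auroc(full$target, full$decoy),
    auroc_no_im = auroc(noim$target, noim$decoy),
    n_true = sum(labels), n_false = sum(!labels))
}

#' Two-species spike-in ratio benchmark
#'
#' Simulates one two-species spike-in experiment (constant background
#' species, second species spiked 45:15 between conditions A and B in
#' triplicate), processes all six runs with the IM quantification filter
#' enabled and disabled (sharing picking and calibration between the two
#' variants), and returns the per-protein log2(A:B) ratio estimates.
#' Quantities are left unnormalized: the simulated runs carry identical
#' loading, so the ratio readout needs no between-run scaling.
#'
#' @param seed Experiment seed.
#' @param config A [simulation_config()]; default
#'   `study_config("two_species", seed)`.
#' @param pconfig A [pipeline_config()] (the IM filter toggle is overridden
#'   per variant).
#' @return `data.frame` with `protein_group`, `species`, `variant`
#'   ("im_filtered" / "unfiltered") and `log2_ab`; attribute `truth_log2`
#'   holds the exact spiked log2 ratio.
#' @export
two_species_benchmark <- function(seed = 1L,
                                  config = study_config("two_species", seed),
                                  pconfig = pipeline_config(normalize = FALSE)) {
  exp2 <- simulate_two_species_experiment(config)
  cfgs <- list(
    im_filtered = { x <- pconfig; x$im_quant_filter <- TRUE; x },
    unfiltered = { x <- pconfig; x$im_quant_filter <- FALSE; x })
  reports <- list(im_filtered = list(), unfiltered = list())
  for (nm in names(exp2$runs)) {
    r <- exp2$runs[[nm]]
    first <- process_run(r$frames, r$spec, exp2$library, run_id = nm,
                         config = cfgs$im_filtered)
    second <- process_run(r$frames, r$spec, exp2$library, run_id = nm,
                          config = cfgs$unfiltered, index = first$index,
                          calib = first$calibration)
    reports$im_filtered[[nm]] <- first$report
    reports$unfiltered[[nm]] <- second$report
  }
  out <- list()
  for (v in names(reports)) {
    rep_v <- do.call(rbind, reports[[v]])
    rep_v <- rep_v[rep_v$Q.Value <= pconfig$precursor_q &
                     !is.na(rep_v$PG.Q.Value) &
                     rep_v$PG.Q.Value <= pconfig$protein_q, , drop = FALSE]
    if (!nrow(rep_v)) next
    dtq <- data.table::as.data.table(rep_v)
    wide <- data.table::dcast(dtq, Precursor.Id + Protein.Group ~ Run,
                              value.var = "Quantity", fun.aggregate = max,
                              fill = NA_real_)
    runs_a <- grep("^A", names(wide), value = TRUE)
    runs_b <- grep("^B", names(wide), value = TRUE)
    pm <- as.matrix(wide[, -(1:2)])
    groups <- wide$Protein.Group
    for (g in unique(groups)) {
      q <- maxlfq_protein(pm[groups == g, , drop = FALSE])
      names(q) <- colnames(pm)
      a <- median(q[runs_a], na.rm = TRUE)
      b <- median(q[runs_b], na.rm = TRUE)
      if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) next
      out[[length(out) + 1L]] <- data.frame(
        protein_group = g, species = sub("_.*$", "", g), variant = v,
        log2_ab = log2(a / b))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "truth_log2") <- log2(exp2$truth_ratio)
  res
}
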
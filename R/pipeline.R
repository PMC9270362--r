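#' Pipeline configuration
#'
#' Defaults follow common DIA practice: 10 ppm mass tolerance cap, precursor
#' q-value threshold 0.01, global protein q-value threshold 0.01. The two
#' ion mobility toggles support ablation runs: `im_scoring` drops the IM
#' consistency and IM deviation features from the classifier, and
#' `im_quant_filter` disables the IM gate during quantification.
#'
#' @param precursor_q,protein_q Acceptance thresholds in (0, 1].
#' @param mass_tol_cap_ppm Upper bound on the calibrated mass tolerance.
#' @param im_scoring,im_quant_filter Ablation toggles (default on).
#' @param classifier_seed Seed for the classifier ensemble.
#' @param calibration_n Precursors sampled for the calibration pass.
#' @param integration_width Quantification half-width, cycles.
#' @param normalize Apply median-ratio run normalization to the quantity
#'   matrices? Disable for experiments acquired (or simulated) at identical
#'   loading, where normalization can only drift on a regulated
#'   subpopulation.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(precursor_q = 0.01, protein_q = 0.01,
                            mass_tol_cap_ppm = 10, im_scoring = TRUE,
                            im_quant_filter = TRUE, classifier_seed = 42L,
                            calibration_n = 100L, integration_width = 2L,
                            normalize = TRUE) {
  stopifnot(precursor_q > 0, precursor_q <= 1, protein_q > 0, protein_q <= 1)
  x <- as.list(environment())
  class(x) <- "pipeline_config"
  x
}

#' Process one run against a library
#'
#' The single-run engine: 2D peak picking (with identical-frame summation),
#' a wide-tolerance calibration pass scored by cosine similarity, run
#' calibration, chromatogram extraction for targets and pseudo-reversed
#' decoys, candidate elution-peak detection (>= 2 co-eluting fragments),
#' IM-aware feature computation, seeded neural-network ensemble scoring with
#' target-decoy q-values, picked protein q-values, and IM-filtered
#' quantification.
#'
#' @param frames List of [im_frame()]s (one run).
#' @param spec The [frame_spec()].
#' @param library Target [spectral_library()] (decoys are generated
#'   internally).
#' @param run_id Run name written to the report.
#' @param config A [pipeline_config()].
#' @param n_cycles Number of cycles; default inferred.
#' @param index,calib Optional precomputed [build_index()] result and
#'   calibration (reused by paired ablation runs so picking and calibration
#'   are not repeated).
#' @return List with `report` (all scored target candidates, unfiltered),
#'   `features` (target/decoy matrices), `index`, `calibration` and `log`.
#' @export
process_run <- function(frames, spec, library, run_id = "run1",
                        config = pipeline_config(), n_cycles = NULL,
                        index = NULL, calib = NULL) {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  if (is.null(index) && length(frames) == 0L)
    stop("stage[pick]: no frames supplied")
  if (is.null(n_cycles)) {
    n_cycles <- if (!is.null(index)) index$n_cycles
    else max(vapply(frames, `[[`, integer(1), "cycle")) + 1L
  }
  ## --- stage: pick
  if (is.null(index)) {
    spectra <- withCallingHandlers(
      pick_run(frames, spec),
      error = function(e) stop("stage[pick]: ", conditionMessage(e),
                               call. = FALSE))
    index <- build_index(spectra, spec, n_cycles = n_cycles)
    say("pick: %d spectra indexed", length(spectra))
  }
  ## --- stage: calibrate (wide first pass, cosine-scored)
  targets <- library$precursors[!library$precursors$decoy, , drop = FALSE]
  if (is.null(calib)) {
    calib <- calibrate_run(index, library, spec, n_cycles, config, run_id)
    say("calibrate: %d confident ids, IM window %.4f, mass tol %.2f ppm%s",
        attr(calib, "n_ids"), calib$im_window,
        calib$mass_tol_ppm, if (calib$fallback) " [fallback]" else "")
  }
  ## --- stage: extract + score candidates for targets and decoys
  decoys <- generate_decoys(library)
  full <- combine_libraries(
    spectral_library(targets,
                     library$fragments[library$fragments$precursor_id %in%
                                         targets$precursor_id, ],
                     library$metadata),
    decoys)
  prec <- full$precursors
  rows <- vector("list", nrow(prec))
  feats <- vector("list", nrow(prec))
  chroms <- vector("list", nrow(prec))
  for (i in seq_len(nrow(prec))) {
    entry <- prec[i, ]
    ch <- extract_chromatograms(index, entry, calib, full)
    cand <- find_candidate_peaks(ch)
    if (!nrow(cand)) next
    ## best candidate per precursor by the fixed linear pre-score
    sc_list <- lapply(cand$apex_cycle, function(a)
      score_candidate(ch, a, entry, calib, full))
    fm <- do.call(rbind, lapply(sc_list, `[[`, "features"))
    pre <- if (nrow(fm) > 1L) fallback_scores(fm) else 0
    b <- which.max(pre + fm[, "cosine"])
    sc <- sc_list[[b]]
    fr <- sc$fragments[sc$fragments$detected, ]
    rows[[i]] <- data.frame(
      precursor_id = entry$precursor_id, decoy = entry$decoy,
      protein_group = entry$protein_group,
      apex_cycle = cand$apex_cycle[b],
      im = median(fr$apex_inv_k0),
      ppm = median(fr$ppm_err, na.rm = TRUE))
    feats[[i]] <- sc$features
    chroms[[i]] <- ch
  }
  scored <- !vapply(rows, is.null, logical(1))
  say("extract: %d/%d precursors with candidate peaks", sum(scored), nrow(prec))
  if (!any(scored & !prec$decoy)) {
    say("score: no target candidates; empty report")
    rep0 <- data.frame(Precursor.Id = character(), Run = character(),
                       Score = numeric(), Q.Value = numeric(),
                       Protein.Group = character(), PG.Q.Value = numeric(),
                       Quantity = numeric(), Apex.Cycle = integer(),
                       IM = numeric(), Mass.Error.PPM = numeric())
    return(list(report = rep0, features = NULL, index = index,
                calibration = calib, log = log))
  }
  cand_df <- do.call(rbind, rows[scored])
  F <- do.call(rbind, feats[scored])
  if (!config$im_scoring)
    F <- F[, setdiff(colnames(F), c("im_spread", "im_dev")), drop = FALSE]
  it <- !cand_df$decoy; id <- cand_df$decoy
  sc <- train_and_score(F[it, , drop = FALSE], F[id, , drop = FALSE],
                        seed = config$classifier_seed)
  say("score: %s scoring of %d targets / %d decoys", sc$method,
      sum(it), sum(id))
  q <- compute_qvalues(sc$target, if (length(sc$decoy)) sc$decoy else -Inf)
  ## protein level (picked competition over all scored precursors)
  allsc <- numeric(nrow(cand_df))
  allsc[it] <- sc$target; allsc[id] <- sc$decoy
  pq <- protein_qvalues(data.frame(protein_group = cand_df$protein_group,
                                   score = allsc, decoy = cand_df$decoy))
  pg_q <- pq$q_value[match(cand_df$protein_group[it], pq$protein_group)]
  ## quantification of targets
  tgt_idx <- which(scored)[it]
  quant <- vapply(seq_along(tgt_idx), function(jj) {
    i <- tgt_idx[jj]
    quantify_precursor(chroms[[i]], cand_df$apex_cycle[it][jj],
                       im_window = calib$im_window,
                       width = config$integration_width,
                       im_filter = config$im_quant_filter)
  }, numeric(1))
  tgt <- cand_df[it, ]
  seqs <- library$precursors$modified_sequence[
    match(tgt$precursor_id, library$precursors$precursor_id)]
  chg <- library$precursors$charge[
    match(tgt$precursor_id, library$precursors$precursor_id)]
  report <- data.frame(
    Precursor.Id = paste0(seqs, chg), Run = run_id, Score = sc$target,
    Q.Value = q, Protein.Group = tgt$protein_group,
    PG.Q.Value = pg_q, Quantity = quant, Apex.Cycle = tgt$apex_cycle,
    IM = tgt$im, Mass.Error.PPM = tgt$ppm)
  list(report = report, features = list(target = F[it, , drop = FALSE],
                                        decoy = F[id, , drop = FALSE]),
       index = index, calibration = calib, log = log)
}

#' Run the full pipeline on simulated or supplied runs
#'
#' Chains simulation (optional), peak picking, calibration, extraction,
#' scoring and quantification over a set of runs, then applies the precursor
#' and global protein q-value filters, median-ratio run normalization and
#' MaxLFQ protein roll-up.
#'
#' @param runs Named list of runs; each `list(frames =, spec =)` (a
#'   [simulate_run()] result works directly).
#' @param library Target [spectral_library()].
#' @param config A [pipeline_config()].
#' @return List with `report` (row-bound filtered per-run reports),
#'   `report_all` (unfiltered), `precursor_matrix`, `protein_matrix`
#'   (normalized quantities), `per_run` (full [process_run()] results) and
#'   `log`.
#' @export
run_pipeline <- function(runs, library, config = pipeline_config()) {
  stopifnot(length(runs) >= 1L)
  if (is.null(names(runs))) names(runs) <- paste0("run", seq_along(runs))
  per_run <- list()
  for (nm in names(runs)) {
    per_run[[nm]] <- process_run(runs[[nm]]$frames, runs[[nm]]$spec, library,
                                 run_id = nm, config = config)
  }
  report_all <- do.call(rbind, lapply(per_run, `[[`, "report"))
  rownames(report_all) <- NULL
  keep <- report_all$Q.Value <= config$precursor_q &
    (is.na(report_all$PG.Q.Value) |
       report_all$PG.Q.Value <= config$protein_q)
  ## global protein filter: a group must pass in at least one run
  report <- report_all[keep & !is.na(report_all$PG.Q.Value), , drop = FALSE]
  ## precursor x run quantity matrix
  pm <- NULL
  if (nrow(report)) {
    dtq <- data.table::as.data.table(report)
    wide <- data.table::dcast(dtq, Precursor.Id + Protein.Group ~ Run,
                              value.var = "Quantity", fun.aggregate = max,
                              fill = NA_real_)
    pm <- as.matrix(wide[, -(1:2)])
    rownames(pm) <- wide$Precursor.Id
    if (config$normalize && ncol(pm) > 1L)
      pm <- suppressWarnings(normalize_runs(pm))
    groups <- wide$Protein.Group
    prot <- lapply(unique(groups), function(g)
      maxlfq_protein(pm[groups == g, , drop = FALSE]))
    protm <- do.call(rbind, prot)
    rownames(protm) <- unique(groups)
    colnames(protm) <- colnames(pm)
  } else protm <- NULL
  list(report = report, report_all = report_all, precursor_matrix = pm,
       protein_matrix = protm, per_run = per_run,
       log = unlist(lapply(per_run, `[[`, "log")))
}
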
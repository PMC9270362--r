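#' Simulation configuration
#'
#' Study conditions for the synthetic dia-PASEF generator. Defaults emulate a
#' fast-gradient acquisition at desk scale: the [default_frame_spec()] window
#' scheme, 40 cycles, Gaussian elution profiles (sigma 2 cycles), Gaussian
#' ion mobility profiles (sigma 1.5 scans), log-normal precursor abundances,
#' Poisson counting noise on every point, uniform dark counts per frame,
#' interfering peptides planted at shifted ion mobility / retention time, and
#' an affine distortion between library and observed 1/K0.
#'
#' @param seed Base seed; a fixed seed gives byte-identical output.
#' @param n_precursors Planted precursors (library size).
#' @param spec A [frame_spec()] (window scheme, axes, frames per window).
#' @param n_cycles Cycles per run.
#' @param elution_sigma Chromatographic peak sigma, cycles.
#' @param im_sigma Ion mobility peak sigma, scans.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance parameters
#'   (total counts per precursor).
#' @param interference_density Expected interfering peptides per window.
#' @param interference_im_shift Range (Vs/cm2) of the absolute 1/K0 shift of
#'   interferers, straddling the typical extraction window so that some
#'   interference survives extraction and must be caught by the IM outlier
#'   machinery.
#' @param interference_rt_shift Range (cycles) of the absolute apex shift of
#'   interferers relative to the peptide they interfere with.
#' @param interference_intensity Range of the interferer abundance as a
#'   multiple of the median precursor abundance; interferer abundance is
#'   independent of the affected peptide (and of any spike design), as for
#'   a genuinely foreign co-fragmented peptide.
#' @param interference_fragments Range of the number of fragment m/z values
#'   an interferer shares with the affected peptide (a foreign peptide
#'   typically collides with only part of a fragment ladder).
#' @param mimic_im_shift When non-`NULL` (a range in Vs/cm2), library
#'   entries left unplanted by the spike design (`spike` multiplier 0)
#'   receive "doppelganger" signal: their full fragment ladder with
#'   perturbed intensity ratios, planted at the entry's own retention time
#'   but at a 1/K0 shifted by this amount — a peptide-spectrum-match decoy
#'   that only the ion mobility dimension can unmask.
#' @param dark_rate Expected dark-count points per frame.
#' @param dark_mean Mean dark-count intensity (counts).
#' @param ppm_jitter Per-point mass error sigma (ppm).
#' @param ppm_offset Systematic run mass offset (ppm).
#' @param im_slope,im_intercept Affine library -> observed 1/K0 distortion.
#' @param im_jitter Per-precursor 1/K0 scatter (Vs/cm2).
#' @param rt_jitter Per-precursor apex scatter (cycles).
#' @param poisson Poisson-sample point intensities? `FALSE` emits the exact
#'   expectations (useful for closed-form checks).
#' @param ms1 Also emit MS1 frames (window 0)?
#' @param noise_only Suppress all planted signal (null runs for FDR
#'   calibration)?
#' @param species_prefix Accession prefix(es) for protein groups; several
#'   prefixes split the library across species (two-species designs).
#' @param species_weights Library share per species prefix (defaults to an
#'   even split); a spiked minority species should be a minority of the
#'   library so that median-ratio normalization stays anchored on the
#'   constant background.
#' @param spike Named per-species abundance multipliers, e.g.
#'   `c(HUM = 1, YST = 3)`.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_precursors = 200L,
                              spec = default_frame_spec(), n_cycles = 40L,
                              elution_sigma = 2, im_sigma = 1.5,
                              abundance_meanlog = log(5000),
                              abundance_sdlog = 0.8,
                              interference_density = 2,
                              interference_im_shift = c(0.005, 0.06),
                              interference_rt_shift = c(0, 3),
                              interference_intensity = c(0.5, 4),
                              interference_fragments = c(1L, 3L),
                              mimic_im_shift = NULL,
                              dark_rate = 100, dark_mean = 30,
                              ppm_jitter = 3, ppm_offset = 2,
                              im_slope = 0.985, im_intercept = 0.015,
                              im_jitter = 0.004, rt_jitter = 0.5,
                              poisson = TRUE,
                              ms1 = TRUE, noise_only = FALSE,
                              species_prefix = "HUM", species_weights = NULL,
                              spike = NULL) {
  cfg <- as.list(environment())
  stopifnot(elution_sigma > 0, im_sigma > 0, interference_density >= 0,
            dark_rate >= 0, n_precursors >= 1L, n_cycles >= 5L)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a spectral library
#'
#' Random tryptic-like peptide sequences (7-14 residues plus a C-terminal K
#' or R) are assembled into precursors with charge chosen so the precursor
#' m/z falls inside the window scheme, y-ion fragment ladders with
#' randomized relative intensities, uniform reference retention indices in
#' \[0, 1\], and reference 1/K0 correlated with precursor m/z plus scatter
#' (mirroring TIMS behaviour). Protein groups hold two precursors each.
#'
#' @param config A [simulation_config()].
#' @return A target [spectral_library()].
#' @export
simulate_library <- function(config) {
  set.seed(config$seed)
  spec <- config$spec
  n <- config$n_precursors
  mz_lo <- min(spec$windows$mz_low); mz_hi <- max(spec$windows$mz_high)
  aa_pool <- setdiff(names(.AA_MONO), c("C"))  # keep mass bookkeeping simple
  prefixes <- config$species_prefix
  w <- config$species_weights
  if (is.null(w)) w <- rep(1, length(prefixes))
  ## deterministic blocked species assignment by library share
  n_per <- diff(round(cumsum(c(0, w / sum(w))) * n))
  species_of <- rep(prefixes, times = n_per)[seq_len(n)]
  prec <- vector("list", n); frag <- vector("list", n)
  i <- 0L; tries <- 0L
  seqs_seen <- character(0)
  while (i < n && tries < n * 60L) {
    tries <- tries + 1L
    len <- sample(7:14, 1)
    sq <- paste(c(sample(aa_pool, len - 1L, replace = TRUE),
                  sample(c("K", "R"), 1)), collapse = "")
    if (sq %in% seqs_seen) next
    mass <- peptide_mono_mass(sq)
    charge <- NA_integer_
    for (z in 2:3) {
      mz <- (mass + z * .MASS_PROTON) / z
      if (mz >= mz_lo + 2 && mz <= mz_hi - 2) { charge <- z; break }
    }
    if (is.na(charge)) next
    ## y-ion ladder restricted to the instrument mass axis
    ann <- paste0("y", 3:(len - 1L))
    fmz <- fragment_mz(sq, ann)
    ok <- fmz >= spec$mz_min + 5 & fmz <= spec$mz_max - 5
    if (sum(ok) < 4L) next
    keep <- which(ok)
    if (length(keep) > 8L) keep <- sort(sample(keep, 8L))
    rel <- runif(length(keep))^1.5
    rel <- rel / max(rel)
    i <- i + 1L
    seqs_seen <- c(seqs_seen, sq)
    mz <- (mass + charge * .MASS_PROTON) / charge
    sp <- species_of[i]
    prec[[i]] <- data.frame(
      precursor_id = i, modified_sequence = sq, charge = charge,
      precursor_mz = mz, ref_rt = runif(1),
      ref_inv_k0 = min(max(0.55 + 0.00085 * mz + rnorm(1, 0, 0.02), 0.75), 1.40),
      protein_group = sprintf("%s_P%04d", sp, (i - 1L) %/% 2L + 1L),
      proteotypic = TRUE, decoy = FALSE)
    frag[[i]] <- data.frame(precursor_id = i, mz = fmz[keep],
                            rel_intensity = rel, annotation = ann[keep])
  }
  if (i < n) stop("could not assemble the requested library size")
  spectral_library(do.call(rbind, prec), do.call(rbind, frag),
                   metadata = list(source = "simulate_library",
                                   seed = config$seed))
}

## ground-truth per-precursor run parameters (shared across replicate runs
## when passed back in via `template`)
simulate_truth <- function(library, config) {
  prec <- library$precursors[!library$precursors$decoy, , drop = FALSE]
  n <- nrow(prec)
  spec <- config$spec
  apex <- 2 + (config$n_cycles - 4) * prec$ref_rt +
    rnorm(n, 0, config$rt_jitter)
  im_true <- config$im_slope * prec$ref_inv_k0 + config$im_intercept +
    rnorm(n, 0, config$im_jitter)
  abundance <- rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  sp <- sub("_.*$", "", prec$protein_group)
  if (!is.null(config$spike)) {
    mult <- config$spike[sp]
    mult[is.na(mult)] <- 1
    abundance <- abundance * as.numeric(mult)
  }
  w <- spec$windows
  widx <- vapply(prec$precursor_mz, function(m) {
    h <- which(m >= w$mz_low & m <= w$mz_high)
    if (length(h)) w$window_id[h[1]] else NA_integer_
  }, integer(1))
  data.frame(precursor_id = prec$precursor_id, species = sp,
             window_id = widx, apex_cycle = apex, inv_k0 = im_true,
             abundance = abundance)
}

## expand one planted species (parent signal or interferer) into sparse
## frame points; returns a data.table(window_id, cycle, scan, bin, intensity)
plant_points <- function(mz, rel, window_id, apex, scan0, abundance, config) {
  spec <- config$spec
  n_ions <- length(mz)
  cyc_lo <- pmax(0, floor(apex - 4 * config$elution_sigma))
  cyc_hi <- pmin(config$n_cycles - 1, ceiling(apex + 4 * config$elution_sigma))
  nc <- cyc_hi - cyc_lo + 1L
  sc_lo <- pmax(0, floor(scan0 - 4 * config$im_sigma))
  sc_hi <- pmin(spec$n_scans - 1, ceiling(scan0 + 4 * config$im_sigma))
  ns <- sc_hi - sc_lo + 1L
  keep <- nc > 0 & ns > 0
  if (!any(keep)) return(NULL)
  reps <- (nc * ns)[keep]
  i <- rep(which(keep), reps)
  cyc <- unlist(lapply(which(keep), function(j)
    rep(cyc_lo[j]:cyc_hi[j], each = ns[j])))
  scn <- unlist(lapply(which(keep), function(j)
    rep(sc_lo[j]:sc_hi[j], times = nc[j])))
  gc_ <- dnorm(cyc, apex[i], config$elution_sigma)
  gs_ <- dnorm(scn, scan0[i], config$im_sigma)
  ## normalize per ion so the expected planted area equals abundance * rel
  gc_sum <- tapply(gc_ * gs_, i, sum)  # joint normalizer (separable grid)
  norm <- as.numeric(gc_sum[as.character(i)])
  mu <- abundance[i] * rel[i] * gc_ * gs_ / norm
  counts <- if (isTRUE(config$poisson)) rpois(length(mu), mu) else mu
  ok <- counts > 0
  if (!any(ok)) return(NULL)
  mzpt <- mz[i[ok]] * (1 + (config$ppm_offset +
                              rnorm(sum(ok), 0, config$ppm_jitter)) * 1e-6)
  bin <- round(mz_to_bin(spec, mzpt))
  good <- bin >= 0 & bin < spec$n_bins
  data.table::data.table(
    window_id = window_id[i[ok]][good], cycle = cyc[ok][good],
    scan = scn[ok][good], bin = as.integer(bin[good]),
    intensity = as.numeric(counts[ok][good]))
}

#' Simulate one dia-PASEF-like run
#'
#' Every planted precursor contributes, in its isolation window's frames,
#' points with expected intensity `abundance x fragment-relative-intensity x
#' Gaussian(cycle) x Gaussian(scan)`, Poisson-sampled, with per-point ppm
#' mass jitter, plus MS1 precursor signal (window 0), interfering peptides
#' at shifted 1/K0 and retention time, and uniform dark counts. With
#' `frames_per_window > 1` the additional repeat frames are Poisson
#' re-draws of the first frame's counts (summing repeats recovers the
#' duty-cycle gain).
#'
#' @param library A target [spectral_library()].
#' @param config A [simulation_config()].
#' @param seed Run seed (default `config$seed`); replicate runs differ only
#'   through this.
#' @param template Optional truth table from a previous call, reused so that
#'   replicate runs share apexes, mobilities and abundances.
#' @return List with `frames` (list of [im_frame()]), `truth` (per-precursor
#'   data.frame: `precursor_id`, `species`, `window_id`, `apex_cycle`,
#'   `inv_k0`, `abundance`), and `spec`.
#' @export
simulate_run <- function(library, config, seed = config$seed,
                         template = NULL) {
  set.seed(seed)
  spec <- config$spec
  truth <- if (is.null(template)) simulate_truth(library, config) else template
  frag <- library$fragments
  prec <- library$precursors
  pieces <- list()
  if (!config$noise_only) {
    planted <- truth[!is.na(truth$window_id), ]
    f <- frag[frag$precursor_id %in% planted$precursor_id, ]
    j <- match(f$precursor_id, planted$precursor_id)
    scan0 <- im_to_scan(spec, planted$inv_k0)
    pieces$signal <- plant_points(
      mz = f$mz, rel = f$rel_intensity, window_id = planted$window_id[j],
      apex = planted$apex_cycle[j], scan0 = scan0[j],
      abundance = planted$abundance[j], config = config)
    if (config$ms1) {
      k <- match(planted$precursor_id, prec$precursor_id)
      pieces$ms1 <- plant_points(
        mz = prec$precursor_mz[k], rel = rep(1, nrow(planted)),
        window_id = rep(0L, nrow(planted)), apex = planted$apex_cycle,
        scan0 = scan0, abundance = planted$abundance * 2, config = config)
    }
    ## doppelgangers: unplanted entries get RT-consistent, IM-shifted signal
    if (!is.null(config$mimic_im_shift)) {
      unpl <- truth[!is.na(truth$window_id) & truth$abundance == 0, ,
                    drop = FALSE]
      if (nrow(unpl)) {
        fm <- frag[frag$precursor_id %in% unpl$precursor_id, ]
        jm <- match(fm$precursor_id, unpl$precursor_id)
        shift <- sample(c(-1, 1), nrow(unpl), TRUE) *
          runif(nrow(unpl), config$mimic_im_shift[1],
                config$mimic_im_shift[2])
        mim_ab <- rlnorm(nrow(unpl), config$abundance_meanlog,
                         config$abundance_sdlog)
        pieces$mimic <- plant_points(
          mz = fm$mz, rel = fm$rel_intensity * runif(nrow(fm), 0.4, 2.5),
          window_id = unpl$window_id[jm], apex = unpl$apex_cycle[jm],
          scan0 = im_to_scan(spec, unpl$inv_k0 + shift)[jm],
          abundance = mim_ab[jm], config = config)
      }
    }
    ## interferers: library-like ghosts at shifted IM / RT
    n_int <- rpois(nrow(spec$windows), config$interference_density)
    ints <- list()
    for (wi in seq_len(nrow(spec$windows))) {
      if (n_int[wi] == 0L) next
      inw <- planted[planted$window_id == spec$windows$window_id[wi], ]
      if (!nrow(inw)) next
      for (e in seq_len(n_int[wi])) {
        p <- inw[sample(nrow(inw), 1), ]
        shift <- sample(c(-1, 1), 1) *
          runif(1, config$interference_im_shift[1],
                config$interference_im_shift[2])
        fi <- frag[frag$precursor_id == p$precursor_id, ]
        ## a foreign peptide collides with only part of the ladder
        n_sh <- min(nrow(fi), sample(config$interference_fragments[1]:
                                       config$interference_fragments[2], 1))
        fi <- fi[sample(nrow(fi), n_sh), , drop = FALSE]
        rt_shift <- sample(c(-1, 1), 1) *
          runif(1, config$interference_rt_shift[1],
                config$interference_rt_shift[2])
        ## abundance independent of the affected peptide and of any spike
        ab <- exp(config$abundance_meanlog) *
          runif(1, config$interference_intensity[1],
                config$interference_intensity[2])
        ints[[length(ints) + 1L]] <- plant_points(
          mz = fi$mz, rel = rep(1, nrow(fi)),
          window_id = rep(p$window_id, nrow(fi)),
          apex = rep(p$apex_cycle + rt_shift, nrow(fi)),
          scan0 = rep(im_to_scan(spec, p$inv_k0 + shift), nrow(fi)),
          abundance = rep(ab, nrow(fi)),
          config = config)
      }
    }
    pieces$interference <- data.table::rbindlist(ints)
  }
  ## dark counts
  wids <- c(if (config$ms1) 0L, spec$windows$window_id)
  n_frames <- length(wids) * config$n_cycles
  ndark <- rpois(n_frames, config$dark_rate)
  tot <- sum(ndark)
  if (tot > 0L) {
    fidx <- rep(seq_len(n_frames), ndark)
    pieces$dark <- data.table::data.table(
      window_id = rep(wids, times = config$n_cycles)[fidx],
      cycle = rep(0:(config$n_cycles - 1L), each = length(wids))[fidx],
      scan = sample(0:(spec$n_scans - 1L), tot, replace = TRUE),
      bin = sample(0:(spec$n_bins - 1L), tot, replace = TRUE),
      intensity = as.numeric(rpois(tot, config$dark_mean) + 1L))
  }
  pts <- data.table::rbindlist(pieces[!vapply(pieces, is.null, logical(1))])
  frames <- list()
  for (rep_i in seq_len(spec$frames_per_window)) {
    p <- if (rep_i == 1L) pts else {
      ## independent Poisson re-draw of the same expectation for repeats
      p2 <- data.table::copy(pts)
      p2[, intensity := as.numeric(rpois(.N, intensity))]
      p2[intensity > 0]
    }
    if (is.null(p) || nrow(p) == 0L) next
    sp <- split(p, by = c("window_id", "cycle"))
    frames <- c(frames, lapply(sp, function(d)
      im_frame(d$window_id[1], d$cycle[1],
               d[, .(scan, bin, intensity)], spec = spec)))
  }
  ## make sure every (window, cycle) exists even if empty
  have <- vapply(frames, function(f) paste(f$window_id, f$cycle), character(1))
  for (w in wids) for (cy in 0:(config$n_cycles - 1L)) {
    if (!paste(w, cy) %in% have)
      frames[[length(frames) + 1L]] <- im_frame(
        w, cy, data.frame(scan = integer(), bin = integer(),
                          intensity = numeric()))
  }
  list(frames = frames, truth = truth, spec = spec)
}

#' Simulate a two-species spike-in experiment
#'
#' Two species share one library; species 2 (e.g. yeast) is spiked at a
#' high:low abundance pair between conditions A and B (default 45:15, a
#' true 3:1 ratio) on a constant species-1 (e.g. human) background.
#' Triplicate runs per condition differ only by seed-derived counting noise;
#' apexes, mobilities and base abundances are shared.
#'
#' @param config A [simulation_config()] with two `species_prefix` entries.
#' @param spike_amounts Numeric pair, condition A and B spike levels of
#'   species 2 (default `c(45, 15)`).
#' @param n_replicates Replicates per condition (default 3).
#' @return List with `library`, `runs` (named list of [simulate_run()]
#'   results; names `A1..Bn`), `design` (`data.frame`: run, condition) and
#'   `truth_ratio` (the exact species-2 A:B abundance ratio).
#' @export
simulate_two_species_experiment <- function(config,
                                            spike_amounts = c(45, 15),
                                            n_replicates = 3L) {
  stopifnot(length(config$species_prefix) == 2L)
  lib <- simulate_library(config)
  sp2 <- config$species_prefix[2]
  set.seed(config$seed + 1L)
  base_truth <- simulate_truth(lib, config)
  runs <- list()
  design <- NULL
  for (ci in 1:2) {
    cond <- c("A", "B")[ci]
    truth_c <- base_truth
    truth_c$abundance <- ifelse(truth_c$species == sp2,
                                truth_c$abundance * spike_amounts[ci] /
                                  spike_amounts[1],
                                truth_c$abundance)
    for (r in seq_len(n_replicates)) {
      nm <- paste0(cond, r)
      runs[[nm]] <- simulate_run(lib, config,
                                 seed = config$seed + 100L * ci + r,
                                 template = truth_c)
      design <- rbind(design, data.frame(run = nm, condition = cond))
    }
  }
  list(library = lib, runs = runs, design = design,
       truth_ratio = spike_amounts[1] / spike_amounts[2])
}
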
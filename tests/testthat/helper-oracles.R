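# Independent brute-force oracles and small fixture factories. The oracles
# deliberately re-implement the definitions literally (full-grid enumeration,
# linear scans) and never call the package's optimized code paths.

tiny_spec <- function(n_scans = 20L, n_bins = 30L, im_begin = 0.7,
                      im_end = 0.9, mz_min = 400, mz_max = 450,
                      frames_per_window = 1L) {
  frame_spec(n_scans, im_begin, im_end, n_bins, mz_min, mz_max,
             windows = data.frame(mz_low = mz_min, mz_high = mz_max,
                                  scan_low = 0L, scan_high = n_scans,
                                  window_id = 1L),
             frames_per_window = frames_per_window)
}

random_frame <- function(spec, n_points, max_intensity = 20L) {
  pts <- data.frame(
    scan = sample(0:(spec$n_scans - 1L), n_points, replace = TRUE),
    bin = sample(0:(spec$n_bins - 1L), n_points, replace = TRUE),
    intensity = sample(c(seq_len(max_intensity), rep(5L, 5L)), n_points,
                       replace = TRUE))
  im_frame(1L, 0L, pts, spec)
}

# exhaustive two-step peak picking over the full (scan, bin) grid
oracle_pick <- function(frame, spec, tol) {
  p <- frame$points
  grid <- expand.grid(scan = 0:(spec$n_scans - 1L), bin = 0:(spec$n_bins - 1L))
  ws <- function(cs, cb) {
    if (nrow(p) == 0L) return(0)
    ds <- abs(p$scan - cs); db <- abs(p$bin - cb)
    sum(p$intensity[db <= tol$mz_tol_bins & ds <= tol$im_tol_scans &
                      (ds + 2 * db * tol$im_scale) < tol$im_tol_scans])
  }
  S <- mapply(ws, grid$scan, grid$bin)
  in_mask <- function(ds, db) {
    abs(db) <= tol$mz_tol_bins & abs(ds) <= tol$im_tol_scans &
      (abs(ds) + 2 * abs(db) * tol$im_scale) < tol$im_tol_scans
  }
  raw_at <- function(cs, cb) {
    hit <- p$scan == cs & p$bin == cb
    if (any(hit)) sum(p$intensity[hit]) else 0
  }
  C <- mapply(raw_at, grid$scan, grid$bin)
  beats <- function(i, j) {
    if (S[i] != S[j]) return(S[i] > S[j])
    if (C[i] != C[j]) return(C[i] > C[j])
    if (grid$bin[i] != grid$bin[j]) return(grid$bin[i] < grid$bin[j])
    grid$scan[i] < grid$scan[j]
  }
  ## enumerate every neighbor position inside the scanning window
  smax <- ceiling(tol$im_tol_scans)
  offs <- expand.grid(ds = -smax:smax, db = -tol$mz_tol_bins:tol$mz_tol_bins)
  offs <- offs[in_mask(offs$ds, offs$db) & !(offs$ds == 0 & offs$db == 0), ]
  at <- function(s, b) {
    if (s < 0 || s >= spec$n_scans || b < 0 || b >= spec$n_bins) return(NA)
    s + b * spec$n_scans + 1L
  }
  cand <- c()
  for (i in which(S > 0)) {
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      j <- at(grid$scan[i] + offs$ds[k], grid$bin[i] + offs$db[k])
      if (is.na(j)) next
      if (!beats(i, j)) { ok <- FALSE; break }
    }
    if (ok) cand <- c(cand, i)
  }
  if (!length(cand))
    return(data.frame(scan = integer(), bin = integer(), intensity = numeric()))
  keep <- sapply(cand, function(i) {
    !any(sapply(cand, function(j) {
      j != i && S[j] > S[i] && abs(grid$bin[j] - grid$bin[i]) <= 1L &&
        in_mask(grid$scan[j] - grid$scan[i], grid$bin[j] - grid$bin[i])
    }))
  })
  res <- data.frame(scan = grid$scan[cand][keep], bin = grid$bin[cand][keep],
                    intensity = S[cand][keep])
  res <- res[order(res$bin, res$scan), ]
  rownames(res) <- NULL
  res
}

expect_picks_equal <- function(got_peaks, spec, oracle_res) {
  exp_mz <- bin_to_mz(spec, oracle_res$bin)
  exp_im <- scan_to_im(spec, oracle_res$scan)
  o <- order(exp_mz, exp_im)
  expect_equal(nrow(got_peaks), nrow(oracle_res))
  if (nrow(oracle_res)) {
    expect_equal(got_peaks$mz, exp_mz[o], tolerance = 1e-12)
    expect_equal(got_peaks$inv_k0, exp_im[o], tolerance = 1e-12)
    expect_equal(got_peaks$intensity, oracle_res$intensity[o],
                 tolerance = 1e-12)
  }
}

# linear-scan extraction oracle
oracle_extract <- function(spectrum, query_mz, mass_tol_ppm, predicted_im,
                           im_window) {
  hits <- which(abs(spectrum$mz - query_mz) / query_mz * 1e6 <= mass_tol_ppm &
                  abs(spectrum$inv_k0 - predicted_im) <= im_window)
  if (!length(hits)) return(NULL)
  best <- hits[order(-spectrum$intensity[hits],
                     abs(spectrum$mz[hits] - query_mz),
                     spectrum$mz[hits])][1]
  list(mz = spectrum$mz[best], inv_k0 = spectrum$inv_k0[best],
       intensity = spectrum$intensity[best])
}

# exhaustive substring digestion oracle: all substrings whose internal
# boundaries are cleavage sites, flanks are termini or cleavage sites, and
# missed cleavages <= k
oracle_digest <- function(sequence, k) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  is_site <- function(pos) pos >= 1 && pos < n && ch[pos] %in% c("K", "R")
  peps <- character(0)
  for (a in 1:n) for (b in a:n) {
    if (!(a == 1 || is_site(a - 1))) next
    if (!(b == n || is_site(b))) next
    internal <- sum(vapply(a:(b - 1), function(p) b > a && is_site(p),
                           logical(1)))
    if (b == a) internal <- 0
    if (internal <= k) peps <- c(peps, paste(ch[a:b], collapse = ""))
  }
  sort(unique(peps))
}

# brute-force picked-pair protein TDC oracle
oracle_protein_q <- function(df) {
  agg <- aggregate(score ~ protein_group + decoy, df, max)
  base <- ifelse(agg$decoy, sub("^DECOY_", "", agg$protein_group),
                 agg$protein_group)
  picked <- rep(TRUE, nrow(agg))
  for (b in unique(base)) {
    i <- which(base == b)
    if (length(i) == 2L) {
      it <- i[!agg$decoy[i]]; id <- i[agg$decoy[i]]
      if (agg$score[id] > agg$score[it]) picked[it] <- FALSE
      else picked[id] <- FALSE
    }
  }
  tk <- agg[picked & !agg$decoy, ]
  dk <- agg[picked & agg$decoy, ]
  ## q(s) = min FDP over thresholds at or below s (larger acceptance sets);
  ## the lowest threshold counts every kept decoy
  q <- vapply(tk$score, function(s) {
    best <- Inf
    for (t in sort(unique(tk$score))) {
      if (t > s) next
      ndec <- if (t == min(tk$score)) nrow(dk) else sum(dk$score >= t)
      best <- min(best, min(ndec / sum(tk$score >= t), 1))
    }
    max(best, 0)
  }, numeric(1))
  data.frame(protein_group = tk$protein_group, q_value = q)
}

write_tmp_fasta <- function(entries) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(entries), function(nm)
    c(paste0(">", nm), entries[[nm]]))), path)
  path
}

# small deterministic spectral library for IO round trips
toy_library <- function() {
  prec <- data.frame(
    precursor_id = 1:2,
    modified_sequence = c("PEPTIDEK", "SAMPLERK"),
    charge = c(2L, 2L),
    precursor_mz = precursor_mz_of_test(c("PEPTIDEK", "SAMPLERK"), 2L),
    ref_rt = c(0.25, 0.75), ref_inv_k0 = c(0.95, 1.1),
    protein_group = c("HUM_P0001", "HUM_P0002"),
    proteotypic = TRUE, decoy = FALSE)
  frag <- data.frame(
    precursor_id = c(1L, 1L, 2L, 2L, 2L),
    mz = c(500.25, 600.33, 480.2, 550.4, 700.5),
    rel_intensity = c(1, 0.5, 0.2, 1, 0.8),
    annotation = c("y4", "y5", "y4", "y5", "y6"))
  spectral_library(prec, frag, metadata = list(source = "toy"))
}

precursor_mz_of_test <- function(seqs, z) {
  (peptide_mono_mass(seqs) + z * 1.00727646688) / z
}

# independent y-ion ladder: y_k = mass of the k C-terminal residues + water
# + proton, derived from whole-peptide masses
fragment_mz_oracle <- function(sq) {
  n <- nchar(sq)
  vapply(1:(n - 1), function(k) {
    suffix <- substr(sq, n - k + 1, n)
    prefix <- substr(sq, 1, n - k)
    ## waters cancel in the subtraction; the y ion keeps one water
    (peptide_mono_mass(sq) - peptide_mono_mass(prefix)) + 18.0105646863 +
      1.00727646688
  }, numeric(1))
}
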
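test_that("pseudo-reversed decoys preserve counts, termini and precursor mass", {
  lib <- toy_library()
  dec <- generate_decoys(lib)
  expect_equal(nrow(dec$precursors), nrow(lib$precursors))
  expect_true(all(dec$precursors$decoy))
  ## "PEPTIDEK" -> reverse of "PEPTIDE" + "K"
  expect_equal(dec$precursors$modified_sequence[1], "EDITPEPK")
  expect_equal(dec$precursors$precursor_mz, lib$precursors$precursor_mz)
  expect_true(all(startsWith(dec$precursors$protein_group, "DECOY_")))
  ## fragment m/z differ from the target's for at least one fragment
  for (i in 1:2) {
    tmz <- lib$fragments$mz[lib$fragments$precursor_id == i]
    dmz <- dec$fragments$mz[dec$fragments$precursor_id ==
                              dec$precursors$precursor_id[i]]
    expect_true(any(abs(tmz - dmz) > 1e-6))
  }
})

test_that("palindromic peptides get a mutated decoy, never a target collision", {
  prec <- data.frame(precursor_id = 1L, modified_sequence = "AGAGAGAK",
                     charge = 2L, precursor_mz = 400.2, ref_rt = 0.5,
                     ref_inv_k0 = 1, protein_group = "HUM_P1",
                     proteotypic = TRUE, decoy = FALSE)
  frag <- data.frame(precursor_id = 1L, mz = c(430.1, 520.2),
                     rel_intensity = c(1, 0.4), annotation = c("y4", "y5"))
  lib <- spectral_library(prec, frag)
  dec <- generate_decoys(lib)
  expect_false(dec$precursors$modified_sequence %in%
                 lib$precursors$modified_sequence)
})

test_that("candidate peaks require two co-eluting fragments", {
  mk_chrom <- function(intensity, im = NULL) {
    nc <- ncol(intensity)
    if (is.null(im)) im <- ifelse(is.na(intensity), NA, 1.0)
    structure(list(
      precursor_id = 1L, window_id = 1L, cycles = 0:(nc - 1),
      ions = data.frame(mz = seq(500, by = 10,
                                 length.out = nrow(intensity)),
                        is_precursor = FALSE,
                        annotation = paste0("y", seq_len(nrow(intensity)))),
      intensity = intensity, inv_k0 = im, obs_mz = intensity * 0 + 500),
      class = "chromatogram_set")
  }
  g <- function(apex, nc = 15, h = 100) h * dnorm(0:(nc - 1), apex, 1.2)
  ## two co-eluting fragments: exactly one candidate at the apex
  x <- rbind(g(7), g(7) * 0.6)
  x[x < 1] <- NA
  cand <- find_candidate_peaks(mk_chrom(x))
  expect_equal(nrow(cand), 1L)
  expect_lte(abs(cand$apex_cycle - 7), 1)
  expect_equal(cand$n_fragments_detected, 2L)
  ## a single-fragment peak yields no candidate
  x1 <- rbind(g(7), g(7) * NA)
  cand1 <- find_candidate_peaks(mk_chrom(x1))
  expect_equal(nrow(cand1), 0L)
  ## two separated peaks yield two candidates
  x2 <- rbind(g(4, nc = 24) + g(17, nc = 24),
              0.5 * (g(4, nc = 24) + g(17, nc = 24)))
  x2[x2 < 1] <- NA
  cand2 <- find_candidate_peaks(mk_chrom(x2))
  expect_equal(nrow(cand2), 2L)
  expect_setequal(round(cand2$apex_cycle), c(4, 17))
  ## empty input
  expect_equal(nrow(find_candidate_peaks(mk_chrom(matrix(NA_real_, 2, 15)))),
               0L)
})

test_that("IM consistency features separate clean matches from interference", {
  cfg <- simulation_config(seed = 31, n_precursors = 30, n_cycles = 24,
                           interference_density = 0, dark_rate = 20)
  lib <- simulate_library(cfg)
  run <- simulate_run(lib, cfg)
  idx <- build_index(pick_run(run$frames, run$spec), run$spec,
                     n_cycles = cfg$n_cycles)
  cal <- wide_calibration(cfg$n_cycles)
  entry <- lib$precursors[3, ]
  ch <- extract_chromatograms(idx, entry, cal, lib,
                              cycles = 0:(cfg$n_cycles - 1L))
  cand <- find_candidate_peaks(ch)
  expect_gte(nrow(cand), 1L)
  a <- cand$apex_cycle[which.max(cand$total_intensity)]
  sc <- score_candidate(ch, a, entry, cal, lib)
  expect_true(all(is.finite(sc$features)))
  expect_gte(sc$features[["cosine"]], 0.5)
  expect_lt(sc$features[["im_spread"]], 0.02)
  ## all fragment mobilities identical -> zero spread and zero deviation
  ch2 <- ch
  ch2$inv_k0[] <- entry$ref_inv_k0
  cal2 <- cal
  sc2 <- score_candidate(ch2, a, entry, cal2, lib)
  expect_equal(sc2$features[["im_spread"]], 0)
  expect_equal(sc2$features[["im_dev"]], 0)
  ## one fragment hijacked to a shifted mobility gets the outlier weight
  ch3 <- ch
  fr <- which(!ch3$ions$is_precursor)
  ch3$inv_k0[fr[1], ] <- ch3$inv_k0[fr[1], ] + 0.05
  sc3 <- score_candidate(ch3, a, entry, cal, lib)
  expect_true(sc3$fragments$im_outlier[1])
  expect_equal(sc3$fragments$weight[1], 0.25)
  expect_true(all(sc3$fragments$weight[-1][sc3$fragments$detected[-1]] == 1))
})

test_that("ensemble scoring is deterministic, separable and null-calibrated", {
  set.seed(701)
  mkX <- function(n, shift) {
    X <- cbind(cosine = rnorm(n, 0.5 + shift * 0.3, 0.1),
               mean_corr = rnorm(n, 0.3 + shift * 0.4, 0.15),
               im_spread = rnorm(n, 0.02 - shift * 0.01, 0.004),
               im_dev = abs(rnorm(n, 0.03 - shift * 0.02, 0.01)),
               rt_dev = abs(rnorm(n, 3 - shift * 2, 1)),
               mean_ppm = abs(rnorm(n, 4 - shift, 1)),
               frac_detected = pmin(1, rnorm(n, 0.5 + shift * 0.4, 0.1)),
               log_intensity = rnorm(n, 5 + shift * 2, 1))
    X
  }
  Xt <- mkX(150, 1); Xd <- mkX(150, 0)
  s1 <- train_and_score(Xt, Xd, seed = 5)
  s2 <- train_and_score(Xt, Xd, seed = 5)
  expect_identical(s1, s2)               # determinism under a fixed seed
  expect_equal(s1$method, "ensemble")
  expect_gt(auroc(s1$target, s1$decoy), 0.95)  # separable case
  ## label shuffling destroys the signal: held-out AUROC near 0.5
  set.seed(702)
  all_X <- rbind(Xt, Xd)
  perm <- sample(nrow(all_X))
  sh <- train_and_score(all_X[perm[1:150], ], all_X[perm[151:300], ],
                        seed = 6)
  expect_lt(abs(auroc(sh$target, sh$decoy) - 0.5), 0.08)
  ## small samples fall back to the fixed linear score
  s3 <- train_and_score(Xt[1:10, ], Xd[1:10, ], seed = 5)
  expect_equal(s3$method, "linear")
  ## degenerate features warn and fall back
  Z <- matrix(1, 60, 8,
              dimnames = list(NULL, colnames(Xt)))
  expect_warning(s4 <- train_and_score(Z, Z, seed = 1), "degenerate")
  expect_equal(s4$method, "linear")
})

test_that("q-values follow the worked example and the score-threshold property", {
  q <- compute_qvalues(c(5, 4, 3, 2, 1), c(4.5, 0.5))
  expect_equal(q, c(0, 0.25, 0.25, 0.25, 0.4))
  ## no decoy above the best target
  expect_equal(compute_qvalues(c(10, 1), c(5, 6))[1], 0)
  ## all decoys above all targets: everything clipped to 1
  expect_equal(compute_qvalues(c(1, 2), c(3, 4)), c(1, 1))
  ## monotone non-increasing in score; q <= alpha selects a threshold set
  set.seed(801)
  for (rep_i in 1:20) {
    t <- rnorm(50); d <- rnorm(50)
    q <- compute_qvalues(t, d)
    o <- order(t, decreasing = TRUE)
    expect_true(all(diff(q[o]) >= -1e-12))
    for (alpha in c(0.01, 0.05, 0.2)) {
      sel <- q <= alpha
      if (any(sel)) expect_true(all(t[sel] >= max(t[!sel][q[!sel] > alpha],
                                                  -Inf)))
    }
  }
})

test_that("picked protein FDR matches the brute-force oracle", {
  ## single target protein whose decoy scores lower: q = 0
  df <- data.frame(protein_group = c("P1", "P1", "DECOY_P1"),
                   score = c(3, 5, 2), decoy = c(FALSE, FALSE, TRUE))
  pq <- protein_qvalues(df)
  expect_equal(pq$q_value[pq$protein_group == "P1"], 0)
  expect_false(pq$picked[pq$protein_group == "DECOY_P1"])
  ## paired decoy outscoring the target eliminates it
  df2 <- data.frame(protein_group = c("P1", "DECOY_P1"), score = c(2, 5),
                    decoy = c(FALSE, TRUE))
  pq2 <- protein_qvalues(df2)
  expect_false(pq2$picked[pq2$protein_group == "P1"])
  expect_true(is.na(pq2$q_value[pq2$protein_group == "P1"]))
  ## randomized 100-protein instances match the enumeration oracle
  set.seed(901)
  for (rep_i in 1:10) {
    n <- 100
    df3 <- data.frame(
      protein_group = c(paste0("P", 1:n), paste0("DECOY_P", 1:n)),
      score = c(rnorm(n, 1), rnorm(n, 0)),
      decoy = rep(c(FALSE, TRUE), each = n))
    ## a few extra precursor rows per protein
    extra <- df3[sample(nrow(df3), 50), ]
    extra$score <- extra$score - runif(50, 0, 2)
    pq3 <- protein_qvalues(rbind(df3, extra))
    orc <- oracle_protein_q(rbind(df3, extra))
    got <- pq3[!pq3$decoy & pq3$picked, c("protein_group", "q_value")]
    m <- merge(got, orc, by = "protein_group")
    expect_equal(nrow(m), nrow(orc))
    expect_equal(m$q_value.x, m$q_value.y, tolerance = 1e-12)
  }
})
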
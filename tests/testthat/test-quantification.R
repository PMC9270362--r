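test_that("MaxLFQ solves consistent ratio systems exactly", {
  ## 2 runs, 2 peptides, both with run1/run2 = 2: protein ratio exactly 2
  m <- rbind(c(20, 10), c(6, 3))
  q <- maxlfq_protein(m)
  expect_equal(q[1] / q[2], 2, tolerance = 1e-12)
  ## totals are preserved
  expect_equal(sum(q), sum(m), tolerance = 1e-9)
  ## noise-free multiplicative model a_p * b_r: b recovered up to scale
  set.seed(1001)
  a <- runif(6, 1, 10); b <- runif(5, 0.5, 4)
  m2 <- outer(a, b)
  q2 <- maxlfq_protein(m2)
  expect_equal(as.numeric(q2 / q2[1]), b / b[1], tolerance = 1e-9)
  ## single-peptide groups pass through
  m3 <- matrix(c(5, 7, NA), nrow = 1)
  expect_equal(as.numeric(maxlfq_protein(m3)), c(5, 7, NA))
})

test_that("MaxLFQ matches brute-force least squares with missing values", {
  set.seed(1002)
  for (rep_i in 1:10) {
    np <- sample(2:6, 1); nr <- sample(3:5, 1)
    m <- outer(runif(np, 1, 20), runif(nr, 0.5, 5)) *
      exp(matrix(rnorm(np * nr, 0, 0.3), np, nr))
    m[sample(np * nr, floor(np * nr * 0.2))] <- NA
    if (any(colSums(!is.na(m)) == 0)) next
    q <- maxlfq_protein(m)
    ## brute force: least squares over all pairwise median log-ratios
    l <- log2(m)
    eqs <- list()
    for (r in 1:(nr - 1)) for (s in (r + 1):nr) {
      sh <- which(!is.na(l[, r]) & !is.na(l[, s]))
      if (length(sh)) eqs[[length(eqs) + 1]] <-
          c(r, s, median(l[sh, r] - l[sh, s]))
    }
    if (!length(eqs)) next
    runs_in <- sort(unique(unlist(lapply(eqs, function(e) e[1:2]))))
    if (length(runs_in) < nr) next  # disconnected graphs tested separately
    A <- do.call(rbind, lapply(eqs, function(e) {
      v <- numeric(nr); v[e[1]] <- 1; v[e[2]] <- -1; v
    }))
    b <- vapply(eqs, `[`, numeric(1), 3)
    x <- qr.solve(crossprod(A) + 1 / nr, crossprod(A, b))  # gauge: sum x = 0
    qb <- 2^as.numeric(x)
    qb <- qb * sum(m, na.rm = TRUE) / sum(qb)
    expect_equal(as.numeric(q), qb, tolerance = 1e-9)
  }
})

test_that("disconnected run pairs are solved per component and flagged", {
  m <- rbind(c(4, 8, NA, NA),
             c(2, 4, NA, NA),
             c(NA, NA, 10, 5))
  q <- maxlfq_protein(m)
  expect_true(attr(q, "disconnected"))
  expect_equal(q[1] / q[2], 0.5, tolerance = 1e-9)
  expect_equal(q[3] / q[4], 2, tolerance = 1e-9)
})

test_that("median-ratio normalization undoes per-run scaling", {
  set.seed(1003)
  prof <- rlnorm(50, 5, 1)
  base <- matrix(prof, 50, 4)
  scaled <- sweep(base, 2, c(1, 2, 0.5, 1.7), "*")
  norm <- normalize_runs(scaled)
  ## all runs agree again
  expect_equal(norm[, 2], norm[, 1], tolerance = 1e-12)
  expect_equal(norm[, 3], norm[, 1], tolerance = 1e-12)
  ## per-run median log-ratios to the reference profile are zero
  ref <- apply(norm, 1, median)
  for (r in 1:4)
    expect_equal(median(log(norm[, r] / ref)), 0, tolerance = 1e-12)
  ## identical runs are unchanged
  same <- cbind(base[, 1], base[, 1])
  expect_equal(normalize_runs(same)[, 1], base[, 1], tolerance = 1e-12)
  ## an empty run warns and is left unscaled
  withna <- cbind(base[, 1], NA_real_)
  expect_warning(n2 <- normalize_runs(withna), "unscaled")
  expect_equal(attr(n2, "size_factors")[2], 1)
})

test_that("CV arithmetic and the completeness rule", {
  m <- rbind(c(90, 100, 110), c(50, 50, 50), c(10, NA, 30))
  rownames(m) <- c("a", "b", "c")
  cv <- cv_report(m, groups = rep("g1", 3))
  expect_equal(cv$per_feature$cv[1], 0.1)       # sd/mean of (90,100,110)
  expect_equal(cv$per_feature$cv[2], 0)         # identical replicates
  ## incomplete feature excluded from the median summary
  expect_equal(unname(cv$median_cv["g1"]), 0.05)
})

test_that("IM-gated quantification recovers planted areas and flags outliers", {
  ## narrow elution and mobility peaks so the apex +- 2 integration window
  ## and the scanning window each hold nearly all of the planted area
  cfg <- simulation_config(seed = 41, n_precursors = 25, n_cycles = 24,
                           elution_sigma = 0.8, im_sigma = 0.6,
                           interference_density = 0,
                           dark_rate = 10, abundance_meanlog = log(30000))
  lib <- simulate_library(cfg)
  run <- simulate_run(lib, cfg)
  idx <- build_index(pick_run(run$frames, run$spec), run$spec,
                     n_cycles = cfg$n_cycles)
  cal <- wide_calibration(cfg$n_cycles, im_window = 0.03)
  checked <- 0L
  for (i in seq_len(15)) {
    entry <- lib$precursors[i, ]
    tr <- run$truth[run$truth$precursor_id == entry$precursor_id, ]
    ch <- extract_chromatograms(idx, entry, cal, lib,
                                cycles = 0:(cfg$n_cycles - 1L))
    cand <- find_candidate_peaks(ch)
    if (!nrow(cand)) next
    a <- cand$apex_cycle[which.max(cand$total_intensity)]
    if (abs(a - tr$apex_cycle) > 1.5) next
    q <- quantify_precursor(ch, a, im_window = 0.03, width = 2L)
    planted_area <- tr$abundance *
      sum(lib$fragments$rel_intensity[lib$fragments$precursor_id ==
                                        entry$precursor_id])
    expect_lt(abs(q / planted_area - 1), 0.12)
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
  ## every fragment outside the gate (even split around the median):
  ## missing quantity with a flag
  g <- 100 * dnorm(0:10, 5, 1)
  ch2 <- structure(list(
    precursor_id = 1L, window_id = 1L, cycles = 0:10,
    ions = data.frame(mz = c(500, 600), is_precursor = FALSE,
                      annotation = c("y3", "y4")),
    intensity = rbind(g, g), inv_k0 = rbind(rep(0.9, 11), rep(1.1, 11)),
    obs_mz = rbind(g, g) * 0 + 500), class = "chromatogram_set")
  q2 <- quantify_precursor(ch2, 5, im_window = 1e-6)
  expect_true(is.na(q2))
  expect_true(attr(q2, "all_im_filtered"))
})

test_that("the IM gate removes hijacked fragments from the quantity", {
  ## hand-built chromatograms: 3 fragments, one replaced by an interferer at
  ## shifted mobility and 5x intensity
  nc <- 11
  g <- 100 * dnorm(0:(nc - 1), 5, 1)
  x <- rbind(g, 0.8 * g, 0.6 * g)
  im <- matrix(1.0, 3, nc)
  ch <- structure(list(
    precursor_id = 1L, window_id = 1L, cycles = 0:(nc - 1),
    ions = data.frame(mz = c(500, 600, 700), is_precursor = FALSE,
                      annotation = c("y3", "y4", "y5")),
    intensity = x, inv_k0 = im, obs_mz = x * 0 + 500),
    class = "chromatogram_set")
  clean <- quantify_precursor(ch, 5, im_window = 0.02)
  ch2 <- ch
  ch2$intensity[3, ] <- 5 * g
  ch2$inv_k0[3, ] <- 1.03
  gated <- quantify_precursor(ch2, 5, im_window = 0.02, im_filter = TRUE)
  ungated <- quantify_precursor(ch2, 5, im_window = 0.02, im_filter = FALSE)
  truth3 <- sum(x[, 4:8])
  expect_lt(abs(gated - sum(x[1:2, 4:8])) / truth3, 1e-9)
  expect_gt(ungated, truth3)            # inflated by the interferer
  expect_lt(abs(gated - sum(x[1:2, 4:8])), abs(ungated - truth3))
})
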
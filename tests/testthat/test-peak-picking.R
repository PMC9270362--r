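test_that("scanning-window tolerances follow the stated arithmetic", {
  ## 900 scans over a 0.73 Vs/cm2 mobility range: 10 * 1 / 0.73 scans
  spec <- frame_spec(900L, 0.7, 1.43, 1000L, 400, 1000,
                     data.frame(mz_low = 400, mz_high = 1000, scan_low = 0,
                                scan_high = 900, window_id = 1))
  tol <- scan_window_tolerances(spec)
  expect_equal(tol$im_tol_scans, 10 * (900 / 900) / 0.73, tolerance = 1e-9)
  expect_equal(tol$im_tol_scans, 13.69863, tolerance = 1e-4)
  expect_identical(tol$mz_tol_bins, 2L)
  expect_equal(tol$im_scale, (900 / 900) / 0.73, tolerance = 1e-12)
  ## 600 scans over a unit range
  spec2 <- frame_spec(600L, 0.7, 1.7, 1000L, 400, 1000,
                      data.frame(mz_low = 400, mz_high = 1000, scan_low = 0,
                                 scan_high = 600, window_id = 1))
  expect_equal(scan_window_tolerances(spec2)$im_tol_scans, 600 / 90,
               tolerance = 1e-9)
  ## degenerate mobility axis is rejected upstream
  expect_error(tiny_spec(im_begin = 1, im_end = 1), "im_begin")
})

test_that("window_sum applies the mixed scan/bin criterion literally", {
  spec <- frame_spec(900L, 0.7, 1.43, 1000L, 400, 1000,
                     data.frame(mz_low = 400, mz_high = 1000, scan_low = 0,
                                scan_high = 900, window_id = 1))
  tol <- scan_window_tolerances(spec)  # im_tol 13.699, im_scale 1.370
  ## dscan=10, dbin=1: 10 + 2 * 1 * 1.3699 = 12.74 < 13.699 -> included
  fr <- im_frame(1, 0, data.frame(scan = 110, bin = 501, intensity = 7))
  expect_equal(window_sum(fr, 100, 500, tol), 7)
  ## dscan=10, dbin=2: 10 + 5.479 >= 13.699 -> excluded
  fr2 <- im_frame(1, 0, data.frame(scan = 110, bin = 502, intensity = 7))
  expect_equal(window_sum(fr2, 100, 500, tol), 0)
  ## empty frame sums to zero
  fr0 <- im_frame(1, 0, data.frame(scan = integer(), bin = integer(),
                                   intensity = numeric()))
  expect_equal(window_sum(fr0, 100, 500, tol), 0)
})

test_that("identical-frame merging sums intensities and validates keys", {
  spec <- tiny_spec()
  f1 <- im_frame(1, 0, data.frame(scan = 10, bin = 20, intensity = 5), spec)
  f2 <- im_frame(1, 0, data.frame(scan = 10, bin = 20, intensity = 5), spec)
  f3 <- im_frame(1, 0, data.frame(scan = 3, bin = 7, intensity = 2), spec)
  ## single frame is returned unchanged
  expect_identical(merge_identical_frames(list(f1)), f1)
  m <- merge_identical_frames(list(f1, f2), spec)
  expect_equal(m$points$intensity, 10)
  ## disjoint point sets form the union
  m2 <- merge_identical_frames(list(f1, f3), spec)
  expect_equal(nrow(m2$points), 2L)
  expect_setequal(m2$points$intensity, c(5, 2))
  f4 <- im_frame(2, 0, data.frame(scan = 1, bin = 1, intensity = 1), spec)
  expect_error(merge_identical_frames(list(f1, f4)), "window_id")
})

test_that("isolated points and adjacent-maxima suppression behave as defined", {
  spec <- tiny_spec(n_scans = 30L, n_bins = 40L, im_end = 0.75)
  tol <- scan_window_tolerances(spec)
  ## a single nonzero point is reported at its own coordinates
  fr <- im_frame(1, 0, data.frame(scan = 12, bin = 17, intensity = 42), spec)
  pk <- pick_peaks_2d(fr, spec, tol)$peaks
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$mz, bin_to_mz(spec, 17))
  expect_equal(pk$inv_k0, scan_to_im(spec, 12))
  expect_equal(pk$intensity, 42)
  ## two points one bin apart on the same scan: only the stronger survives
  ## step 2 (verified against the exhaustive oracle)
  fr2 <- im_frame(1, 0, data.frame(scan = c(12, 12), bin = c(17, 18),
                                   intensity = c(100, 60)), spec)
  pk2 <- pick_peaks_2d(fr2, spec, tol)$peaks
  expect_picks_equal(pk2, spec, oracle_pick(fr2, spec, tol))
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$intensity, 160)  # both points inside the stronger window
  expect_equal(pk2$mz, bin_to_mz(spec, 17))
  ## empty frame gives an empty spectrum
  fr0 <- im_frame(1, 0, data.frame(scan = integer(), bin = integer(),
                                   intensity = numeric()))
  expect_equal(nrow(pick_peaks_2d(fr0, spec, tol)$peaks), 0L)
})

test_that("picker equals the exhaustive two-step oracle on random frames", {
  set.seed(77)
  for (trial in 1:60) {
    ns <- sample(8:40, 1); nb <- sample(8:40, 1)
    spec <- tiny_spec(n_scans = ns, n_bins = nb,
                      im_end = 0.7 + runif(1, 0.05, 1.2))
    tol <- scan_window_tolerances(spec)
    fr <- random_frame(spec, sample(1:30, 1))
    expect_picks_equal(pick_peaks_2d(fr, spec, tol)$peaks, spec,
                       oracle_pick(fr, spec, tol))
  }
})

test_that("picking is translation-equivariant and intensity-monotone", {
  set.seed(88)
  spec <- tiny_spec(n_scans = 40L, n_bins = 40L, im_end = 0.8)
  tol <- scan_window_tolerances(spec)
  for (trial in 1:10) {
    pts <- data.frame(scan = sample(5:25, 12, replace = TRUE),
                      bin = sample(5:25, 12, replace = TRUE),
                      intensity = sample(1:50, 12, replace = TRUE))
    base <- pick_peaks_2d(im_frame(1, 0, pts, spec), spec, tol)$peaks
    ## shift all points by (+3 scans, +4 bins), inside bounds
    sh <- pts; sh$scan <- sh$scan + 3L; sh$bin <- sh$bin + 4L
    shifted <- pick_peaks_2d(im_frame(1, 0, sh, spec), spec, tol)$peaks
    expect_equal(nrow(shifted), nrow(base))
    expect_equal(sort(round(mz_to_bin(spec, shifted$mz))),
                 sort(round(mz_to_bin(spec, base$mz)) + 4L))
    expect_equal(sort(round(im_to_scan(spec, shifted$inv_k0))),
                 sort(round(im_to_scan(spec, base$inv_k0)) + 3L))
    expect_equal(sort(shifted$intensity), sort(base$intensity))
    ## scaling intensities by c > 0 scales peak intensities, not coordinates
    sc <- pts; sc$intensity <- sc$intensity * 2.5
    scaled <- pick_peaks_2d(im_frame(1, 0, sc, spec), spec, tol)$peaks
    expect_equal(scaled$mz, base$mz)
    expect_equal(scaled$inv_k0, base$inv_k0)
    expect_equal(scaled$intensity, base$intensity * 2.5)
  }
})

test_that("merging k identical frames equals picking one frame scaled by k", {
  set.seed(99)
  spec <- tiny_spec(n_scans = 30L, n_bins = 30L, im_end = 0.78)
  tol <- scan_window_tolerances(spec)
  pts <- data.frame(scan = sample(0:29, 15, replace = TRUE),
                    bin = sample(0:29, 15, replace = TRUE),
                    intensity = sample(1:40, 15, replace = TRUE))
  k <- 3L
  merged <- merge_identical_frames(rep(list(im_frame(1, 0, pts, spec)), k),
                                   spec)
  via_merge <- pick_peaks_2d(merged, spec, tol)$peaks
  sc <- pts; sc$intensity <- sc$intensity * k
  via_scale <- pick_peaks_2d(im_frame(1, 0, sc, spec), spec, tol)$peaks
  expect_equal(via_merge, via_scale)
})

test_that("pick_run reproduces per-frame picking across windows and cycles", {
  set.seed(123)
  spec <- tiny_spec(n_scans = 25L, n_bins = 35L, im_end = 0.76)
  spec$windows <- rbind(spec$windows,
                        within(spec$windows, window_id <- 2L))
  tol <- scan_window_tolerances(spec)
  frames <- list()
  for (w in 1:2) for (cy in 0:2) {
    frames[[length(frames) + 1L]] <- im_frame(
      w, cy, data.frame(scan = sample(0:24, 10, replace = TRUE),
                        bin = sample(0:34, 10, replace = TRUE),
                        intensity = sample(1:30, 10, replace = TRUE)), spec)
  }
  got <- pick_run(frames, spec, tol)
  expect_length(got, 6L)
  for (s in got) {
    f <- Filter(function(fr) fr$window_id == s$window_id &&
                  fr$cycle == s$cycle, frames)[[1]]
    expect_equal(s$peaks, pick_peaks_2d(f, spec, tol)$peaks,
                 info = sprintf("w%d c%d", s$window_id, s$cycle))
  }
})
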
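# Filtering, pulse detection and dense-sampling featurization.

test_that("low-pass filter preserves DC and attenuates the stopband", {
  fs <- 2e5
  n <- 20000
  const <- new_trace_from_matrix(matrix(0.7, n, 4), fs)
  out <- lowpass_filter(const, 1e4)
  expect_lt(max(abs(out$samples - 0.7)), 1e-9)
  # pure sinusoid at twice the cutoff: attenuation at least the designed
  # stopband factor of the squared (forward-backward) Butterworth response
  cutoff <- 1e4
  t <- seq_len(n) / fs
  sine <- new_trace_from_matrix(matrix(sin(2 * pi * 2 * cutoff * t), n, 4), fs)
  out_s <- lowpass_filter(sine, cutoff, order = 4L)
  mid <- 5000:15000
  att <- max(abs(out_s$samples[mid, 1])) / 1
  # |H|^2 at 2x cutoff for an order-4 Butterworth applied twice
  expected <- 1 / (1 + 2^(2 * 4))
  expect_lt(att, expected * 1.5)
  expect_error(lowpass_filter(const, 1.5e5), "Nyquist")
})

test_that("filtering reduces background noise on a seeded pulse trace", {
  lib <- preset_class_library("DS")
  tr <- simulate_pure(lib[[1]], 3, 0.3, seed = 8)
  ftr <- lowpass_filter(tr)
  head_ix <- 1:2000
  expect_lt(sd(ftr$samples[head_ix, 1]), sd(tr$samples[head_ix, 1]))
})

test_that("detection finds every injected pulse and nothing in background", {
  lib <- four_class_library()
  tr <- simulate_mixture(lib, counts = rep(5, 4), duration = 1, seed = 14)
  pulses <- detect_pulses(lowpass_filter(tr))
  expect_length(pulses, 20L)
  gt <- tr$ground_truth[order(tr$ground_truth$start), ]
  for (i in seq_along(pulses)) {
    # each detected pulse overlaps its ground-truth interval
    expect_lt(max(pulses[[i]]$start, gt$start[i]),
              min(pulses[[i]]$end, gt$end[i]))
  }
  flat <- new_trace_from_matrix(matrix(0.05, 5000, 4), 2e5, filtered = TRUE)
  expect_length(detect_pulses(flat), 0L)
})

test_that("a 2 ms pulse at 200 kS/s is detected near its 400-sample width", {
  cls <- particle_class("w", "parametric", depol = 0.2, settling_sdlog = 0,
                        brightness_sdlog = 0, jitter_depol = 0,
                        jitter_ret_deg = 0)
  tr <- simulate_mixture(list(cls), counts = 1, duration = 0.05, seed = 3)
  p <- detect_pulses(lowpass_filter(tr))
  expect_length(p, 1L)
  w <- p[[1]]$width_samples
  # threshold crossing trims the Gaussian wings: oracle for the expected
  # width given peak/threshold ratio ~ sigma_g * 2 sqrt(2 log(peak/thr))
  expect_gt(w, 200)
  expect_lte(w, 420)
  expect_equal(p[[1]]$width_seconds, w / 2e5)
})

test_that("an absolute threshold below background is refused", {
  flat <- new_trace_from_matrix(matrix(0.2, 5000, 4), 2e5, filtered = TRUE)
  expect_error(detect_pulses(flat, threshold_spec(absolute = 0.5)),
               "background")
  expect_warning(detect_pulses(new_trace_from_matrix(matrix(0.2, 5000, 4),
                                                     2e5, filtered = FALSE)),
                 "filtered")
})

test_that("sampling schemes follow the segmentation definitions", {
  expect_equal(sampling_scheme("ave")$k, 1L)
  expect_equal(sampling_scheme(1)$mode, "ave")
  expect_equal(sampling_scheme("4")$k, 4L)
  expect_true(is.na(sampling_scheme("all")$k))
  expect_error(sampling_scheme("bogus"), "unknown")

  # 400-sample pulse, 4 segments of exactly 100 samples each
  S <- stokes(1, 0.3, 0.1, 0.4)
  p400 <- constant_pulse(S, 400)
  rows <- densify(p400, 4)
  expect_equal(nrow(rows), 4L)
  expect_equal(rows$segment_index, 0:3)
  # remainder handling: 10 into 4 segments -> 3,3,2,2
  sizes <- pulsepol:::segment_sizes(10L, 4L)
  expect_equal(sizes, c(3L, 3L, 2L, 2L))
  expect_equal(sum(sizes), 10L)
})

test_that("ave equals one segment and constant pulses collapse to one row", {
  S <- stokes(1.2, 0.2, -0.1, 0.5)
  p <- constant_pulse(S, 37)
  ave <- densify(p, "ave")
  one <- densify(p, 1)
  expect_equal(ave, one)
  all_rows <- densify(p, "all")
  expect_equal(nrow(all_rows), 37L)
  for (col in c("I", "q", "u", "v", "DOP")) {
    expect_true(all(abs(all_rows[[col]] - ave[[col]][1]) < 1e-12))
  }
})

test_that("short pulses are skipped or padded per policy", {
  p <- constant_pulse(stokes(1, 0, 0, 0.5), 5)
  expect_null(densify(p, 10))
  padded <- densify(p, 10, short_pulse = "pad")
  expect_equal(nrow(padded), 5L)
})

test_that("row counts follow the scheme and labels propagate", {
  lib <- preset_class_library(c("CD", "PS-10"))
  traces <- lapply(1:2, function(i)
    simulate_pure(lib[[i]], 6, 0.5, seed = 40 + i))
  ave_tab <- build_dataset(traces, "ave")
  expect_equal(nrow(ave_tab), 12L)  # one row per pulse
  expect_setequal(unique(ave_tab$label), c("CD", "PS-10"))
  k10 <- build_dataset(traces, 10)
  # k x pulses, less the wing rows dropped below the noise floor
  expect_equal(nrow(k10) + attr(k10, "n_nonpositive"), 120L)
  expect_equal(attr(k10, "n_skipped"), 0L)
  expect_equal(as.integer(attr(k10, "n_pulses")), c(6L, 6L))
})

test_that("channel-space averaging matches the mean of per-sample sources", {
  lib <- preset_class_library("DS")
  tr <- simulate_pure(lib[[1]], 4, 0.4, seed = 55)
  ftr <- subtract_background(lowpass_filter(tr))
  pulses <- detect_pulses(ftr)
  for (p in pulses) {
    ave <- densify(p, "ave")
    # the averaged channel vector inverted = mean of per-sample inversions
    S_all <- invert_stokes(p$samples)
    expect_equal(ave$I, mean(S_all[, 1]), tolerance = 1e-9)
    expect_equal(ave$q * ave$I, mean(S_all[, 2]), tolerance = 1e-9)
  }
})

test_that("per-pulse feature variance decreases with segment averaging", {
  # constant-state pulses with i.i.d. channel noise: segment means average
  # w/k samples, so the within-pulse feature variance must fall as k does
  set.seed(66)
  A <- ideal_psa_matrix()
  ch0 <- as.numeric(unclass(A) %*% stokes(1, 0.2, -0.1, 0.5))
  var_of <- function(scheme) {
    v <- vapply(1:8, function(i) {
      ch <- matrix(rep(ch0, each = 400), nrow = 400) +
        matrix(rnorm(400 * 4, 0, 0.03), 400)
      rows <- densify(make_pulse(ch), scheme)
      var(rows$q) + var(rows$u) + var(rows$v)
    }, numeric(1))
    mean(v)
  }
  v4 <- var_of(4); v10 <- var_of(10); v100 <- var_of(100); vall <- var_of("all")
  expect_gt(vall, v100)
  expect_gt(v100, v10)
  expect_gt(v10, v4)
})

test_that("per-class caps subsample to balanced totals", {
  lib <- preset_class_library(c("CD", "PS-10"))
  traces <- lapply(1:2, function(i)
    simulate_pure(lib[[i]], 6, 0.5, seed = 40 + i))
  capped <- build_dataset(traces, 10, cap_per_class = 25, seed = 1)
  expect_equal(as.integer(table(capped$label)), c(25L, 25L))
  expect_error(build_dataset(traces, 10, cap_per_class = 25), "seed")
})

test_that("feature tables round-trip through the delimited format", {
  lib <- preset_class_library("CD")
  tab <- build_dataset(simulate_pure(lib[[1]], 4, 0.4, seed = 2), 4)
  path <- tempfile(fileext = ".csv")
  write_features(tab, path, meta = list(seed = 2))
  tab2 <- read_features(path)
  expect_equal(tab2$DOP, tab$DOP, tolerance = 1e-12)
  expect_equal(tab2$label, tab$label)
  expect_equal(attr(tab2, "scheme"), "PLP-4")
})
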